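#' @title Gibbs sampler for potential-landscape inference
#' @description
#' The joint posterior over the latent trajectory `x_{1:N}`, the potential
#' values `u_{1:M}` at the inducing points, the friction `zeta` and the
#' measurement-noise variance `sigma2` is sampled by iterating four
#' conditionals: single-site Metropolis-Hastings over positions, an exact
#' multivariate-Gaussian draw for the potential, a log-scale random-walk
#' Metropolis-Hastings update for the friction, and an exact inverse-gamma
#' draw for the noise variance.
#' @name gibbs
NULL

# normalize data into a list of y matrices + dt
prep_data <- function(data) {
  if (!is.list(data)) abort("`data` must be a data frame or a list of data frames.")
  if (is.data.frame(data)) data <- list(data)
  ylist <- purrr::map(data, function(df) {
    cols <- grep("^y[0-9]+$", names(df), value = TRUE)
    if (!length(cols)) cols <- grep("^x[0-9]+$", names(df), value = TRUE)
    if (!length(cols)) abort("Each trajectory needs y1[, y2] (or x1[, x2]) columns.")
    m <- as.matrix(df[cols])
    if (any(!is.finite(m))) abort("Trajectories must not contain non-finite values.")
    m
  })
  D <- unique(vapply(ylist, ncol, 1L))
  if (length(D) != 1L) abort("All trajectories must share the same dimensionality.")
  dts <- vapply(data, function(df) {
    if (!"t" %in% names(df) || nrow(df) < 2) return(NA_real_)
    diff(df$t[1:2])
  }, numeric(1))
  dt <- unique(round(dts[!is.na(dts)], 12))
  if (length(dt) > 1L) abort("All trajectories must share the same sampling interval.")
  list(y = ylist, dt = if (length(dt)) dt else NA_real_, D = as.integer(D),
       n_tot = sum(vapply(ylist, nrow, 1L)))
}

kernel_core_of <- function(kernels) {
  if (inherits(kernels, "skipper_kernel_core")) kernels
  else if (inherits(kernels, "kernel_set")) kernels$core
  else abort("`kernels` must be a kernel_set or its core.")
}

#' Log conditional density of a single latent position
#'
#' Up to an additive constant, the log of the product of: the backward
#' transition density into `x_n` (for `n = 1`, the zero-mean prior with
#' variance `2 dt kT / zeta`), the forward transition density out of `x_n`
#' (absent for `n = N`), and the measurement density `N(y_n; x_n, sigma2)`.
#' Forces are evaluated through the kernel interpolant of `state$u`.
#'
#' @param n Time index, 1..N.
#' @param state List with elements `x` (`N x D` latent matrix), `u`, `zeta`,
#'   `sigma2`.
#' @param y Observed `N x D` matrix (or trajectory tibble).
#' @param params A [skipper_params()] supplying `kT` and `dt` (its `zeta` and
#'   `sigma2` are ignored in favour of `state`).
#' @param kernels A [build_kernel_set()] or its core (grid + factorization).
#' @param value Candidate value(s) for `x_n`: a length-D vector or a `k x D`
#'   matrix; defaults to the current `state$x[n, ]`.
#' @return A length-`k` vector of log densities.
#' @export
position_log_conditional <- function(n, state, y, params, kernels,
                                     value = state$x[n, , drop = FALSE]) {
  core <- kernel_core_of(kernels)
  D <- core$grid$dims
  x <- as_points(state$x, D); y <- as_points(if (is.data.frame(y)) y[grep("^y[0-9]+$", names(y))] else y, D)
  val <- as_points(value, D)
  N <- nrow(x)
  if (n < 1 || n > N) abort("`n` out of range.")
  tau <- params$dt; kT <- params$kT
  g2 <- 2 * tau * kT / state$zeta
  alpha <- core$Kinv %*% state$u
  lp <- numeric(nrow(val))
  if (n == 1L) {
    lp <- lp - rowSums(val^2) / (2 * g2) - D / 2 * log(2 * pi * g2)
  } else {
    fprev <- cpp_force_batch(x[n - 1L, , drop = FALSE], core$grid$locations,
                             alpha, core$hyper$h2, core$hyper$ell)
    mprev <- x[n - 1L, ] + tau / state$zeta * fprev[1, ]
    lp <- lp - rowSums(sweep(val, 2, mprev, "-")^2) / (2 * g2) - D / 2 * log(2 * pi * g2)
  }
  if (n < N) {
    fval <- cpp_force_batch(val, core$grid$locations, alpha,
                            core$hyper$h2, core$hyper$ell)
    mnext <- val + tau / state$zeta * fval
    lp <- lp - rowSums(sweep(mnext, 2, x[n + 1L, ], "-")^2) / (2 * g2) - D / 2 * log(2 * pi * g2)
  }
  lp - rowSums(sweep(val, 2, y[n, ], "-")^2) / (2 * state$sigma2) -
    D / 2 * log(2 * pi * state$sigma2)
}

#' One Metropolis-Hastings sweep over all latent positions
#'
#' Sequential single-site Gaussian random-walk updates for `n = 1..N`,
#' targeting [position_log_conditional()] at every site.
#'
#' @inheritParams position_log_conditional
#' @param prop_sd Random-walk proposal standard deviation, nm.
#' @return List with the updated `x` matrix and the number of `accepted`
#'   moves (out of N).
#' @export
sample_positions <- function(state, y, params, kernels, prop_sd = 1) {
  core <- kernel_core_of(kernels)
  D <- core$grid$dims
  x <- as_points(state$x, D)
  y <- as_points(if (is.data.frame(y)) y[grep("^y[0-9]+$", names(y))] else y, D)
  alpha <- as.vector(core$Kinv %*% state$u)
  cpp_sweep_positions(x, y, core$grid$locations, alpha, core$hyper$h2,
                      core$hyper$ell, params$dt, params$kT, state$zeta,
                      state$sigma2, prop_sd)
}

#' Gaussian conditional for the inducing-point potential values
#'
#' Collapses the Langevin transition likelihood, expressed in force space
#' through the derivative cross-covariance, with the Gaussian-process prior
#' `N(0, K)`:
#' `b = tau/(2 kT) K^{-1} Kstar^T v`,
#' `Lambda = tau/(2 zeta kT) K^{-1} Kstar^T Kstar K^{-1}`,
#' `K_tilde = (K^{-1} + Lambda)^{-1}`, `mu_tilde = K_tilde b`,
#' where `v` holds the flattened per-step velocities `(x_{n+1} - x_n)/tau`.
#' Multiple trajectories contribute additively to `b` and `Lambda`.
#'
#' @param x Latent trajectory: `N x D` matrix, or a list of them.
#' @param zeta Current friction coefficient.
#' @param params A [skipper_params()] supplying `kT` and `dt`.
#' @param kernels Kernel core (or set); only the grid and cached factorization
#'   are used — the force cross-covariance is rebuilt here on the current `x`.
#' @return An object of class `potential_conditional` with elements `b`,
#'   `Lambda`, `mu_tilde`, `K_tilde`, `precision`, `chol_precision`.
#' @export
potential_conditional <- function(x, zeta, params, kernels) {
  core <- kernel_core_of(kernels)
  D <- core$grid$dims
  if (is.matrix(x) || is.data.frame(x)) x <- list(as_points(x, D))
  tau <- params$dt; kT <- params$kT
  M <- nrow(core$K)
  w <- numeric(M); G <- matrix(0, M, M)
  for (xr in x) {
    xr <- as_points(xr, D)
    N <- nrow(xr)
    if (N < 2L) abort("Each trajectory needs N >= 2 for the potential conditional.")
    v <- flatten_multidim(diff(xr) / tau)
    if (any(!is.finite(v))) abort("Non-finite velocities; check `dt` and positions.")
    Ks <- cpp_kstar_flat(xr[-N, , drop = FALSE], core$grid$locations,
                         core$hyper$h2, core$hyper$ell)
    w <- w + drop(crossprod(Ks, v))
    G <- G + crossprod(Ks)
  }
  b <- tau / (2 * kT) * drop(core$Kinv %*% w)
  Lambda <- tau / (2 * zeta * kT) * (core$Kinv %*% G %*% core$Kinv)
  Lambda <- (Lambda + t(Lambda)) / 2
  P <- core$Kinv + Lambda
  P <- (P + t(P)) / 2
  chP <- chol_with_jitter(P, scale = mean(diag(P)))
  Kt <- chol2inv(chP)
  structure(list(b = b, Lambda = Lambda, mu_tilde = drop(Kt %*% b),
                 K_tilde = Kt, precision = P, chol_precision = chP),
            class = "potential_conditional")
}

chol_with_jitter <- function(A, scale = mean(diag(A))) {
  jit <- 0
  repeat {
    ch <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    jit <- if (jit == 0) 1e-10 * scale else jit * 10
    if (jit > 1e-4 * scale)
      abort("Conditional precision could not be factorized.",
            class = "skipper_numeric_error")
  }
}

#' Exact draw from the potential conditional
#'
#' `u ~ N(mu_tilde, K_tilde)` via the cached Cholesky factor of the
#' conditional precision; no Metropolis-Hastings step is involved.
#'
#' @param cond A [potential_conditional()].
#' @return Length-M numeric vector of potential values (kT).
#' @export
sample_potential <- function(cond) {
  stopifnot(inherits(cond, "potential_conditional"))
  z <- rnorm(length(cond$mu_tilde))
  cond$mu_tilde + backsolve(cond$chol_precision, z)
}

#' Log conditional density of the friction coefficient
#'
#' Gamma prior plus the first-position prior `N(x_1; 0, 2 dt kT / zeta)` and
#' the `N - 1` Langevin transition densities, with forces held fixed at the
#' supplied values. Returns `-Inf` for non-positive `zeta`.
#'
#' @param zeta Friction value(s) at which to evaluate (vectorized).
#' @param x `N x D` latent matrix, or list of them.
#' @param forces Matching `(N-1) x D` force matrices `f(x_n)`, or list.
#' @param params A [skipper_params()] supplying `kT` and `dt`.
#' @param priors A [skipper_priors()].
#' @return Log density (up to a constant), same length as `zeta`.
#' @export
friction_log_conditional <- function(zeta, x, forces, params, priors) {
  if (is.matrix(x) || is.data.frame(x)) { x <- list(as.matrix(x)) }
  if (is.matrix(forces) || is.data.frame(forces) || is.null(forces)) forces <- list(forces)
  tau <- params$dt; kT <- params$kT
  vapply(zeta, function(z) {
    if (!is.finite(z) || z <= 0) return(-Inf)
    lp <- stats::dgamma(z, shape = priors$alpha_zeta, rate = priors$beta_zeta, log = TRUE)
    g2 <- 2 * tau * kT / z
    for (r in seq_along(x)) {
      xr <- as.matrix(x[[r]]); N <- nrow(xr); D <- ncol(xr)
      if (N == 0L) next  # no data: conditional reduces to the prior
      lp <- lp - D / 2 * log(2 * pi * g2) - sum(xr[1, ]^2) / (2 * g2)
      if (N >= 2L) {
        fr <- as.matrix(forces[[r]])
        resid <- xr[-1, , drop = FALSE] - xr[-N, , drop = FALSE] - (tau / z) * fr
        lp <- lp - (N - 1) * D / 2 * log(2 * pi * g2) - sum(resid^2) / (2 * g2)
      }
    }
    lp
  }, numeric(1))
}

# sufficient-statistic version used inside the sweep loop:
# lp(zeta) ∝ (alpha_z - 1 + cnt/2) log zeta - beta_z zeta
#            - zeta * s_dx2/(4 tau kT) - tau * s_f2/(4 kT zeta)
# with s_dx2 = sum |dx|^2 + sum |x1|^2, s_f2 = sum |f|^2, cnt = N_tot * D
lp_zeta_stats <- function(zeta, stats, priors, tau, kT) {
  if (zeta <= 0) return(-Inf)
  (priors$alpha_zeta - 1 + stats$cnt / 2) * log(zeta) - priors$beta_zeta * zeta -
    zeta * stats$s_dx2 / (4 * tau * kT) - tau * stats$s_f2 / (4 * kT * zeta)
}

sample_friction_mh <- function(zeta, stats, priors, tau, kT, prop_sd, n_steps) {
  acc <- 0L
  lp0 <- lp_zeta_stats(zeta, stats, priors, tau, kT)
  for (i in seq_len(n_steps)) {
    zp <- zeta * exp(prop_sd * rnorm(1))
    lp1 <- lp_zeta_stats(zp, stats, priors, tau, kT)
    # log-normal proposal: Jacobian term log(zp) - log(zeta)
    if (log(runif(1)) < lp1 - lp0 + log(zp) - log(zeta)) {
      zeta <- zp; lp0 <- lp1; acc <- acc + 1L
    }
  }
  list(zeta = zeta, accepted = acc)
}

#' Conjugate draw of the measurement-noise variance
#'
#' `sigma2 | x, y ~ InvGamma(alpha + N D / 2, beta + sum |x_n - y_n|^2 / 2)`
#' where the shape counts every scalar residual. With no data, returns a
#' draw from the prior.
#'
#' @param x,y Latent and observed `N x D` matrices (or lists of them, or
#'   trajectory tibbles).
#' @param priors A [skipper_priors()].
#' @return A single draw of `sigma2` (nm^2).
#' @export
sample_noise_variance <- function(x, y, priors) {
  as_mats <- function(obj, pref) {
    if (is.data.frame(obj)) {
      cols <- grep(paste0("^", pref, "[0-9]+$"), names(obj), value = TRUE)
      obj <- if (length(cols)) as.matrix(obj[cols]) else as.matrix(obj)
    }
    if (is.matrix(obj)) list(obj) else if (is.null(obj)) list() else
      lapply(obj, function(o) as_mats(o, pref)[[1]])
  }
  xs <- as_mats(x, "x"); ys <- as_mats(y, "y")
  if (length(xs) != length(ys)) abort("`x` and `y` must have matching structure.")
  ssr <- 0; cnt <- 0
  for (r in seq_along(xs)) {
    if (!all(dim(xs[[r]]) == dim(ys[[r]]))) abort("`x` and `y` shapes differ.")
    ssr <- ssr + sum((xs[[r]] - ys[[r]])^2)
    cnt <- cnt + length(xs[[r]])
  }
  1 / rgamma(1, shape = priors$alpha_sigma2 + cnt / 2,
             rate = priors$beta_sigma2 + ssr / 2)
}

#' Fit the landscape model by Gibbs sampling
#'
#' Runs the full sampler on one trajectory or a list of trajectories sharing
#' one potential, friction, and noise level (each trajectory keeps its own
#' latent positions). Per sweep: a Metropolis-Hastings pass over all latent
#' positions, an exact Gaussian draw of the inducing-point potential values,
#' `n_zeta_steps` Metropolis-Hastings updates of the friction, and an exact
#' inverse-gamma draw of the noise variance. The inducing covariance is
#' factorized once up front; only the force cross-covariance is rebuilt each
#' sweep (on the current latent positions).
#'
#' Initialization: `x = y`, `u = 0`, and prior means for `zeta` and `sigma2`.
#' Proposal scales adapt toward `control$target_accept` during burn-in only.
#'
#' @param data Trajectory tibble (columns `t`, `y1`[, `y2`]) or a list of
#'   them; latent `x*` columns are used as observations if no `y*` columns
#'   exist.
#' @param kT Thermal energy unit (default 1).
#' @param dt Sampling interval (ms); taken from the `t` column when `NULL`.
#' @param priors A [skipper_priors()].
#' @param hyper A [kernel_hyper()].
#' @param grid An [inducing_grid()]; defaults to [grid_from_data()].
#' @param m Inducing points per dimension for the default grid.
#' @param control A [skipper_control()].
#' @param seed Optional integer seed; fixes the entire chain.
#' @param verbose Print acceptance rates and log-posterior every 100 sweeps.
#' @return An object of class `skipper_fit`; see [tidy.skipper_fit()],
#'   [glance.skipper_fit()], [summarize_potential()].
#' @examples
#' tr <- simulate_trajectory(make_harmonic(0.005), skipper_params(),
#'                           n_steps = 200, seed = 1)
#' obs <- add_measurement_noise(tr, sigma2 = 4, seed = 2)
#' fit <- run_gibbs(obs, control = skipper_control(sweeps = 50, burnin = 20),
#'                  seed = 3)
#' glance(fit)
#' @export
run_gibbs <- function(data, kT = 1, dt = NULL, priors = skipper_priors(),
                      hyper = kernel_hyper(), grid = NULL, m = NULL,
                      control = skipper_control(), seed = NULL,
                      verbose = FALSE) {
  pd <- prep_data(data)
  if (is.null(dt)) dt <- pd$dt
  if (!is.finite(dt) || dt <= 0) abort("Provide a positive `dt` (or a `t` column).")
  if (any(vapply(pd$y, nrow, 1L) < 2L)) abort("Each trajectory needs N >= 2.")
  if (is.null(grid)) grid <- grid_from_data(pd$y, hyper, m = m)
  if (grid$dims != pd$D) abort("Grid dimensionality does not match the data.")
  core <- kernel_core(grid, hyper)
  params <- skipper_params(kT = kT, zeta = 1, dt = dt, sigma2 = 1)  # carrier for kT, dt
  tau <- dt
  R <- length(pd$y)
  M <- grid$M
  nD <- pd$n_tot * pd$D

  # initialization
  x <- lapply(pd$y, identity)
  u <- numeric(M)
  zeta <- priors$alpha_zeta / priors$beta_zeta
  sigma2 <- if (priors$alpha_sigma2 > 1)
    priors$beta_sigma2 / (priors$alpha_sigma2 - 1) else priors$beta_sigma2
  prop_sd <- control$prop_sd_x %||% (sqrt(sigma2) / 2)
  prop_sd_z <- control$prop_sd_zeta

  init <- list(x = x, u = u, zeta = zeta, sigma2 = sigma2, iteration = 0L)
  S <- control$sweeps
  keep_iters <- if (S > control$burnin)
    seq.int(control$burnin + control$thin, S, by = control$thin) else integer(0)
  # handle thin > remaining sweeps
  keep_iters <- keep_iters[keep_iters <= S]
  if (S > control$burnin && !length(keep_iters)) keep_iters <- S

  zeta_tr <- sigma2_tr <- lp_tr <- accx_tr <- accz_tr <- numeric(S)
  u_draws <- matrix(NA_real_, length(keep_iters), M)
  x_draws <- if (control$store_x) vector("list", length(keep_iters)) else NULL
  ki <- 0L

  with_seed_(seed, {
    for (s in seq_len(S)) {
      # -- positions ------------------------------------------------------
      alpha <- as.vector(core$Kinv %*% u)
      acc <- 0L
      for (r in seq_len(R)) {
        res <- cpp_sweep_positions(x[[r]], pd$y[[r]], grid$locations, alpha,
                                   hyper$h2, hyper$ell, tau, kT, zeta,
                                   sigma2, prop_sd)
        x[[r]] <- res$x
        acc <- acc + res$accepted
      }
      acc_rate <- acc / pd$n_tot

      # -- potential ------------------------------------------------------
      cond <- potential_conditional(x, zeta, params, core)
      u <- sample_potential(cond)
      alpha <- as.vector(core$Kinv %*% u)

      # -- friction -------------------------------------------------------
      s_dx2 <- 0; s_f2 <- 0; lp_dyn_xf <- 0
      for (r in seq_len(R)) {
        xr <- x[[r]]; N <- nrow(xr)
        f <- cpp_force_batch(xr[-N, , drop = FALSE], grid$locations, alpha,
                             hyper$h2, hyper$ell)
        dx <- diff(xr)
        s_dx2 <- s_dx2 + sum(dx^2) + sum(xr[1, ]^2)
        s_f2 <- s_f2 + sum(f^2)
        lp_dyn_xf <- lp_dyn_xf + sum(dx * f)
      }
      zstats <- list(s_dx2 = s_dx2, s_f2 = s_f2, cnt = nD)
      zres <- sample_friction_mh(zeta, zstats, priors, tau, kT, prop_sd_z,
                                 control$n_zeta_steps)
      zeta <- zres$zeta
      accz <- zres$accepted / control$n_zeta_steps

      # -- noise variance -------------------------------------------------
      ssr <- sum(vapply(seq_len(R), function(r) sum((x[[r]] - pd$y[[r]])^2), 0))
      sigma2 <- 1 / rgamma(1, shape = priors$alpha_sigma2 + nD / 2,
                           rate = priors$beta_sigma2 + ssr / 2)

      # -- bookkeeping ----------------------------------------------------
      if (!all(is.finite(c(zeta, sigma2))) || any(!is.finite(u)))
        abort(sprintf("Non-finite state at sweep %d (block: %s).", s,
                      if (!is.finite(zeta)) "friction" else if (!is.finite(sigma2))
                        "noise" else "potential"),
              class = "skipper_numeric_error")
      # unnormalized joint log posterior (diagnostic only)
      lp <- lp_zeta_stats(zeta, zstats, priors, tau, kT) + lp_dyn_xf / (2 * kT) -
        ssr / (2 * sigma2) - (nD / 2 + priors$alpha_sigma2 + 1) * log(sigma2) -
        priors$beta_sigma2 / sigma2 - 0.5 * sum(u * (core$Kinv %*% u))
      zeta_tr[s] <- zeta; sigma2_tr[s] <- sigma2; lp_tr[s] <- lp
      accx_tr[s] <- acc_rate; accz_tr[s] <- accz

      # burn-in-only adaptation (Robbins-Monro toward target acceptance)
      if (control$adapt && s <= control$burnin) {
        step <- min(0.1, 5 / sqrt(s + 10))
        prop_sd <- prop_sd * exp(step * (acc_rate - control$target_accept))
        prop_sd_z <- prop_sd_z * exp(step * (accz - control$target_accept))
      }

      if (s %in% keep_iters) {
        ki <- ki + 1L
        u_draws[ki, ] <- u
        if (control$store_x) x_draws[[ki]] <- x
      }
      if (verbose && s %% 100 == 0)
        message(sprintf("sweep %d: acc_x %.2f acc_zeta %.2f zeta %.3g sigma %.3g logpost %.4g",
                        s, acc_rate, accz, zeta, sqrt(sigma2), lp))
    }
  })

  draws <- tibble(
    iteration = seq_len(S), zeta = zeta_tr, sigma2 = sigma2_tr,
    log_post = lp_tr, accept_x = accx_tr, accept_zeta = accz_tr
  )
  structure(
    list(draws = draws, u_draws = u_draws, kept_iterations = keep_iters,
         x_draws = x_draws, x_final = x,
         state = list(x = x, u = u, zeta = zeta, sigma2 = sigma2, iteration = S),
         init = init, grid = grid, hyper = hyper, core = core,
         priors = priors, control = control, data = pd, kT = kT, dt = dt,
         prop_sd = c(x = prop_sd, zeta = prop_sd_z), seed = seed),
    class = "skipper_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.skipper_fit <- function(x, ...) {
  cat(sprintf("<skipper_fit> %d trajectories, %d points (%dD), M = %d inducing points\n",
              length(x$data$y), x$data$n_tot, x$data$D, x$grid$M))
  cat(sprintf("  %d sweeps (%d burn-in, thin %d): %d retained potential draws\n",
              x$control$sweeps, x$control$burnin, x$control$thin, nrow(x$u_draws)))
  if (x$control$sweeps > x$control$burnin) {
    post <- dplyr::filter(x$draws, .data$iteration > x$control$burnin)
    cat(sprintf("  posterior means: zeta = %.4g, sigma = %.4g nm\n",
                mean(post$zeta), mean(sqrt(post$sigma2))))
  }
  invisible(x)
}

#' Tidy the scalar chain of a fit
#'
#' @param x A `skipper_fit`.
#' @param include_burnin Keep burn-in sweeps (default drops them).
#' @param ... Unused.
#' @return A long tibble with `iteration`, `term` (`zeta`, `sigma2`,
#'   `log_post`) and `value`.
#' @export
tidy.skipper_fit <- function(x, include_burnin = FALSE, ...) {
  d <- x$draws
  if (!include_burnin) d <- dplyr::filter(d, .data$iteration > x$control$burnin)
  tidyr::pivot_longer(
    dplyr::select(d, "iteration", "zeta", "sigma2", "log_post"),
    -"iteration", names_to = "term", values_to = "value")
}

#' One-row posterior summary of a fit
#'
#' @param x A `skipper_fit`.
#' @param ... Unused.
#' @return A tibble with data size, posterior means and sds of `zeta` and
#'   `sigma2`, the posterior-mean noise magnitude `sigma`, and mean
#'   acceptance rates.
#' @export
glance.skipper_fit <- function(x, ...) {
  post <- dplyr::filter(x$draws, .data$iteration > x$control$burnin)
  tibble(
    n_traj = length(x$data$y), n_points = x$data$n_tot, dims = x$data$D,
    sweeps = x$control$sweeps, burnin = x$control$burnin,
    zeta_mean = mean(post$zeta), zeta_sd = sd(post$zeta),
    sigma2_mean = mean(post$sigma2), sigma2_sd = sd(post$sigma2),
    sigma_mean = mean(sqrt(post$sigma2)),
    accept_x = mean(post$accept_x), accept_zeta = mean(post$accept_zeta)
  )
}

#' Trace plots of the scalar chain
#'
#' @param object A `skipper_fit`.
#' @param include_burnin Show burn-in sweeps too.
#' @param ... Unused.
#' @return A ggplot with one facet per scalar parameter.
#' @export
autoplot.skipper_fit <- function(object, include_burnin = TRUE, ...) {
  d <- tidy(object, include_burnin = include_burnin)
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "sweep", y = NULL)
}
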
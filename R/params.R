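#' Physical parameters of the overdamped dynamics and measurement model
#'
#' Bundles the constants entering the forward model: the thermal energy `kT`
#' (the package's internal energy unit, so normally 1), the friction
#' coefficient `zeta` (kT ms / nm^2), the sampling interval `dt` (ms) and the
#' measurement-noise variance `sigma2` (nm^2). The per-step dynamical variance
#' of the forward-Euler scheme is `gamma2 = 2 * kT * dt / zeta`.
#'
#' Default values describe a micron-scale bead in a feedback trap sampled at
#' 100 kHz: `dt = 0.01` ms, `zeta = 2e-3` kT ms / nm^2 (diffusion coefficient
#' `kT / zeta` = 500 nm^2/ms), and 5 nm measurement noise.
#'
#' @param kT Thermal energy; energies elsewhere are expressed in units of it.
#' @param zeta Friction coefficient, kT ms / nm^2. Must be positive.
#' @param dt Sampling interval, ms. Must be positive.
#' @param sigma2 Measurement-noise variance, nm^2. Must be non-negative.
#'
#' @return An object of class `skipper_params` (a named list with an added
#'   `gamma2` element).
#' @examples
#' p <- skipper_params()
#' p$gamma2  # 2 * kT * dt / zeta
#' @export
skipper_params <- function(kT = 1, zeta = 2e-3, dt = 0.01, sigma2 = 25) {
  if (!is.numeric(kT) || length(kT) != 1 || kT <= 0) abort("`kT` must be a positive scalar.")
  if (!is.numeric(zeta) || length(zeta) != 1 || zeta <= 0) abort("`zeta` must be a positive scalar.")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) abort("`dt` must be a positive scalar.")
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 < 0) abort("`sigma2` must be non-negative.")
  structure(
    list(kT = kT, zeta = zeta, dt = dt, sigma2 = sigma2,
         gamma2 = 2 * kT * dt / zeta),
    class = "skipper_params"
  )
}

#' @export
print.skipper_params <- function(x, ...) {
  cat("<skipper_params>\n")
  cat(sprintf("  kT     = %g (energy unit)\n", x$kT))
  cat(sprintf("  zeta   = %g kT ms/nm^2  (D = kT/zeta = %g nm^2/ms)\n", x$zeta, x$kT / x$zeta))
  cat(sprintf("  dt     = %g ms\n", x$dt))
  cat(sprintf("  sigma2 = %g nm^2  (sigma = %g nm)\n", x$sigma2, sqrt(x$sigma2)))
  cat(sprintf("  gamma2 = %g nm^2 per step\n", x$gamma2))
  invisible(x)
}

#' Prior hyperparameters for the Gibbs sampler
#'
#' The friction coefficient carries a Gamma(`alpha_zeta`, `beta_zeta`) prior
#' (shape/rate) and the measurement-noise variance an inverse-gamma
#' (`alpha_sigma2` shape, `beta_sigma2` scale), conjugate to the Gaussian
#' measurement model. `Theta2` is an alternative fixed prior variance for the
#' first latent position; the sampler instead uses the friction-dependent
#' variance `2 * dt * kT / zeta` throughout so that the friction conditional
#' keeps its closed multiplicative form, and `Theta2` is retained only for
#' completeness.
#'
#' Defaults are weakly informative at laboratory scales: prior mean friction
#' 2e-3 kT ms/nm^2 with unit-shape spread, and a noise prior with mean 25 nm^2
#' (sigma = 5 nm) and infinite variance.
#'
#' @param alpha_zeta,beta_zeta Gamma shape and rate for the friction prior.
#' @param alpha_sigma2,beta_sigma2 Inverse-gamma shape and scale for the
#'   noise-variance prior.
#' @param Theta2 Unused alternative prior variance (nm^2) for the first
#'   position; see Details.
#' @return An object of class `skipper_priors`.
#' @examples
#' skipper_priors()
#' @export
skipper_priors <- function(alpha_zeta = 2, beta_zeta = 1000,
                           alpha_sigma2 = 2, beta_sigma2 = 25,
                           Theta2 = 1e4) {
  vals <- c(alpha_zeta, beta_zeta, alpha_sigma2, beta_sigma2, Theta2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("All prior hyperparameters must be positive and finite.")
  structure(
    list(alpha_zeta = alpha_zeta, beta_zeta = beta_zeta,
         alpha_sigma2 = alpha_sigma2, beta_sigma2 = beta_sigma2,
         Theta2 = Theta2),
    class = "skipper_priors"
  )
}

#' @export
print.skipper_priors <- function(x, ...) {
  cat("<skipper_priors>\n")
  cat(sprintf("  zeta   ~ Gamma(shape = %g, rate = %g)   [mean %g]\n",
              x$alpha_zeta, x$beta_zeta, x$alpha_zeta / x$beta_zeta))
  cat(sprintf("  sigma2 ~ InvGamma(shape = %g, scale = %g)\n",
              x$alpha_sigma2, x$beta_sigma2))
  invisible(x)
}

#' Squared-exponential kernel hyperparameters
#'
#' The potential prior kernel is `k(x, x') = h2 * exp(-|x - x'|^2 / (2 ell^2))`
#' with output scale `h2` (kT^2) and length scale `ell` (nm). These are fixed
#' per run (not sampled).
#'
#' @param h2 Kernel output variance, kT^2. Default 25 (prior pointwise sd 5 kT).
#' @param ell Kernel length scale, nm. Default 10.
#' @return An object of class `skipper_kernel_hyper`.
#' @export
kernel_hyper <- function(h2 = 25, ell = 10) {
  if (!is.numeric(h2) || length(h2) != 1 || h2 <= 0) abort("`h2` must be positive.")
  if (!is.numeric(ell) || length(ell) != 1 || ell <= 0) abort("`ell` must be positive.")
  structure(list(h2 = h2, ell = ell), class = "skipper_kernel_hyper")
}

#' @export
print.skipper_kernel_hyper <- function(x, ...) {
  cat(sprintf("<skipper_kernel_hyper> h2 = %g kT^2, ell = %g nm\n", x$h2, x$ell))
  invisible(x)
}

#' Sampler controls
#'
#' @param sweeps Total Gibbs sweeps.
#' @param burnin Sweeps discarded as burn-in (must be < `sweeps`).
#' @param thin Keep every `thin`-th post-burn-in sweep for the stored potential
#'   and trajectory draws (scalars are stored every sweep).
#' @param prop_sd_x Initial random-walk proposal sd for positions, nm. Adapted
#'   toward `target_accept` during burn-in only.
#' @param prop_sd_zeta Initial log-scale proposal sd for the friction update.
#' @param n_zeta_steps Metropolis-Hastings steps on the friction per sweep.
#' @param target_accept Acceptance rate targeted by burn-in adaptation.
#' @param store_x Store thinned latent-trajectory draws (can be large).
#' @param adapt Adapt proposal scales during burn-in.
#' @return An object of class `skipper_control`.
#' @export
skipper_control <- function(sweeps = 5000, burnin = 2000, thin = 5,
                            prop_sd_x = NULL, prop_sd_zeta = 0.1,
                            n_zeta_steps = 5, target_accept = 0.35,
                            store_x = FALSE, adapt = TRUE) {
  if (sweeps < 0) abort("`sweeps` must be non-negative.")
  if (burnin < 0 || (sweeps > 0 && burnin >= sweeps))
    abort("`burnin` must be in [0, sweeps).")
  if (thin < 1) abort("`thin` must be >= 1.")
  structure(
    list(sweeps = as.integer(sweeps), burnin = as.integer(burnin),
         thin = as.integer(thin), prop_sd_x = prop_sd_x,
         prop_sd_zeta = prop_sd_zeta, n_zeta_steps = as.integer(n_zeta_steps),
         target_accept = target_accept, store_x = isTRUE(store_x),
         adapt = isTRUE(adapt)),
    class = "skipper_control"
  )
}

# evaluate a block with a temporary seed without clobbering the caller's RNG;
# seed = NULL leaves the RNG stream alone
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    abort("`seed` must be a single finite number or NULL.")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
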
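#' Simulate an overdamped Langevin trajectory
#'
#' Forward-Euler integration of overdamped Langevin dynamics: given the
#' current position, the next is drawn from
#' `N(x_n + (dt / zeta) * f(x_n), gamma2 * I)` with per-step variance
#' `gamma2 = 2 * kT * dt / zeta`. A warning is issued when the local curvature
#' of the potential makes the scheme marginally stable
#' (`dt * stiffness / zeta > 0.1`), and integration aborts with the offending
#' step index if the trajectory leaves `[-bound, bound]` (the usual symptom of
#' a `dt` too large for the stiffness).
#'
#' @param potential A [skipper_potential].
#' @param params A [skipper_params()] (`sigma2` is ignored here).
#' @param n_steps Number of time points (>= 1).
#' @param x0 Initial position (length-D vector).
#' @param seed Optional integer seed; identical seeds give identical
#'   trajectories and the caller's RNG state is left untouched.
#' @param bound Divergence guard, nm.
#' @return A tibble with columns `t` (ms) and `x1`[, `x2`] (nm).
#' @examples
#' tr <- simulate_trajectory(make_harmonic(0.005), skipper_params(),
#'                           n_steps = 100, seed = 1)
#' @export
simulate_trajectory <- function(potential, params, n_steps, x0 = NULL,
                                seed = NULL, bound = 1e5) {
  stopifnot(inherits(potential, "skipper_potential"),
            inherits(params, "skipper_params"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) abort("`n_steps` must be >= 1.")
  D <- potential$dims
  if (is.null(x0)) x0 <- rep(0, D)
  if (length(x0) != D) abort(sprintf("`x0` must have length %d.", D))
  check_stability(potential, params, x0)
  drift <- params$dt / params$zeta
  g <- sqrt(params$gamma2)
  x <- matrix(NA_real_, n_steps, D)
  x[1, ] <- x0
  with_seed_(seed, {
    if (n_steps > 1L) {
      noise <- matrix(rnorm((n_steps - 1L) * D, sd = g), ncol = D)
      for (n in seq_len(n_steps - 1L)) {
        f <- potential$force(x[n, , drop = FALSE])
        x[n + 1L, ] <- x[n, ] + drift * f + noise[n, ]
        if (any(abs(x[n + 1L, ]) > bound))
          abort(sprintf(
            "Trajectory diverged at step %d (|x| > %g nm): `dt` is likely too large for the local stiffness.",
            n + 1L, bound), class = "skipper_numeric_error")
      }
    }
  })
  out <- as_tibble(as.data.frame(x))
  names(out) <- paste0("x", seq_len(D))
  dplyr::bind_cols(tibble(t = (seq_len(n_steps) - 1) * params$dt), out)
}

# warn when forward Euler is marginally stable at x: dt * max curvature / zeta > 0.1
check_stability <- function(potential, params, x, h = 1e-3) {
  x <- as_points(x, potential$dims)
  curv <- vapply(seq_len(potential$dims), function(d) {
    e <- matrix(0, 1, potential$dims); e[1, d] <- h
    (potential$energy(x + e) - 2 * potential$energy(x) + potential$energy(x - e)) / h^2
  }, numeric(1))
  stiff <- max(abs(curv))
  if (params$dt * stiff / params$zeta > 0.1)
    warn(sprintf(
      "dt * stiffness / zeta = %.3g > 0.1 at the initial position; forward Euler may be inaccurate.",
      params$dt * stiff / params$zeta))
  invisible(stiff)
}

#' Corrupt a latent trajectory with Gaussian measurement noise
#'
#' Adds independent `N(0, sigma2 * I)` measurement noise to every position:
#' `y_n = x_n + eps_n`. The latent columns are retained as ground truth.
#'
#' @param x A latent trajectory tibble from [simulate_trajectory()] (columns
#'   `t`, `x1`[, `x2`]).
#' @param sigma2 Measurement-noise variance, nm^2 (>= 0).
#' @param seed Optional integer seed.
#' @return The input tibble with added measurement columns `y1` (and `y2`).
#' @export
add_measurement_noise <- function(x, sigma2, seed = NULL) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 < 0)
    abort("`sigma2` must be a non-negative scalar.")
  xcols <- grep("^x[0-9]+$", names(x), value = TRUE)
  if (!length(xcols)) abort("`x` must contain latent position columns x1[, x2].")
  xm <- as.matrix(x[xcols])
  # noise drawn row-major so that corrupting a sliced trajectory matches
  # slicing a corrupted one under the same seed
  ym <- with_seed_(seed,
    xm + matrix(rnorm(length(xm), sd = sqrt(sigma2)),
                nrow = nrow(xm), byrow = TRUE))
  for (d in seq_along(xcols)) x[[paste0("y", d)]] <- ym[, d]
  x
}

#' Ensemble of non-equilibrium "roll-off" trajectories
#'
#' Simulates `n_traj` short, independent trajectories all initiated at the
#' same point (canonically a barrier top), each corrupted independently with
#' measurement noise. Ensembles of such traces jointly constrain a landscape
#' that no single short trace samples fully.
#'
#' @inheritParams simulate_trajectory
#' @param n_traj Number of trajectories (default 100).
#' @param len_traj Points per trajectory (default 500).
#' @param sigma2 Measurement-noise variance (defaults to `params$sigma2`).
#' @return A list of `n_traj` trajectory tibbles (`t`, `x*`, `y*` columns).
#' @export
simulate_rolloff_ensemble <- function(potential, params, n_traj = 100,
                                      len_traj = 500, x0 = NULL,
                                      sigma2 = params$sigma2, seed = NULL) {
  n_traj <- as.integer(n_traj)
  if (n_traj < 1L) abort("`n_traj` must be >= 1.")
  with_seed_(seed, {
    purrr::map(seq_len(n_traj), function(i) {
      tr <- simulate_trajectory(potential, params, n_steps = len_traj, x0 = x0)
      add_measurement_noise(tr, sigma2)
    })
  })
}
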
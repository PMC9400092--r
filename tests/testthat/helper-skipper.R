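# shared fixtures and small numerical utilities, all built in code

# a potential with identically zero force (free diffusion)
flat_potential <- function() {
  skipper:::new_potential(
    energy = function(x) rep(0, nrow(skipper:::as_points(x, 1L))),
    force = function(x) matrix(0, nrow(skipper:::as_points(x, 1L)), 1L),
    dims = 1L, name = "flat"
  )
}

# central-difference gradient of a potential's energy at points (n x D)
fd_gradient <- function(pot, pts, h = 1e-4) {
  pts <- skipper:::as_points(pts, pot$dims)
  out <- matrix(NA_real_, nrow(pts), pot$dims)
  for (d in seq_len(pot$dims)) {
    e <- matrix(0, 1, pot$dims); e[1, d] <- h
    ep <- pts + matrix(e, nrow(pts), pot$dims, byrow = TRUE)
    em <- pts - matrix(e, nrow(pts), pot$dims, byrow = TRUE)
    out[, d] <- (pot$energy(ep) - pot$energy(em)) / (2 * h)
  }
  out
}

# total-variation distance between a sample and a density known on a uniform grid
tv_distance <- function(samples, grid, log_density) {
  half <- diff(grid[1:2]) / 2
  breaks <- c(grid - half, grid[length(grid)] + half)
  counts <- tabulate(findInterval(samples, breaks) + 1L,
                     nbins = length(breaks) + 1L)
  p_hat <- counts[2:length(breaks)] / length(samples)
  outside <- (counts[1] + counts[length(breaks) + 1L]) / length(samples)
  dens <- exp(log_density - max(log_density))
  p_true <- dens / sum(dens)
  # mass escaping the grid counts fully against the distance
  0.5 * (sum(abs(p_hat - p_true)) + outside)
}

# multivariate normal log density (independent of any package internals)
mvn_log_density <- function(X, mu, S) {
  Xc <- sweep(as.matrix(X), 2, mu, "-")
  Si <- solve(S)
  -0.5 * rowSums((Xc %*% Si) * Xc) - 0.5 * determinant(S)$modulus[1] -
    ncol(X) / 2 * log(2 * pi)
}

# quadratic curvature of an energy curve around its minimum: U = c0 + 0.5*k*(x-x0)^2
fit_curvature <- function(x, energy, weights = NULL) {
  fit <- stats::lm(energy ~ x + I(x^2), weights = weights)
  2 * stats::coef(fit)[["I(x^2)"]]
}

# standard benchmark settings used across tests
bench_params <- function(sigma2 = 25) skipper_params(zeta = 2e-3, dt = 0.01, sigma2 = sigma2)
bench_harmonic <- function() make_harmonic(stiffness = 0.005)
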
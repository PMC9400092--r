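#' Boltzmann histogram estimate of a potential
#'
#' The classical equilibrium baseline: bin the observed positions, convert
#' occupancy fractions `p_i` to energies `U_i = -kT log(p_i)`, and report
#' energies relative to the minimum-energy occupied bin (set to 0 kT). The
#' estimate assumes equilibrium sampling and ignores measurement noise, which
#' broadens the apparent potential — the failure mode the full sampler is
#' designed to avoid.
#'
#' @param data Trajectory tibble (uses `y1`[, `y2`] columns, falling back to
#'   `x1`[, `x2`]), a numeric vector, or a matrix of positions.
#' @param bin_width Bin width, nm (scalar or per dimension). Default 2 nm in
#'   1D and 10 nm in 2D.
#' @param kT Thermal energy unit.
#' @return An object of class `boltzmann_estimate`: a tibble with bin-centre
#'   columns `x1`[, `x2`], `count`, `p` (fraction of time, summing to 1 over
#'   occupied bins), `occupied`, and `energy` (kT; `NA` for unoccupied bins).
#'   Bin edges are kept in the `edges` attribute.
#' @examples
#' y <- rnorm(10000, sd = 10)
#' boltzmann_estimate(y, bin_width = 2)
#' @export
boltzmann_estimate <- function(data, bin_width = NULL, kT = 1) {
  ym <- obs_matrix(data)
  D <- ncol(ym)
  if (is.null(bin_width)) bin_width <- if (D == 1L) 2 else 10
  bin_width <- rep_len(bin_width, D)
  if (any(bin_width <= 0)) abort("`bin_width` must be positive.")
  edges <- lapply(seq_len(D), function(d) {
    r <- range(ym[, d])
    nb <- max(1L, ceiling((r[2] - r[1]) / bin_width[d]))
    seq(r[1], by = bin_width[d], length.out = nb + 1L)
  })
  idx <- vapply(seq_len(D), function(d)
    pmin(findInterval(ym[, d], edges[[d]], rightmost.closed = TRUE),
         length(edges[[d]]) - 1L), integer(nrow(ym)))
  idx <- matrix(idx, ncol = D)
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  lin <- idx[, 1]
  if (D == 2L) lin <- lin + (idx[, 2] - 1L) * nb[1]
  counts <- tabulate(lin, nbins = prod(nb))
  if (sum(counts > 0) == 1L)
    warn("All observations fall in a single bin; the estimate is a single point.")
  centers <- lapply(edges, function(e) (head(e, -1) + tail(e, -1)) / 2)
  grid <- as.matrix(expand.grid(centers))
  colnames(grid) <- paste0("x", seq_len(D))
  p <- counts / sum(counts)
  energy <- ifelse(p > 0, -kT * log(p), NA_real_)
  energy <- energy - min(energy, na.rm = TRUE)
  out <- dplyr::bind_cols(as_tibble(as.data.frame(grid)),
                          tibble(count = counts, p = p,
                                 occupied = counts > 0L, energy = energy))
  structure(out, edges = edges, bin_width = bin_width, kT = kT,
            class = c("boltzmann_estimate", class(out)))
}

# extract an observation matrix from tibble / vector / matrix input
obs_matrix <- function(data) {
  if (is.data.frame(data)) {
    cols <- grep("^y[0-9]+$", names(data), value = TRUE)
    if (!length(cols)) cols <- grep("^x[0-9]+$", names(data), value = TRUE)
    if (!length(cols)) abort("No y1[, y2] or x1[, x2] columns found.")
    ym <- as.matrix(data[cols])
  } else if (is.matrix(data)) ym <- data
  else ym <- matrix(as.numeric(data), ncol = 1)
  if (!ncol(ym) %in% 1:2) abort("Only 1D and 2D data are supported.")
  if (any(!is.finite(ym))) abort("Positions must be finite.")
  ym
}

#' @export
autoplot.boltzmann_estimate <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$occupied)
  if (!"x2" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$x1, .data$energy)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "position (nm)", y = "U (kT)",
                    title = "Boltzmann histogram estimate")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$x1, .data$x2, fill = .data$energy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(direction = -1) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "U (kT)")
  }
}

#' Measurement-noise statistics from a dual-detector difference trace
#'
#' Two simultaneous measurements of the same trajectory differ only by their
#' measurement noises, so the per-sample difference has mean equal to the
#' calibration offset, variance equal to the sum of the two noise variances,
#' and — for independent noise — an autocorrelation that is flat beyond
#' lag 0.
#'
#' @param y1,y2 Two trajectories of equal length: tibbles (using the `y*`
#'   columns), vectors, or matrices.
#' @param max_lag Largest autocorrelation lag reported.
#' @return A list with `offset` and `variance_sum` (per dimension) and
#'   `lag_autocorr`, a tibble of normalized autocorrelations by `lag` and
#'   `dim`.
#' @export
noise_from_difference <- function(y1, y2, max_lag = 50) {
  m1 <- obs_matrix(y1); m2 <- obs_matrix(y2)
  if (!all(dim(m1) == dim(m2)))
    abort("`y1` and `y2` must have the same length and dimensionality.")
  d <- m1 - m2
  ac <- purrr::map_dfr(seq_len(ncol(d)), function(k) {
    a <- acf(d[, k], lag.max = max_lag, plot = FALSE, demean = TRUE)
    tibble(dim = k, lag = as.vector(a$lag), autocorr = as.vector(a$acf))
  })
  list(offset = colMeans(d),
       variance_sum = apply(d, 2, var),
       lag_autocorr = ac,
       n = nrow(d))
}
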
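#' Posterior draws of the potential on evaluation points
#'
#' Evaluates every retained inducing-point draw through the kernel
#' interpolant, giving one curve (or surface) per retained sweep.
#'
#' @param fit A [run_gibbs()] fit.
#' @param eval_points Evaluation locations (vector in 1D or `n x D` matrix);
#'   defaults to the inducing-grid locations.
#' @return A list with `locations` (matrix) and `draws`
#'   (`n_retained x n_eval` matrix, kT).
#' @export
potential_draws <- function(fit, eval_points = NULL) {
  stopifnot(inherits(fit, "skipper_fit"))
  if (nrow(fit$u_draws) < 1L)
    abort("The chain holds no retained potential draws.")
  pts <- if (is.null(eval_points)) fit$grid$locations
         else as_points(eval_points, fit$grid$dims)
  B <- cpp_se_kernel(pts, fit$grid$locations, fit$hyper$h2, fit$hyper$ell) %*%
    fit$core$Kinv
  list(locations = pts, draws = fit$u_draws %*% t(B))
}

#' Posterior summary of the potential with credible bands
#'
#' Pointwise posterior mean and quantile bands of the potential over a set of
#' evaluation points. Band width tracks the local density of data: regions
#' the particle rarely visits revert toward the prior and carry wide bands.
#' With `align = "min"` each retained curve is first shifted so its minimum
#' is 0 (landscapes are only identified up to an additive constant by the
#' dynamics), and the reported mean curve is shifted to touch 0.
#'
#' @inheritParams potential_draws
#' @param probs Two quantiles for the credible band (default 90% equal-tail).
#' @param align `"none"` or `"min"`.
#' @return A `potential_summary`: tibble with `x1`[, `x2`], `mean`, `lower`,
#'   `upper` (kT), plus `probs` and `align` attributes.
#' @export
summarize_potential <- function(fit, eval_points = NULL,
                                probs = c(0.05, 0.95),
                                align = c("none", "min")) {
  align <- match.arg(align)
  if (length(probs) != 2L || any(probs <= 0) || any(probs >= 1) ||
      probs[1] >= probs[2])
    abort("`probs` must be two increasing values in (0, 1).")
  pd <- potential_draws(fit, eval_points)
  if (nrow(pd$draws) < 2L)
    abort("Need at least 2 retained draws to summarize the potential.")
  dr <- pd$draws
  if (align == "min") dr <- dr - apply(dr, 1, min)
  m <- colMeans(dr)
  qs <- apply(dr, 2, quantile, probs = probs, names = FALSE)
  offset <- 0
  if (align == "min") {
    offset <- min(m)
    m <- m - offset; qs <- qs - offset
  }
  out <- as_tibble(as.data.frame(pd$locations))
  names(out) <- paste0("x", seq_len(ncol(pd$locations)))
  out$mean <- m; out$lower <- qs[1, ]; out$upper <- qs[2, ]
  structure(out, probs = probs, align = align, offset = offset,
            class = c("potential_summary", class(out)))
}

#' Barrier height of a double-well posterior-mean curve
#'
#' Locates the local minima and maxima of the (1D) mean curve on its
#' evaluation grid, takes the two deepest minima, and returns the largest
#' interior value between them minus the mean of the two minima. Ties are
#' broken toward the leftmost extremum. Errors when the curve has no interior
#' maximum flanked by two minima (e.g. a flat or single-well curve).
#'
#' @param summary A [summarize_potential()] result, or any data frame with
#'   `x1` and `mean` (or `energy`) columns, sorted or not.
#' @return Barrier height, kT.
#' @examples
#' curve <- eval_potential(make_double_well(), seq(-120, 120, by = 1))
#' curve$mean <- curve$energy
#' barrier_height(curve)  # 10
#' @export
barrier_height <- function(summary) {
  df <- as_tibble(summary)
  if ("x2" %in% names(df)) abort("`barrier_height()` requires a 1D summary.")
  ycol <- if ("mean" %in% names(df)) "mean" else if ("energy" %in% names(df))
    "energy" else abort("Need a `mean` or `energy` column.")
  df <- dplyr::arrange(df, .data$x1)
  m <- df[[ycol]]
  n <- length(m)
  if (n < 3L) abort("Need at least 3 grid points.")
  d <- diff(m)
  # strict sign changes; plateaus resolved toward the leftmost point
  mins <- which(d[-1] > 0 & d[-(n - 1)] < 0) + 1L
  maxs <- which(d[-1] < 0 & d[-(n - 1)] > 0) + 1L
  if (length(mins) < 2L || !length(maxs))
    abort("No interior maximum flanked by two minima was found in the mean curve.")
  mins <- mins[order(m[mins])][1:2]
  mins <- sort(mins)
  between <- maxs[maxs > mins[1] & maxs < mins[2]]
  if (!length(between))
    abort("No interior maximum found between the two deepest minima.")
  top <- max(m[between])
  top - mean(m[mins])
}

#' Plot a potential summary
#'
#' 1D: posterior-mean curve with its credible ribbon, optionally overlaid
#' with a ground-truth potential and a Boltzmann baseline. 2D: raster of the
#' posterior mean with cells more than `mask_above` kT above the minimum
#' masked (shown blank), mirroring the usual display convention.
#'
#' @param object A `potential_summary`.
#' @param truth Optional [skipper_potential] to overlay (1D only).
#' @param boltzmann Optional [boltzmann_estimate()] overlay (1D only).
#' @param mask_above Masking threshold for 2D display, kT above the minimum.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potential_summary <- function(object, truth = NULL, boltzmann = NULL,
                                       mask_above = 5, ...) {
  df <- as_tibble(object)
  if (!"x2" %in% names(df)) {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x1)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                           fill = "steelblue", alpha = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue") +
      ggplot2::labs(x = "position (nm)", y = "U (kT)")
    if (!is.null(truth)) {
      tr <- eval_potential(truth, df$x1)
      if (attr(object, "align") == "min") tr$energy <- tr$energy - min(tr$energy)
      p <- p + ggplot2::geom_line(data = tr, ggplot2::aes(y = .data$energy),
                                  linetype = 2)
    }
    if (!is.null(boltzmann)) {
      bz <- dplyr::filter(as_tibble(boltzmann), .data$occupied)
      p <- p + ggplot2::geom_point(data = bz, ggplot2::aes(y = .data$energy),
                                   shape = 1, size = 0.8)
    }
    p
  } else {
    df$masked <- df$mean > min(df$mean) + mask_above
    ggplot2::ggplot(dplyr::filter(df, !.data$masked),
                    ggplot2::aes(.data$x1, .data$x2, fill = .data$mean)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(direction = -1) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "U (kT)")
  }
}
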
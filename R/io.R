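#' Read and write trajectory CSV files
#'
#' Trajectories are exchanged as plain CSV with one row per time step and
#' header columns `t`, `y1`[, `y2`] (and `x1`[, `x2`] for the latent ground
#' truth when simulated).
#'
#' @param data Trajectory tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `data` invisibly; `read_trajectory()`
#'   returns a tibble.
#' @export
write_trajectory <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double()))
}

#' Write a potential summary (or Boltzmann estimate) as CSV
#'
#' @param summary A [summarize_potential()] or [boltzmann_estimate()] result
#'   (any data frame works).
#' @param path File path.
#' @export
write_potential_csv <- function(summary, path) {
  readr::write_csv(as_tibble(summary), path)
  invisible(summary)
}

#' Save / load the retained potential draws of a fit as CSV
#'
#' Row `i` holds retained draw `i`; columns are the inducing points, in the
#' row order of `fit$grid$locations`. The grid itself is written alongside
#' (same stem, `_grid.csv` suffix) so bands can be recomputed later without
#' the fit object.
#'
#' @param fit A `skipper_fit`.
#' @param path Path for the draws CSV.
#' @return Invisibly, the paths written.
#' @export
write_chain_csv <- function(fit, path) {
  stopifnot(inherits(fit, "skipper_fit"))
  scal <- fit$draws
  readr::write_csv(scal, sub("\\.csv$", "_scalars.csv", path))
  u <- as.data.frame(fit$u_draws)
  names(u) <- paste0("u", seq_len(ncol(u)))
  u <- dplyr::bind_cols(tibble(iteration = fit$kept_iterations), u)
  readr::write_csv(u, path)
  g <- as.data.frame(fit$grid$locations)
  names(g) <- paste0("x", seq_len(ncol(g)))
  gpath <- sub("\\.csv$", "_grid.csv", path)
  readr::write_csv(dplyr::bind_cols(g, tibble(h2 = fit$hyper$h2, ell = fit$hyper$ell)), gpath)
  invisible(c(path, gpath))
}

#' Summarize stored potential draws without the fit object
#'
#' Reads the CSVs written by [write_chain_csv()] and recomputes posterior
#' mean and credible bands on a user grid.
#'
#' @param path Draws CSV path (the `_grid.csv` companion must sit alongside).
#' @param eval_points Evaluation locations; defaults to the stored grid.
#' @param probs,align See [summarize_potential()].
#' @return A `potential_summary` tibble.
#' @export
summarize_chain_csv <- function(path, eval_points = NULL,
                                probs = c(0.05, 0.95),
                                align = c("none", "min")) {
  align <- match.arg(align)
  u <- as.matrix(read_trajectory(path)[, -1])
  gdf <- read_trajectory(sub("\\.csv$", "_grid.csv", path))
  hyper <- kernel_hyper(h2 = gdf$h2[1], ell = gdf$ell[1])
  loc <- as.matrix(gdf[grep("^x[0-9]+$", names(gdf))])
  D <- ncol(loc)
  grid <- structure(list(locations = loc, dims = D, M = nrow(loc),
                         m_per_dim = NA), class = "skipper_grid")
  core <- kernel_core(grid, hyper)
  fit <- structure(list(u_draws = u, grid = grid, hyper = hyper, core = core),
                   class = "skipper_fit")
  summarize_potential(fit, eval_points, probs = probs, align = align)
}
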
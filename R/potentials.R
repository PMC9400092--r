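#' Potential-energy functions
#'
#' A `skipper_potential` bundles an energy evaluator `U(x)` (kT), its force
#' field `f(x) = -grad U(x)` (kT/nm) and the dimensionality `D` (1 or 2).
#' Constructors are provided for the three benchmark landscape families:
#' a harmonic well, a symmetric quartic double well, and a 2D pixel-grid
#' potential composed of Gaussian wells.
#'
#' @param energy Function mapping an `n x D` matrix of positions (nm) to a
#'   length-`n` vector of energies (kT).
#' @param force Function mapping positions to an `n x D` matrix of forces.
#' @param dims Dimensionality, 1 or 2.
#' @param name Display label.
#' @param pars Named list of the defining parameters (kept for printing).
#' @return An object of class `skipper_potential`.
#' @name skipper_potential
NULL

new_potential <- function(energy, force, dims, name, pars = list()) {
  structure(list(energy = energy, force = force, dims = as.integer(dims),
                 name = name, pars = pars),
            class = "skipper_potential")
}

# coerce a point / vector of points to an n x D matrix
as_points <- function(x, dims) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (dims == 1L) x <- matrix(x, ncol = 1) else x <- matrix(x, ncol = dims, byrow = TRUE)
  }
  if (ncol(x) != dims)
    abort(sprintf("Positions must have %d column(s), got %d.", dims, ncol(x)))
  storage.mode(x) <- "double"
  x
}

#' @export
print.skipper_potential <- function(x, ...) {
  cat(sprintf("<skipper_potential> %s (%dD)\n", x$name, x$dims))
  if (length(x$pars))
    cat("  ", paste(names(x$pars), vapply(x$pars, function(p)
      paste(format(p), collapse = ","), ""), sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate a potential on a set of locations
#'
#' @param potential A [skipper_potential].
#' @param locations Numeric vector (1D), matrix, or data frame of positions in
#'   nm.
#' @return A tibble with the location columns (`x1`[, `x2`]) and `energy` (kT).
#' @examples
#' eval_potential(make_harmonic(0.005), seq(-30, 30, by = 10))
#' @export
eval_potential <- function(potential, locations) {
  pts <- as_points(locations, potential$dims)
  out <- as_tibble(as.data.frame(pts, col.names = paste0("x", seq_len(ncol(pts)))))
  names(out) <- paste0("x", seq_len(ncol(pts)))
  out$energy <- potential$energy(pts)
  out
}

#' Harmonic well
#'
#' `U(x) = stiffness/2 * |x - center|^2`, the standard optical-trap potential.
#'
#' @param stiffness Spring constant, kT/nm^2; must be positive. The
#'   equilibrium position variance in each dimension is `kT / stiffness`.
#' @param center Well centre (length gives the dimensionality).
#' @return A [skipper_potential].
#' @examples
#' pot <- make_harmonic(0.005)
#' pot$energy(matrix(20))   # 0.5 * 0.005 * 400 = 1 kT
#' @export
make_harmonic <- function(stiffness = 0.005, center = 0) {
  if (!is.numeric(stiffness) || length(stiffness) != 1 || stiffness <= 0)
    abort("`stiffness` must be a positive scalar.")
  dims <- length(center)
  if (!dims %in% 1:2) abort("`center` must have length 1 or 2.")
  ctr <- matrix(center, nrow = 1)
  new_potential(
    energy = function(x) {
      x <- as_points(x, dims)
      0.5 * stiffness * rowSums(sweep(x, 2, ctr, "-")^2)
    },
    force = function(x) {
      x <- as_points(x, dims)
      -stiffness * sweep(x, 2, ctr, "-")
    },
    dims = dims, name = "harmonic well",
    pars = list(stiffness = stiffness, center = center)
  )
}

#' Symmetric quartic double well
#'
#' `U(x) = barrier_height * ((x / half_separation)^2 - 1)^2`: minima at
#' `x = +/- half_separation` with `U = 0`, and a barrier of height
#' `barrier_height` at `x = 0`. Defaults reproduce the benchmark design of a
#' 10 kT barrier with wells at +/- 75 nm.
#'
#' @param barrier_height Barrier height at the origin, kT; positive.
#' @param half_separation Distance from the origin to each minimum, nm;
#'   positive.
#' @return A 1D [skipper_potential].
#' @examples
#' dw <- make_double_well()
#' dw$energy(matrix(0))  # 10 kT barrier top
#' @export
make_double_well <- function(barrier_height = 10, half_separation = 75) {
  if (!is.numeric(barrier_height) || length(barrier_height) != 1 || barrier_height <= 0)
    abort("`barrier_height` must be a positive scalar.")
  if (!is.numeric(half_separation) || length(half_separation) != 1 || half_separation <= 0)
    abort("`half_separation` must be a positive scalar.")
  b <- barrier_height; a <- half_separation
  new_potential(
    energy = function(x) {
      x <- as_points(x, 1L)
      b * ((x[, 1] / a)^2 - 1)^2
    },
    force = function(x) {
      x <- as_points(x, 1L)
      s <- x[, 1] / a
      matrix(-b * 4 * s * (s^2 - 1) / a, ncol = 1)
    },
    dims = 1L, name = "quartic double well",
    pars = list(barrier_height = b, half_separation = a)
  )
}

# 13 x 13 boolean masks for the pixel-grid face: TRUE marks face pixels;
# `features` marks the (deeper) eye and mouth pixels. Layout is illustrative;
# rows run top to bottom.
winky_masks <- function() {
  face <- matrix(FALSE, 13, 13)
  ctr <- 7
  for (i in 1:13) for (j in 1:13)
    if ((i - ctr)^2 + (j - ctr)^2 <= 36) face[i, j] <- TRUE
  features <- matrix(FALSE, 13, 13)
  features[4, 4:5] <- TRUE            # open left eye
  features[5, 4:5] <- TRUE
  features[5, 9:10] <- TRUE           # winking right eye (a dash)
  features[9, c(4, 10)] <- TRUE       # smile
  features[10, 5:9] <- TRUE
  features <- features & face
  list(face = face, features = features)
}

#' 2D pixel-grid "winky face" potential
#'
#' A 13 x 13 grid of Gaussian wells centred on pixel centres. Plain face
#' pixels share a common well depth; "eye" and "mouth" pixels are
#' `relief_depth` deeper, and the region outside the face stays at the
#' `background` level (>= 20 kT by default) so a simulated particle remains
#' inside the face. The composed potential is an analytic superposition of
#' Gaussians, hence smooth everywhere, with an analytic gradient. The pixel
#' layout itself is illustrative.
#'
#' @param pixel_width Pixel spacing, nm (default 10, giving a 130 nm face).
#' @param relief_depth Extra depth of feature pixels relative to the rest of
#'   the face, kT (default 2).
#' @param background Energy level far from any well, kT (default 25).
#' @param well_width Gaussian width of each pixel well, nm (default
#'   `0.6 * pixel_width`).
#' @param face_level Approximate energy of plain face pixels, kT (default 2).
#' @return A 2D [skipper_potential] carrying the pixel grid in `pars`.
#' @export
make_winky_face <- function(pixel_width = 10, relief_depth = 2,
                            background = 25, well_width = 0.6 * pixel_width,
                            face_level = 2) {
  if (!is.numeric(pixel_width) || length(pixel_width) != 1 || pixel_width <= 0)
    abort("`pixel_width` must be a positive scalar.")
  if (relief_depth < 0) abort("`relief_depth` must be non-negative.")
  masks <- winky_masks()
  depth <- matrix(0, 13, 13)
  depth[masks$face] <- background - face_level
  depth[masks$features] <- background - face_level + relief_depth
  # pixel centres, centred on the origin; x1 = column axis, x2 = row axis (up)
  offs <- (seq_len(13) - 7) * pixel_width
  centers <- cbind(x1 = rep(offs, each = 13), x2 = rep(-offs, times = 13))
  depths <- as.vector(depth)  # column-major matches rep(each)/rep(times) above
  keep <- depths > 0
  centers <- centers[keep, , drop = FALSE]
  depths <- depths[keep]
  w2 <- well_width^2
  new_potential(
    energy = function(x) {
      x <- as_points(x, 2L)
      d2 <- outer(x[, 1], centers[, 1], "-")^2 + outer(x[, 2], centers[, 2], "-")^2
      as.vector(background - exp(-d2 / (2 * w2)) %*% depths)
    },
    force = function(x) {
      x <- as_points(x, 2L)
      dx1 <- outer(x[, 1], centers[, 1], "-")
      dx2 <- outer(x[, 2], centers[, 2], "-")
      wgt <- exp(-(dx1^2 + dx2^2) / (2 * w2))
      # f = -dU/dx = -(sum_p depth_p * wgt_p * (x - c_p) / w2)
      cbind(-((wgt * dx1) %*% depths) / w2,
            -((wgt * dx2) %*% depths) / w2)
    },
    dims = 2L, name = "winky-face pixel grid",
    pars = list(pixel_values = depth, pixel_width = pixel_width,
                well_width = well_width, background = background,
                relief_depth = relief_depth, centers = centers)
  )
}

#' Tabulate a potential on a regular grid
#'
#' Convenience for plotting and CSV export: evaluates the potential on a
#' regular 1D sequence or 2D lattice.
#'
#' @param potential A [skipper_potential].
#' @param from,to Range per dimension (recycled across dimensions).
#' @param n Number of grid points per dimension.
#' @return A tibble with `x1`[, `x2`] and `energy`.
#' @export
potential_grid <- function(potential, from = -100, to = 100, n = 201) {
  D <- potential$dims
  from <- rep_len(from, D); to <- rep_len(to, D)
  axes <- lapply(seq_len(D), function(d) seq(from[d], to[d], length.out = n))
  pts <- as.matrix(expand.grid(axes))
  colnames(pts) <- paste0("x", seq_len(D))
  eval_potential(potential, pts)
}

#' Plot a potential
#'
#' @param object A [skipper_potential].
#' @param from,to,n Grid specification passed to [potential_grid()].
#' @param ... Unused.
#' @return A ggplot object (line in 1D, filled raster in 2D).
#' @export
autoplot.skipper_potential <- function(object, from = -100, to = 100, n = 201, ...) {
  df <- potential_grid(object, from, to, n)
  if (object$dims == 1L) {
    ggplot2::ggplot(df, ggplot2::aes(.data$x1, .data$energy)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "position (nm)", y = "U (kT)", title = object$name)
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$x1, .data$x2, fill = .data$energy)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(direction = -1) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "U (kT)", title = object$name)
  }
}
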
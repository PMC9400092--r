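#' Squared-exponential kernel
#'
#' `k(x, x') = h2 * exp(-|x - x'|^2 / (2 * ell^2))`: the smoothness prior used
#' for the potential. `x` and `xp` may be scalars (1D), length-D vectors
#' (a single D-dim point each), or `n x D` matrices; a full covariance matrix
#' is returned for matrix input.
#'
#' @param x,xp Positions (nm).
#' @param hyper A [kernel_hyper()].
#' @return Covariance value(s), kT^2.
#' @examples
#' se_kernel(0, 10, kernel_hyper(h2 = 25, ell = 10))  # 25 * exp(-1/2)
#' @export
se_kernel <- function(x, xp, hyper = kernel_hyper()) {
  dims <- if (is.matrix(x)) ncol(x) else length(x)
  a <- as_points(x, dims); b <- as_points(xp, dims)
  out <- cpp_se_kernel(a, b, hyper$h2, hyper$ell)
  if (length(out) == 1L) out[1, 1] else out
}

#' Inducing-point grid
#'
#' Fixed locations at which the potential is represented; everything else is
#' interpolated through the kernel. In 2D the grid is the Cartesian product of
#' the per-dimension sequences.
#'
#' @param lower,upper Numeric vectors (length = dimensionality) giving the
#'   grid extent in nm.
#' @param m Points per dimension (default 50 in 1D, 30 in 2D).
#' @return An object of class `skipper_grid` with a `locations` matrix
#'   (`M x D`), `m_per_dim` and `dims`.
#' @export
inducing_grid <- function(lower, upper, m = NULL) {
  D <- length(lower)
  if (length(upper) != D) abort("`lower` and `upper` must have equal length.")
  if (!D %in% 1:2) abort("Only 1D and 2D grids are supported.")
  if (any(upper <= lower)) abort("`upper` must exceed `lower` in every dimension.")
  if (is.null(m)) m <- if (D == 1L) 50L else 30L
  m <- rep_len(as.integer(m), D)
  if (any(m < 2L)) abort("Need at least 2 inducing points per dimension.")
  axes <- lapply(seq_len(D), function(d) seq(lower[d], upper[d], length.out = m[d]))
  loc <- as.matrix(expand.grid(axes))
  colnames(loc) <- paste0("x", seq_len(D))
  structure(list(locations = loc, m_per_dim = m, dims = D, M = nrow(loc)),
            class = "skipper_grid")
}

#' @export
print.skipper_grid <- function(x, ...) {
  cat(sprintf("<skipper_grid> %s inducing points (%dD), range %s\n",
              paste(x$m_per_dim, collapse = " x "), x$dims,
              paste(sprintf("[%g, %g]", apply(x$locations, 2, min),
                            apply(x$locations, 2, max)), collapse = " x ")))
  invisible(x)
}

#' Default inducing grid spanning observed data
#'
#' Spans the per-dimension data range widened by `margin` (default three
#' kernel length scales) on each side.
#'
#' @param y Matrix / data-frame of observed positions, or a list of them.
#' @param hyper A [kernel_hyper()] (sets the margin scale).
#' @param m Points per dimension; see [inducing_grid()].
#' @param margin Extra span beyond the data range, nm.
#' @return A `skipper_grid`.
#' @export
grid_from_data <- function(y, hyper = kernel_hyper(), m = NULL,
                           margin = 3 * hyper$ell) {
  if (is.list(y) && !is.data.frame(y)) y <- do.call(rbind, lapply(y, as.matrix))
  y <- as.matrix(y)
  inducing_grid(apply(y, 2, min) - margin, apply(y, 2, max) + margin, m = m)
}

# Factorize K once per (grid, hyper): adds jitter*h2 to the diagonal,
# escalating x10 from 1e-8 to 1e-4 before giving up.
kernel_core <- function(grid, hyper) {
  K0 <- cpp_se_kernel(grid$locations, grid$locations, hyper$h2, hyper$ell)
  jit <- 1e-8
  repeat {
    K <- K0 + diag(jit * hyper$h2, nrow(K0))
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (!is.null(ch)) break
    jit <- jit * 10
    if (jit > 1e-4)
      abort(paste("Inducing covariance could not be factorized even after",
                  "jitter escalation; increase `ell` or use fewer inducing points."),
            class = "skipper_numeric_error")
  }
  e <- new.env(parent = emptyenv())
  e$grid <- grid; e$hyper <- hyper; e$jitter <- jit
  e$K <- K; e$chol_K <- ch; e$Kinv <- chol2inv(ch)
  class(e) <- "skipper_kernel_core"
  e
}

#' Kernel matrices for a set of evaluation points
#'
#' Builds the full kernel machinery: the inducing covariance `K` (with its
#' cached Cholesky factor, computed once per grid and reused), the
#' cross-covariance `K_cross` between evaluation and inducing points, and the
#' derivative (force) cross-covariance `K_force`. `K_force` is stored in
#' flattened form: row `(i - 1) * D + d` is the covariance between the force
#' along dimension `d` at evaluation point `i` and the potential at the
#' inducing points (see [flatten_multidim()]).
#'
#' Pass the `core` of an existing kernel set to reuse its factorization when
#' only the evaluation points change (the intended pattern inside the Gibbs
#' sampler, where evaluation points move every sweep but the inducing grid is
#' static).
#'
#' @param grid A [inducing_grid()].
#' @param eval_points Evaluation locations: vector (1D) or `n x D` matrix.
#' @param hyper A [kernel_hyper()].
#' @param core Optional `skipper_kernel_core` to reuse.
#' @return An object of class `kernel_set`.
#' @export
build_kernel_set <- function(grid, eval_points, hyper = kernel_hyper(),
                             core = NULL) {
  pts <- as_points(eval_points, grid$dims)
  if (any(!is.finite(pts))) abort("`eval_points` must be finite.")
  if (is.null(core)) {
    core <- kernel_core(grid, hyper)
  } else {
    stopifnot(inherits(core, "skipper_kernel_core"))
  }
  structure(
    list(core = core, eval_points = pts,
         K_cross = cpp_se_kernel(pts, grid$locations, core$hyper$h2, core$hyper$ell),
         K_force = cpp_kstar_flat(pts, grid$locations, core$hyper$h2, core$hyper$ell)),
    class = "kernel_set"
  )
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("<kernel_set> M = %d inducing points, %d eval points (%dD), jitter %g\n",
              nrow(x$core$K), nrow(x$eval_points), x$core$grid$dims, x$core$jitter))
  invisible(x)
}

#' Interpolate the potential from inducing-point values
#'
#' `U(eval) = K_cross K^{-1} u`: the kernel interpolant through the potential
#' values `u` at the inducing points. Reproduces `u` exactly (up to jitter) at
#' the inducing points and reverts to the prior mean 0 far from all of them.
#'
#' @param u Length-M vector of potential values at the inducing points (kT).
#' @param kernels A [build_kernel_set()] built on the desired eval points.
#' @return Vector of energies at the evaluation points (kT).
#' @export
interpolate_potential <- function(u, kernels) {
  stopifnot(length(u) == nrow(kernels$core$K))
  as.vector(kernels$K_cross %*% (kernels$core$Kinv %*% u))
}

#' Interpolate the force field from inducing-point potential values
#'
#' `f_k(eval) = K_force^{(k)} K^{-1} u`, the exact derivative of the kernel
#' interpolant; equal to minus the gradient of [interpolate_potential()].
#'
#' @inheritParams interpolate_potential
#' @param dim Dimension index to extract, or `NULL` (default) for an
#'   `n x D` matrix of all components.
#' @return Vector (if `dim` given) or matrix of forces (kT/nm).
#' @export
interpolate_force <- function(u, kernels, dim = NULL) {
  stopifnot(length(u) == nrow(kernels$core$K))
  D <- kernels$core$grid$dims
  f <- kernels$K_force %*% (kernels$core$Kinv %*% u)
  f <- unflatten_multidim(as.vector(f), D)
  if (is.null(dim)) f else f[, dim]
}

#' Flatten multi-dimensional per-time arrays
#'
#' Packs an `N x D` array (rows = time levels, columns = dimensions) into a
#' length `N * D` vector with dimension running fastest: elements
#' `(n-1) * D + 1 .. (n-1) * D + D` hold time level `n`. The force
#' cross-covariance rows produced by [build_kernel_set()] follow the same
#' order, so the one-dimensional conditional algebra applies unchanged to
#' multi-dimensional trajectories. `unflatten_multidim()` inverts it.
#'
#' @param values An `N x D` numeric matrix (a plain vector is treated as
#'   `D = 1` and returned unchanged).
#' @return A numeric vector of length `N * D`.
#' @export
flatten_multidim <- function(values) {
  if (is.null(dim(values))) return(as.numeric(values))
  as.vector(t(values))
}

#' @rdname flatten_multidim
#' @param v Flattened vector.
#' @param dims Number of dimensions `D`.
#' @export
unflatten_multidim <- function(v, dims) {
  if (length(v) %% dims != 0)
    abort("Length of `v` is not a multiple of `dims`.")
  matrix(v, ncol = dims, byrow = TRUE)
}

# draw n samples u ~ N(0, K) on the inducing grid (test / prior-predictive use)
draw_potential_prior <- function(core, n = 1) {
  z <- matrix(rnorm(n * nrow(core$K)), nrow = nrow(core$K))
  t(core$chol_K) %*% z
}
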
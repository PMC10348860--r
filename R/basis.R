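# Penalized B-spline (P-spline) basis: cubic B-splines on equally spaced
# knots with a second-order difference penalty on the coefficients. The basis
# columns are centred on the observation times so the smooth carries no
# intercept; the penalty null space that remains (linear-in-time) is handled
# by an explicit linear term in the trend model.

#' Build a P-spline design and penalty
#'
#' Cubic B-spline basis on `basis_dim` equally spaced knots spanning
#' `range(ref_times)`, with a second-difference penalty matrix. Columns are
#' centred (column means over `ref_times` subtracted), which removes the
#' constant direction of the penalty null space from the fitted values.
#'
#' @param times Evaluation times.
#' @param basis_dim Number of basis functions (>= 4 for cubic splines; must
#'   not exceed the number of distinct `ref_times`).
#' @param degree Spline degree (default 3, cubic).
#' @param ref_times Times defining the knot span and the centring (default
#'   `times`). Evaluation outside `range(ref_times)` is an error.
#' @return An object of class `spline_basis`: list with `X` (centred design at
#'   `times`), `K` (penalty matrix, `t(D2) %*% D2`), `knots`, `degree`,
#'   `center` (subtracted column means) and `ref_range`.
#' @export
build_spline_basis <- function(times, basis_dim = 8L, degree = 3L,
                               ref_times = times) {
  if (basis_dim < degree + 1L) {
    .stopf("`basis_dim` must be at least degree + 1 = %d", degree + 1L)
  }
  nref <- length(unique(ref_times))
  if (basis_dim > nref) {
    .stopf("`basis_dim` (%d) exceeds the number of distinct times (%d)",
           basis_dim, nref)
  }
  rng <- range(ref_times)
  if (any(times < rng[1L] - 1e-9) || any(times > rng[2L] + 1e-9)) {
    .stopf("evaluation times outside the reference range [%g, %g]",
           rng[1L], rng[2L])
  }
  nseg <- basis_dim - degree
  dx <- diff(rng) / nseg
  knots <- seq(rng[1L] - degree * dx, rng[2L] + degree * dx, by = dx)
  X <- splines::splineDesign(knots, .clamp(times, rng[1L], rng[2L]),
                             ord = degree + 1L)
  center <- colMeans(splines::splineDesign(knots, ref_times, ord = degree + 1L))
  X <- sweep(X, 2L, center)
  D <- diff(diag(basis_dim), differences = 2L)
  structure(
    list(X = X, K = crossprod(D), knots = knots, degree = degree,
         basis_dim = basis_dim, center = center, ref_range = rng),
    class = "spline_basis"
  )
}

#' Evaluate a `spline_basis` at new times
#'
#' Returns the centred design matrix of [build_spline_basis()] evaluated at
#' `times` (which must lie within the reference range).
#'
#' @param basis A `spline_basis`.
#' @param times Evaluation times.
#' @return Matrix with `length(times)` rows and `basis_dim` columns.
#' @export
spline_basis_eval <- function(basis, times) {
  rng <- basis$ref_range
  if (any(times < rng[1L] - 1e-9) || any(times > rng[2L] + 1e-9)) {
    .stopf("evaluation times outside the reference range [%g, %g]",
           rng[1L], rng[2L])
  }
  X <- splines::splineDesign(basis$knots, .clamp(times, rng[1L], rng[2L]),
                             ord = basis$degree + 1L)
  sweep(X, 2L, basis$center)
}

# Mixed-model reparameterization of the penalty: eigenvectors of K with
# positive eigenvalues, scaled so the implied prior on the transformed
# coefficients is iid N(0, tau^2). Returns the (basis_dim x (basis_dim - 2))
# transform; the 2-dim null space (constant, linear) is excluded -- constant
# is annihilated by centring, linear is modelled explicitly.
.penalty_transform <- function(K) {
  eg <- eigen(K, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  eg$vectors[, pos, drop = FALSE] %*% diag(1 / sqrt(eg$values[pos]),
                                           nrow = sum(pos))
}
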
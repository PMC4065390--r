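# Penalized spline bases. Two kinds:
#   * cubic_ps    -- cubic B-splines on an equally spaced knot grid with a
#                    second-order difference penalty (the default: sparse,
#                    banded, fast at tens of thousands of days);
#   * thin_plate  -- reduced-rank thin-plate regression splines (1-D, m = 2):
#                    eigen-truncated radial basis r^3/12 over representative
#                    centers, with the polynomial null space {1, x} explicit.
# Both expose: an evaluation matrix at arbitrary x in [0,1], a positive
# semi-definite penalty whose null space contains the linear functions, and
# the index of the column that carries the constant (needed to absorb the
# sum-to-zero identifiability constraint).

#' @keywords internal
#' @noRd
make_smooth_basis <- function(kind, q, x) {
  switch(kind,
    cubic_ps = basis_cubic_ps(q),
    thin_plate = basis_thin_plate(q, x),
    bg_abort(paste0("Unknown basis kind: ", kind), "birthgam_config_error")
  )
}

# Cubic B-splines: q basis functions require q - 3 interior segments on [0,1]
# plus 3 exterior knots each side. Partition of unity holds on [0,1], so the
# coefficient vector 1 reproduces the constant function.
basis_cubic_ps <- function(q) {
  if (q < 4) bg_abort("Cubic basis needs rank >= 4.", "birthgam_config_error")
  nseg <- q - 3L
  h <- 1 / nseg
  knots <- seq(-3 * h, 1 + 3 * h, by = h)
  D <- diff(diag(q), differences = 2)
  structure(
    list(kind = "cubic_ps", q = q, knots = knots,
         penalty = crossprod(D),
         const_col = NA_integer_),   # constant is spread over all columns
    class = "birthgam_basis"
  )
}

# Reduced-rank thin-plate regression spline (Wood-style): radial part
# eta(r) = r^3/12 evaluated against K representative centers, truncated to its
# leading q - 2 eigen-directions, constrained orthogonal to the polynomial
# null space, which is appended explicitly as [1, x].
basis_thin_plate <- function(q, x, max_centers = 500L) {
  if (q < 4) bg_abort("Thin-plate basis needs rank >= 4.",
                      "birthgam_config_error")
  ux <- sort(unique(x))
  K <- min(length(ux), max(2L * q, 100L), max_centers)
  if (K < q) bg_abort("Too few unique covariate values for requested rank.",
                      "birthgam_config_error")
  centers <- if (length(ux) == K) ux else
    ux[unique(round(seq(1, length(ux), length.out = K)))]
  K <- length(centers)
  E <- tp_eta(abs(outer(centers, centers, "-")))
  eg <- eigen(E, symmetric = TRUE)
  # q eigen-directions lose two to the side constraint, leaving q - 2 radial
  # columns; the polynomial null space [1, x] brings the total back to q
  ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(q)]
  U <- eg$vectors[, ord, drop = FALSE]
  D <- eg$values[ord]
  # absorb the thin-plate side constraint T' delta = 0, T = [1, centers]
  Tm <- cbind(1, centers)
  Z <- qr.Q(qr(crossprod(U, Tm)), complete = TRUE)[, -(1:2), drop = FALSE]
  M <- U %*% Z                              # K x (q - 2): delta = M z
  S_rad <- crossprod(Z, Z * D)              # Z' diag(D) Z
  S_rad <- (S_rad + t(S_rad)) / 2
  # eta is only conditionally positive definite; truncation can leave tiny
  # negative penalty eigenvalues, so project onto the PSD cone
  es <- eigen(S_rad, symmetric = TRUE)
  S_rad <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
  penalty <- matrix(0, q, q)
  penalty[seq_len(q - 2L), seq_len(q - 2L)] <- (S_rad + t(S_rad)) / 2
  structure(
    list(kind = "thin_plate", q = q, centers = centers, M = M,
         penalty = penalty,
         const_col = q - 1L),               # layout: [radial..., 1, x]
    class = "birthgam_basis"
  )
}

tp_eta <- function(r) r^3 / 12

#' Evaluate a smooth basis at covariate values
#'
#' @param basis A basis object from the fitted design.
#' @param x Numeric values on the normalized day index scale `[0, 1]`.
#' @param sparse Return a sparse matrix where the basis supports it.
#' @return An `n x q` matrix of basis function values.
#' @keywords internal
#' @noRd
eval_basis <- function(basis, x, sparse = TRUE) {
  if (basis$kind == "cubic_ps") {
    splines::splineDesign(basis$knots, x, ord = 4, outer.ok = TRUE,
                          sparse = sparse)
  } else {
    Ef <- tp_eta(abs(outer(x, basis$centers, "-")))
    cbind(Ef %*% basis$M, 1, x)
  }
}

# Absorb the sum-to-zero constraint of the trend smooth while keeping the
# design sparse: remove the constant direction (for B-splines, dropping one
# column suffices because the remaining columns plus the intercept still span
# the space and the difference penalty is invariant to constant shifts; for
# thin-plate, drop the explicit constant column), then column-center. The
# centering is carried as a rank-one correction vector u so the stored matrix
# stays sparse: X_constrained = X_kept - 1 u'.
absorb_constraint <- function(basis, X) {
  drop_col <- if (is.na(basis$const_col)) basis$q else basis$const_col
  keep <- setdiff(seq_len(basis$q), drop_col)
  Xk <- X[, keep, drop = FALSE]
  u <- as.numeric(Matrix::colMeans(Xk))
  list(X = Xk, u = u, keep = keep,
       penalty = basis$penalty[keep, keep, drop = FALSE])
}
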
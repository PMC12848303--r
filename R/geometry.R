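# Vector frames and scalarization.
#
# A local right-handed orthonormal basis ("vector frame") is attached to
# pieces of molecular geometry; projecting geometric vectors onto it turns
# rotation-equivariant quantities into rotation-invariant scalars. Frames are
# built at three granularities: ligand atom pairs, protein backbone triads
# (N, C-alpha, C), and consecutive pocket residues.

#' Tolerance below which a vector is treated as degenerate (zero) when
#' normalizing, in Angstrom. Well below atomic-coordinate noise.
#' @noRd
EPS_NORM <- 1e-8

stop_neuralmd <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "neuralmd_error")))
}

#' Normalize a 3-vector to unit length
#'
#' @param v numeric length-3 vector.
#' @return the unit vector `v / ||v||`.
#' @details Signals a condition of class `degenerate_vector` when
#'   `||v|| <= 1e-8`, the package-wide degeneracy threshold.
#' @export
#' @examples
#' normalize_vec(c(3, 0, 0))
normalize_vec <- function(v) {
  stopifnot(length(v) == 3L)
  n <- sqrt(sum(v^2))
  if (!is.finite(n) || n <= EPS_NORM) {
    stop_neuralmd("cannot normalize a (near-)zero vector", "degenerate_vector")
  }
  v / n
}

new_frame <- function(e1, e2, e3) {
  structure(list(e1 = e1, e2 = e2, e3 = e3), class = "orthonormal_frame")
}

#' @export
print.orthonormal_frame <- function(x, ...) {
  cat("<orthonormal_frame>\n")
  m <- rbind(e1 = x$e1, e2 = x$e2, e3 = x$e3)
  colnames(m) <- c("x", "y", "z")
  print(round(m, 6))
  invisible(x)
}

#' Build a vector frame from a pair of points
#'
#' Gram-Schmidt frame spanned by a pair of positions: `e1` along the
#' difference `x_i - x_j`, `e2` along the cross product of the two positions
#' after centering on `center`, and `e3 = e1 x e2`. Used for ligand atom
#' pairs (centered on the ligand centroid) and for consecutive pocket
#' residues (centered on the pocket centroid); the centering makes the
#' cross-product axis translation invariant. Since `(a - b)` is orthogonal
#' to `(a x b)`, the result is orthonormal by construction.
#'
#' @param x_i,x_j positions of the pair, length-3, Angstrom.
#' @param center centering point subtracted before the cross product
#'   (default the pair's containing-set centroid should be supplied;
#'   falls back to the origin).
#' @return an `orthonormal_frame` with unit, mutually orthogonal,
#'   right-handed axes `e1`, `e2`, `e3`.
#' @details Degenerate inputs (coincident points, or centered positions
#'   parallel so the cross product vanishes) signal `degenerate_vector`.
#' @export
#' @examples
#' build_pair_frame(c(2, 0, 0), c(0, 2, 0), center = c(0, 0, 0))
build_pair_frame <- function(x_i, x_j, center = c(0, 0, 0)) {
  a <- x_i - center
  b <- x_j - center
  e1 <- normalize_vec(x_i - x_j)
  e2 <- normalize_vec(cross3(a, b))
  e3 <- cross3(e1, e2)
  new_frame(e1, e2, e3)
}

#' Build a backbone vector frame for one residue
#'
#' Frame from the N, C-alpha, C backbone triad: `e1` along `x_N - x_Ca`,
#' `e2` along `x_Ca - x_C` orthogonalized against `e1` (Gram-Schmidt),
#' `e3 = e1 x e2`. The two bond directions are generally not orthogonal
#' (the backbone N-Ca-C angle is ~111 degrees), so the second axis is
#' explicitly orthogonalized to honour the orthonormal-frame contract.
#'
#' @param x_n,x_ca,x_c backbone atom positions, length-3, Angstrom.
#' @return an `orthonormal_frame`.
#' @details Coincident or colinear backbone atoms signal `degenerate_vector`.
#' @export
build_backbone_frame <- function(x_n, x_ca, x_c) {
  e1 <- normalize_vec(x_n - x_ca)
  u2 <- normalize_vec(x_ca - x_c)
  u2 <- u2 - sum(u2 * e1) * e1
  e2 <- normalize_vec(u2)
  e3 <- cross3(e1, e2)
  new_frame(e1, e2, e3)
}

#' Project a vector onto a frame (scalarization)
#'
#' Returns the three coefficients of `v` in the frame basis,
#' `(v . e1, v . e2, v . e3)`. When `v` and the frame's generating
#' coordinates rotate together the output is unchanged, which is the
#' mechanism the force network uses to obtain rotation-invariant features.
#'
#' @param v numeric length-3 vector.
#' @param frame an `orthonormal_frame`.
#' @return numeric length-3 vector of projections.
#' @export
scalarize <- function(v, frame) {
  stopifnot(inherits(frame, "orthonormal_frame"), length(v) == 3L)
  c(sum(v * frame$e1), sum(v * frame$e2), sum(v * frame$e3))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# random rotation matrix (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
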
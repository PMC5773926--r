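# Superposition RMSD kernels.  qcp_rmsd() is the production kernel (compiled
# QCP); kabsch_rmsd() is a deliberately independent SVD implementation kept as
# the cross-validation oracle.

check_point_set <- function(m, arg = "a") {
  if (!is.matrix(m) || !is.numeric(m) || ncol(m) != 3L)
    fp_data_error("%s must be a numeric N x 3 coordinate matrix", arg)
  if (nrow(m) < 3L)
    fp_data_error(
      "%s has %d points; superposition is underdetermined below 3", arg, nrow(m))
  if (!all(is.finite(m)))
    fp_data_error("%s contains non-finite coordinates", arg)
  invisible(m)
}

#' Superposition RMSD via the QCP method
#'
#' Minimum root-mean-square deviation over all proper rigid-body
#' superpositions (rotation + translation, no reflection) of `b` onto `a`.
#' Atom correspondence is positional: row i of `a` pairs with row i of `b`.
#' Computed with the quaternion characteristic polynomial (QCP) method, which
#' obtains the optimal-superposition RMSD from the largest eigenvalue of a
#' 4x4 key matrix without building the rotation.
#'
#' @param a,b numeric N x 3 coordinate matrices (Angstrom), N >= 3.
#' @return Non-negative RMSD in Angstrom.
#' @seealso [kabsch_rmsd()] for the independent SVD-based oracle.
#' @examples
#' a <- matrix(rnorm(36), ncol = 3)
#' qcp_rmsd(a, a)  # 0
#' @export
qcp_rmsd <- function(a, b) {
  check_point_set(a, "a")
  check_point_set(b, "b")
  if (nrow(a) != nrow(b))
    fp_data_error("incompatible fragments: %d vs %d points", nrow(a), nrow(b))
  qcp_rmsd_cpp(a, b)
}

#' Superposition RMSD via the Kabsch algorithm
#'
#' Same quantity as [qcp_rmsd()], computed by an independent route: centering,
#' SVD of the 3x3 covariance matrix, reflection correction by the determinant
#' sign, explicit rotation and direct deviation measurement.  Exists for
#' cross-validation of the QCP kernel; prefer [qcp_rmsd()] in production code.
#'
#' @inheritParams qcp_rmsd
#' @return Non-negative RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  check_point_set(a, "a")
  check_point_set(b, "b")
  if (nrow(a) != nrow(b))
    fp_data_error("incompatible fragments: %d vs %d points", nrow(a), nrow(b))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(bc, ac))         # H = b^T a; rotation maps b onto a
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1                  # degenerate (planar) covariance
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  dev <- ac - bc %*% t(rot)
  sqrt(max(0, sum(dev^2) / nrow(a)))
}

# Flatten a list of N x 3 matrices into the pool layout the compiled
# one-vs-many kernel expects (row per set, x1,y1,z1,...,xN,yN,zN).
coords_pool_matrix <- function(coord_list) {
  n <- length(coord_list)
  if (n == 0L) return(matrix(numeric(0), nrow = 0, ncol = 0))
  np <- nrow(coord_list[[1L]])
  out <- matrix(0, nrow = n, ncol = 3L * np)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(coord_list[[i]]))
  out
}

# One query against many coordinate sets; returns a numeric vector of RMSDs.
qcp_rmsd_one_vs_many <- function(query_coords, pool_matrix) {
  if (nrow(pool_matrix) == 0L) return(numeric(0))
  qcp_rmsd_many_cpp(query_coords, pool_matrix)
}
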
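#' @useDynLib sitematch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Exact geometric kernel: measurements, internal <-> Cartesian conversion and
# least-squares superposition.  All angles are degrees, all lengths Angstrom.

.as_point <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop("a point must be a finite 3-vector", call. = FALSE)
  p
}

#' Wrap an angle into (-180, 180]
#'
#' Centralized periodic arithmetic: all dihedral comparisons in the package go
#' through this function.
#'
#' @param x angle(s) in degrees.
#' @return wrapped angle(s) in degrees, in `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

#' Geometric measurements on 2-4 points
#'
#' Computes an interatomic distance, a bond angle or a torsion (dihedral)
#' angle.  Dihedrals follow the IUPAC sign convention: looking from the second
#' down the axis to the third point, a clockwise rotation of the far bond is
#' positive; values lie in `(-180, 180]`.
#'
#' @param kind one of `"distance"`, `"angle"`, `"dihedral"`.
#' @param ... two, three or four coordinate 3-vectors (or a single matrix with
#'   the points as rows).
#' @return distance in Angstrom, or angle in degrees.
#' @examples
#' measure("distance", c(0, 0, 0), c(3, 4, 0))  # 5
#' measure("angle", c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
measure <- function(kind = c("distance", "angle", "dihedral"), ...) {
  kind <- match.arg(kind)
  pts <- list(...)
  if (length(pts) == 1L && is.matrix(pts[[1L]]))
    pts <- lapply(seq_len(nrow(pts[[1L]])), function(i) pts[[1L]][i, ])
  pts <- lapply(pts, .as_point)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L)[[kind]]
  if (length(pts) != need)
    stop(sprintf("'%s' needs %d points, got %d", kind, need, length(pts)),
         call. = FALSE)
  switch(kind,
    distance = sqrt(sum((pts[[1L]] - pts[[2L]])^2)),
    angle = {
      u <- pts[[1L]] - pts[[2L]]
      v <- pts[[3L]] - pts[[2L]]
      nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
      if (nu == 0 || nv == 0)
        stop("degenerate geometry: coincident points in angle", call. = FALSE)
      acos(max(-1, min(1, sum(u * v) / (nu * nv)))) * 180 / pi
    },
    dihedral = {
      b1 <- pts[[2L]] - pts[[1L]]
      b2 <- pts[[3L]] - pts[[2L]]
      b3 <- pts[[4L]] - pts[[3L]]
      n1 <- .cross3(b1, b2)
      n2 <- .cross3(b2, b3)
      if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
        stop("degenerate geometry: collinear points in dihedral", call. = FALSE)
      nb2 <- sqrt(sum(b2^2))
      ang <- atan2(sum(.cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
      wrap_angle(ang)
    })
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Place a point from internal coordinates
#'
#' NeRF-style placement: given three reference points `a`, `b`, `c`, places a
#' point `d` such that `|d - c| = length`, `angle(b, c, d) = angle` and
#' `dihedral(a, b, c, d) = torsion`, each to better than 1e-9 on its unit.
#'
#' @param a,b,c reference coordinate 3-vectors (must not be collinear).
#' @param length bond length in Angstrom (> 0).
#' @param angle bond angle in degrees, open interval (0, 180).
#' @param torsion torsion in degrees.
#' @return coordinate 3-vector of the placed point.
#' @export
internal_to_cartesian <- function(a, b, c, length, angle, torsion) {
  a <- .as_point(a); b <- .as_point(b); c <- .as_point(c)
  if (length <= 0) stop("bond length must be > 0", call. = FALSE)
  if (angle <= 0 || angle >= 180)
    stop("bond angle must lie in the open interval (0, 180) degrees", call. = FALSE)
  if (sum(.cross3(b - a, c - b)^2) < 1e-20)
    stop("reference points a, b, c are collinear", call. = FALSE)
  zm <- matrix(c(1, 2, 3, length, angle, torsion), nrow = 1)
  out <- chain_place_cpp(rbind(a, b, c), zm, numeric(0), numeric(0), numeric(0))
  out[4L, ]
}

#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the rigid transform (proper rotation + translation) minimizing the
#' RMSD between `mobile` and `target`, with correspondence given by row order.
#'
#' @param mobile,target numeric matrices (n x 3) with matching rows.
#' @return a list with elements `rmsd` (Angstrom, after fitting), `rotation`
#'   (3 x 3, det +1), `translation` (3-vector; the fit is
#'   `mobile %*% t(rotation) + translation`).
#' @seealso [rmsd_nofit()] for the direct, unfitted RMSD used when comparing a
#'   matched transition-state pose against its crystal reference.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3L || nrow(mobile) < 1L)
    stop("mobile and target must be matching n x 3 matrices", call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(ct - (R %*% cm)))
}

#' Apply a rigid transform returned by [superpose()]
#' @param xyz n x 3 coordinate matrix.
#' @param fit list with `rotation` and `translation`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Direct (no-fit) RMSD
#'
#' RMSD between two coordinate sets in their current frames, without
#' superposition.  This is the comparison used for matched transition states
#' against their reference pose: the match must place the ligand where the
#' reference has it, so translation is not factored out.
#'
#' @param a,b numeric matrices (n x 3) with matching rows.
#' @return RMSD in Angstrom.
#' @export
rmsd_nofit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)))
    stop("coordinate sets must have identical dimensions", call. = FALSE)
  sqrt(mean(rowSums((a - b)^2)))
}
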
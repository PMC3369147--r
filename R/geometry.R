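#' @keywords internal
"_PACKAGE"

#' @importFrom stats splinefun lm coef pt qt aov anova sd cor median mad
#'   rnorm runif setNames t.test complete.cases
#' @importFrom utils head tail write.csv
NULL

## ---- small vector helpers (3D rows) ----------------------------------------

vnorm <- function(x) sqrt(sum(x^2))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  x / n
}

## cross product of two 3-vectors, or row-wise for matrices
cross3 <- function(a, b) {
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a)) a <- matrix(a, nrow(b), 3, byrow = TRUE)
    if (!is.matrix(b)) b <- matrix(b, nrow(a), 3, byrow = TRUE)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  } else {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
}

rownorms <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) m / pmax(rownorms(m), .Machine$double.xmin)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## rotation matrices about the anatomical axes (x lateral, y anterior,
## z superior; right-handed, angles in degrees)
rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}
rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
}
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

## plane as list(point =, normal =) with unit normal
new_plane <- function(point, normal) {
  list(point = as.numeric(point), normal = unitv(as.numeric(normal)))
}

plane_signed_distance <- function(plane, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  as.numeric((pts - matrix(plane$point, nrow(pts), 3, byrow = TRUE)) %*%
               plane$normal)
}

## ---- least-squares sphere / circle fits ------------------------------------

#' Fit a sphere to 3D points
#'
#' Algebraic least-squares fit (linear in center and radius) followed by a
#' few Gauss-Newton iterations on the geometric residuals
#' \eqn{\|p_i - c\| - R}.  Used to locate the geometric center of the
#' femoral head.
#'
#' @param points numeric matrix (n x 3) of points in mm, n >= 4 and not
#'   coplanar.
#' @return list with `center` (length-3), `radius`, and `rms_residual` (mm).
#' @examples
#' u <- matrix(rnorm(300), ncol = 3)
#' u <- u / sqrt(rowSums(u^2))
#' fit_sphere(25 * u + rep(c(1, 2, 3), each = 100))
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 4) stop("need at least 4 points to fit a sphere")
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) stop("points are coplanar or degenerate")
  fit_hypersphere(points)
}

#' Fit a circle to 2D points
#'
#' Algebraic least-squares fit refined geometrically; supplies the femoral
#' head center and radius used by the lateral center-edge angle and the
#' posterior wall distance.
#'
#' @param points numeric matrix (n x 2), n >= 3 and not collinear.
#' @return list with `center` (length-2), `radius`, `rms_residual`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 25)
#' fit_circle(cbind(10 + 25 * cos(th), 20 + 25 * sin(th)))
#' @export
fit_circle <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 3) stop("need at least 3 points to fit a circle")
  sv <- svd(sweep(points, 2, colMeans(points)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) stop("points are collinear")
  fit_hypersphere(points)
}

## shared algebraic + geometric fit in d dimensions
fit_hypersphere <- function(points) {
  d <- ncol(points)
  ## algebraic: |p|^2 = 2 p.c + (R^2 - |c|^2)
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sol <- qr.solve(A, b)
  center <- sol[seq_len(d)]
  radius <- sqrt(max(sol[d + 1] + sum(center^2), 0))
  ## Gauss-Newton on geometric residuals
  for (it in 1:20) {
    diff <- sweep(points, 2, center)
    r <- rownorms(diff)
    res <- r - radius
    J <- cbind(-diff / pmax(r, .Machine$double.eps), -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, d + 1))
    center <- center + step[seq_len(d)]
    radius <- radius + step[d + 1]
    if (max(abs(step)) < 1e-12 * max(radius, 1)) break
  }
  diff <- sweep(points, 2, center)
  res <- rownorms(diff) - radius
  list(center = as.numeric(center), radius = as.numeric(radius),
       rms_residual = sqrt(mean(res^2)))
}

## ---- least-squares plane fit ------------------------------------------------

## returns plane through the centroid with normal = smallest principal axis
fit_plane <- function(points) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  e <- eigen(crossprod(sweep(points, 2, ctr)), symmetric = TRUE)
  new_plane(ctr, e$vectors[, 3])
}
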
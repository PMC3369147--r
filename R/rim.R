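## Acetabular rim curves: an ordered closed sequence of 3D points with a
## periodic cubic spline through them (chord-length parameterisation).

#' Construct a rim curve from ordered 3D points
#'
#' Fits a closed periodic cubic spline (one per coordinate, chord-length
#' parameterised) through an ordered sequence of acetabular-rim points.
#'
#' @param points numeric matrix (n x 3), ordered around the rim, mm.  The
#'   first point must not be repeated at the end.
#' @return object of class `rim_curve` with elements `points`, `spline`
#'   (a function of t in `[0,1)`) and `samples` (default densification).
#' @export
rim_curve <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) >= 2 &&
      sqrt(sum((points[1, ] - points[nrow(points), ])^2)) < 1e-9)
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(points) < 8) stop("rim curve needs at least 8 control points")
  closed <- rbind(points, points[1, ])
  seg <- rownorms(diff(closed))
  if (any(seg < 1e-12)) stop("rim curve has coincident consecutive points")
  t <- c(0, cumsum(seg)) / sum(seg)
  fx <- splinefun(t, closed[, 1], method = "periodic")
  fy <- splinefun(t, closed[, 2], method = "periodic")
  fz <- splinefun(t, closed[, 3], method = "periodic")
  sp <- function(tt) {
    tt <- tt %% 1
    cbind(fx(tt), fy(tt), fz(tt))
  }
  structure(list(points = points, spline = sp,
                 samples = sp(seq(0, 1, length.out = 513)[-513])),
            class = "rim_curve")
}

#' @export
print.rim_curve <- function(x, ...) {
  cat(sprintf("<rim_curve> %d control points, centroid (%.1f, %.1f, %.1f) mm\n",
              nrow(x$points), mean(x$points[, 1]), mean(x$points[, 2]),
              mean(x$points[, 3])))
  invisible(x)
}

#' Sample a rim curve at n equally spaced parameter values
#' @param rim a `rim_curve`.
#' @param n number of samples.
#' @return n x 3 matrix of points on the spline.
#' @export
sample_rim <- function(rim, n = 512) {
  stopifnot(inherits(rim, "rim_curve"))
  rim$spline(seq(0, 1, length.out = n + 1)[-(n + 1)])
}
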
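## The six radiographic measures of acetabular morphology, computed from a
## named landmark set.  All measures are defined along/about the horizontal
## reference direction, with the lateral sign set by `side`, which makes
## them invariant under rigid in-plane transforms and left/right mirroring.

dot2 <- function(a, b) sum(a * b)

#' Extrusion index
#'
#' Fraction of the femoral head's horizontal diameter uncovered lateral to
#' the acetabulum: `a / (2 * radius)`, where `a` is the horizontal distance
#' from the lateral sourcil to the lateral edge of the head (clamped at 0
#' when the sourcil overhangs the head).
#'
#' @param lm a `radiograph_landmarks`.
#' @return ratio in `[0, 1]`.
#' @export
extrusion_index <- function(lm) {
  l <- lateral_dir(lm)
  head_edge <- dot2(lm$head_circle$center, l) + lm$head_circle$radius
  a <- max(0, head_edge - dot2(lm$lateral_sourcil, l))
  a / (2 * lm$head_circle$radius)
}

#' Lateral center-edge angle (degrees)
#'
#' Angle between the vertical through the femoral head center and the ray
#' from the center to the lateral sourcil; positive when the sourcil is
#' lateral to the vertical.
#'
#' @param lm a `radiograph_landmarks`.
#' @return degrees in `(-90, 90)`.
#' @export
lcea <- function(lm) {
  v <- lm$lateral_sourcil - lm$head_circle$center
  if (vnorm(v) < 1e-9) stop("lateral sourcil coincides with the head center")
  rad2deg(atan2(dot2(v, lateral_dir(lm)), dot2(v, superior_dir(lm))))
}

#' Acetabular index (degrees)
#'
#' Inclination of the sourcil: angle of the medial-to-lateral sourcil
#' segment relative to the horizontal reference, positive when the lateral
#' end is superior (up-sloping roof).
#'
#' @param lm a `radiograph_landmarks`.
#' @return degrees.
#' @export
acetabular_index <- function(lm) {
  v <- lm$lateral_sourcil - lm$medial_sourcil
  if (vnorm(v) < 1e-9) stop("sourcil endpoints coincide")
  rad2deg(atan2(dot2(v, superior_dir(lm)), abs(dot2(v, lateral_dir(lm)))))
}

#' Acetabular angle (degrees)
#'
#' Angle of the teardrop-to-lateral-sourcil line relative to the horizontal
#' reference, positive superiorly (the angle of Sharp).
#'
#' @param lm a `radiograph_landmarks`.
#' @return degrees.
#' @export
acetabular_angle <- function(lm) {
  v <- lm$lateral_sourcil - lm$teardrop
  if (vnorm(v) < 1e-9) stop("teardrop coincides with the lateral sourcil")
  rad2deg(atan2(dot2(v, superior_dir(lm)), abs(dot2(v, lateral_dir(lm)))))
}

#' Crossover ratio
#'
#' Locates the first transversal crossing of the anterior over the
#' posterior wall, sweeping along the anterior wall from the lateral rim
#' (sign change of the signed distance to the posterior wall).  Returns
#' `NA` when the walls do not cross (crossover sign negative); otherwise
#' the distance from the lateral rim to the crossover point divided by the
#' acetabular diameter (lateral rim to teardrop).
#'
#' @param lm a `radiograph_landmarks`.
#' @param tol transversality tolerance as a fraction of the acetabular
#'   diameter (default 0.5%): wall separations smaller than this never
#'   count as crossings, so walls sharing their endpoints, coincident
#'   symmetric walls, or sub-millimetre grazing contacts are not read as
#'   crossovers.
#' @return ratio in `[0, 1]`, or `NA` if no crossover.
#' @export
crossover_ratio <- function(lm, tol = 5e-3) {
  A <- lm$anterior_wall
  P <- lm$posterior_wall
  if (nrow(A) < 2 || nrow(P) < 2) stop("walls need at least 2 points")
  b <- vnorm(lm$lateral_rim - lm$teardrop)
  eps <- tol * b
  f <- signed_dist_to_polyline(A, P)
  ## exclude samples that (a) project onto the posterior wall's free
  ## endpoints, or (b) lie in the convergence zones where the two walls
  ## merge (first 4% / last 10% of the anterior wall's course): separations
  ## there reflect the shared wall origin, not a crossover
  arc <- c(0, cumsum(sqrt(rowSums(diff(A)^2))))
  arc <- arc / max(arc[length(arc)], .Machine$double.xmin)
  ok <- which(abs(f) > eps & !attr(f, "at_end") &
                arc >= 0.04 & arc <= 0.90)
  if (length(ok) < 2) return(NA_real_)
  s <- sign(f[ok])
  flip <- which(s[-length(s)] != s[-1])
  if (length(flip) == 0) return(NA_real_)
  i1 <- ok[flip[1]]; i2 <- ok[flip[1] + 1]
  ## interpolate the zero crossing along the anterior wall between i1..i2
  seg_f <- f[i1:i2]
  jz <- which(sign(seg_f[-length(seg_f)] * seg_f[-1]) <= 0)[1]
  a1 <- i1 + jz - 1; a2 <- a1 + 1
  w <- f[a1] / (f[a1] - f[a2])
  X <- A[a1, ] + w * (A[a2, ] - A[a1, ])
  vnorm(lm$lateral_rim - X) / b
}

## signed perpendicular distance of each point of polyline Q to polyline P
## (sign: which side of P's local tangent).  Attribute "at_end" flags
## queries whose nearest point is one of P's free endpoints.
signed_dist_to_polyline <- function(Q, P) {
  nP <- nrow(P)
  S1 <- P[-nP, , drop = FALSE]
  S2 <- P[-1, , drop = FALSE]
  E <- S2 - S1
  len2 <- pmax(rowSums(E^2), .Machine$double.xmin)
  at_end <- logical(nrow(Q))
  f <- vapply(seq_len(nrow(Q)), function(i) {
    q <- Q[i, ]
    t <- ((q[1] - S1[, 1]) * E[, 1] + (q[2] - S1[, 2]) * E[, 2]) / len2
    t <- pmin(pmax(t, 0), 1)
    X <- S1 + t * E
    d2 <- (q[1] - X[, 1])^2 + (q[2] - X[, 2])^2
    j <- which.min(d2)
    at_end[i] <<- (j == 1 && t[j] <= 0) || (j == nrow(S1) && t[j] >= 1)
    crossz <- E[j, 1] * (q[2] - S1[j, 2]) - E[j, 2] * (q[1] - S1[j, 1])
    sign(crossz) * sqrt(d2[j])
  }, numeric(1))
  attr(f, "at_end") <- at_end
  f
}

#' Posterior wall distance (mm, signed)
#'
#' Horizontal distance from the femoral head center to the posterior wall,
#' measured where the wall crosses the horizontal line through the center;
#' positive when the wall is lateral to the center, negative when medial.
#' With multiple crossings the most lateral is used.
#'
#' @param lm a `radiograph_landmarks`.
#' @return signed mm.
#' @export
posterior_wall_distance <- function(lm) {
  l <- lateral_dir(lm)
  s <- superior_dir(lm)
  c2 <- lm$head_circle$center
  P <- lm$posterior_wall
  h <- (P[, 1] - c2[1]) * s[1] + (P[, 2] - c2[2]) * s[2]  # height above line
  cross_idx <- which(h[-length(h)] * h[-1] <= 0 &
                       !(h[-length(h)] == 0 & h[-1] == 0))
  if (length(cross_idx) == 0)
    stop("posterior wall does not cross the horizontal through the head center")
  xs <- vapply(cross_idx, function(j) {
    w <- if (h[j] == h[j + 1]) 0.5 else h[j] / (h[j] - h[j + 1])
    X <- P[j, ] + w * (P[j + 1, ] - P[j, ])
    dot2(X - c2, l)
  }, numeric(1))
  max(xs)  # most lateral crossing
}

#' Obturator index and adequacy screen
#'
#' Ratio of the ipsilateral to contralateral obturator foramen widths; an
#' AP radiograph is adequate when the ratio lies in `[0.8, 1.2]`.
#'
#' @param lm a `radiograph_landmarks`.
#' @return list(ratio, pass).
#' @export
obturator_index <- function(lm) {
  if (lm$obturator_width_ipsi <= 0 || lm$obturator_width_contra <= 0)
    stop("obturator widths must be positive")
  ratio <- lm$obturator_width_ipsi / lm$obturator_width_contra
  list(ratio = ratio, pass = ratio >= 0.8 && ratio <= 1.2)
}

#' All radiographic measures as a one-row tibble
#'
#' @param lm a `radiograph_landmarks`.
#' @return tibble with `extrusion_index`, `crossover_ratio` (NA when no
#'   crossover), `acetabular_angle`, `acetabular_index`, `lcea`,
#'   `posterior_wall_distance`, `obturator_ratio`, `radiograph_adequate`.
#' @export
measure_radiograph <- function(lm) {
  stopifnot(inherits(lm, "radiograph_landmarks"))
  ob <- obturator_index(lm)
  tibble::tibble(
    extrusion_index = extrusion_index(lm),
    crossover_ratio = crossover_ratio(lm),
    acetabular_angle = acetabular_angle(lm),
    acetabular_index = acetabular_index(lm),
    lcea = lcea(lm),
    posterior_wall_distance = posterior_wall_distance(lm),
    obturator_ratio = ob$ratio,
    radiograph_adequate = ob$pass)
}

#' Write / read a landmark set as JSON
#' @param lm a `radiograph_landmarks`; `path` file path.
#' @return `path` invisibly (write); a `radiograph_landmarks` (read).
#' @export
write_landmarks_json <- function(lm, path) {
  x <- unclass(lm)
  x$anterior_wall <- unname(apply(lm$anterior_wall, 1, as.numeric,
                                  simplify = FALSE))
  x$posterior_wall <- unname(apply(lm$posterior_wall, 1, as.numeric,
                                   simplify = FALSE))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_wall <- function(w) {
    if (is.matrix(w)) w else matrix(unlist(w), ncol = 2, byrow = TRUE)
  }
  radiograph_landmarks(
    head_circle = list(center = x$head_circle$center,
                       radius = x$head_circle$radius),
    lateral_sourcil = x$lateral_sourcil, medial_sourcil = x$medial_sourcil,
    teardrop = x$teardrop, teardrop_contralateral = x$teardrop_contralateral,
    lateral_rim = x$lateral_rim,
    anterior_wall = as_wall(x$anterior_wall),
    posterior_wall = as_wall(x$posterior_wall),
    obturator_width_ipsi = x$obturator_width_ipsi,
    obturator_width_contra = x$obturator_width_contra,
    horizontal_ref = x$horizontal_ref, side = x$side)
}
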
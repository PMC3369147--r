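## Simulated AP-pelvis radiograph: orthographic projection of the hip onto
## the coronal plane after applying pelvic tilt/rotation, emitting the named
## landmark set the 2D measures consume.  Image coordinates are mm, with
## `horizontal_ref` along +u; for a right hip the lateral direction is -u
## (patient's right appears on the image left, as on a standard AP film).

#' Construct a named AP-radiograph landmark set
#'
#' @param head_circle list(center = 2D point, radius) of the projected
#'   femoral head, mm.
#' @param lateral_sourcil,medial_sourcil 2D points: lateral and medial ends
#'   of the sourcil (weight-bearing acetabular roof).
#' @param teardrop,teardrop_contralateral 2D points.
#' @param lateral_rim 2D point: most lateral point of the projected rim.
#' @param anterior_wall,posterior_wall polylines (m x 2), ordered from the
#'   lateral rim medially.
#' @param obturator_width_ipsi,obturator_width_contra largest horizontal
#'   widths of the obturator foramina, mm.
#' @param horizontal_ref unit 2D direction of the pelvic horizontal.
#' @param side `"left"` or `"right"`.
#' @return object of class `radiograph_landmarks`.
#' @export
radiograph_landmarks <- function(head_circle, lateral_sourcil, medial_sourcil,
                                 teardrop, teardrop_contralateral,
                                 lateral_rim, anterior_wall, posterior_wall,
                                 obturator_width_ipsi, obturator_width_contra,
                                 horizontal_ref = c(1, 0),
                                 side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(head_circle$radius > 0,
            nrow(anterior_wall) >= 2, nrow(posterior_wall) >= 2)
  structure(list(
    head_circle = list(center = as.numeric(head_circle$center),
                       radius = head_circle$radius),
    lateral_sourcil = as.numeric(lateral_sourcil),
    medial_sourcil = as.numeric(medial_sourcil),
    teardrop = as.numeric(teardrop),
    teardrop_contralateral = as.numeric(teardrop_contralateral),
    lateral_rim = as.numeric(lateral_rim),
    anterior_wall = as.matrix(anterior_wall),
    posterior_wall = as.matrix(posterior_wall),
    obturator_width_ipsi = obturator_width_ipsi,
    obturator_width_contra = obturator_width_contra,
    horizontal_ref = unitv(as.numeric(horizontal_ref)),
    side = side), class = "radiograph_landmarks")
}

#' @export
print.radiograph_landmarks <- function(x, ...) {
  cat(sprintf("<radiograph_landmarks> %s hip, head r %.1f mm, walls %d/%d pts\n",
              x$side, x$head_circle$radius, nrow(x$anterior_wall),
              nrow(x$posterior_wall)))
  invisible(x)
}

## image-frame helpers.  The lateral and superior directions are derived
## from the landmarks themselves, which makes every measure invariant under
## mirroring and rigid transforms regardless of sign conventions:
## medial points from the ipsilateral toward the contralateral teardrop
## (along the horizontal reference line), and superior is the perpendicular
## on the sourcil side of the teardrop.
lateral_dir <- function(lm) {
  h <- lm$horizontal_ref
  med <- sum((lm$teardrop_contralateral - lm$teardrop) * h)
  if (abs(med) < 1e-12)
    stop("teardrops do not separate along the horizontal reference")
  -sign(med) * h
}
superior_dir <- function(lm) {
  l <- lateral_dir(lm)
  p <- c(-l[2], l[1])
  up <- sum((lm$lateral_sourcil - lm$teardrop) * p)
  if (abs(up) < 1e-12)  # sourcil level with the teardrop: use the head center
    up <- sum((lm$head_circle$center - lm$teardrop) * p)
  if (abs(up) < 1e-12)
    stop("cannot orient the superior direction from these landmarks")
  sign(up) * p
}

#' Project a hip onto a simulated AP radiograph
#'
#' Applies pelvic tilt (about the lateral axis) and rotation (about the
#' superior axis) around the head center, projects orthographically onto
#' the coronal plane, and derives the landmark set: the head circle, the
#' anterior and posterior wall polylines (the projected rim split at its
#' most lateral and most medial points, classified by 3D anterior
#' coordinate), sourcil ends, teardrops, obturator widths and the
#' horizontal reference (inter-teardrop direction).
#'
#' @param mesh femur `surface_mesh`, or `NULL` when `head_sphere` is given.
#' @param rim acetabular `rim_curve`.
#' @param pelvic_tilt,pelvic_rotation degrees, within +/-30.
#' @param head_sphere optional list(center, radius); estimated from the
#'   mesh when `NULL`.
#' @param n_wall_samples rim samples used to trace the walls.
#' @param interteardrop inter-teardrop distance used to place the
#'   contralateral teardrop, mm.
#' @param obturator_base baseline obturator foramen width, mm.
#' @param fossa_angle_deg,fossa_radius_frac synthetic medial-sourcil
#'   convention: the medial end of the weight-bearing roof sits at this
#'   angle medial of the vertical through the head center, at this fraction
#'   of the cup radius (the subchondral roof is deeper than the rim at the
#'   acetabular fossa edge).
#' @return a `radiograph_landmarks` (side `"right"`).
#' @export
project_to_radiograph <- function(mesh, rim, pelvic_tilt = 0,
                                  pelvic_rotation = 0, head_sphere = NULL,
                                  n_wall_samples = 192,
                                  interteardrop = 120, obturator_base = 30,
                                  fossa_angle_deg = 10,
                                  fossa_radius_frac = 0.8) {
  if (abs(pelvic_tilt) > 30 || abs(pelvic_rotation) > 30)
    stop("pelvic tilt/rotation must be within +/-30 degrees")
  stopifnot(inherits(rim, "rim_curve"))
  if (is.null(head_sphere)) {
    if (is.null(mesh)) stop("either a mesh or a head_sphere is required")
    head_sphere <- robust_head_sphere(mesh)
  }
  c0 <- head_sphere$center
  Q <- rot_z(pelvic_rotation) %*% rot_x(pelvic_tilt)
  xf <- function(pts) {
    if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
    sweep(sweep(pts, 2, c0) %*% t(Q), 2, c0, "+")
  }
  proj <- function(pts3) cbind(-pts3[, 1], pts3[, 3])  # u = -x, v = z

  rs3 <- xf(sample_rim(rim, n_wall_samples))
  rp <- proj(rs3)
  if (diff(range(rp[, 1])) < 1e-6 * max(diff(range(rs3[, 1])), 1) ||
      diff(range(rp[, 1])) <= 0)
    stop("projection degenerate: rim collapses in the image plane")

  i_lat <- which.min(rp[, 1])   # lateral = -u for a right hip
  i_med <- which.max(rp[, 1])
  idx_a <- cyclic_span(i_lat, i_med, n_wall_samples)
  idx_b <- rev(cyclic_span(i_med, i_lat, n_wall_samples))
  ## both chains run lateral -> medial; the anterior one has larger mean y
  y_a <- mean(rs3[idx_a, 2]); y_b <- mean(rs3[idx_b, 2])
  ant_idx <- if (y_a >= y_b) idx_a else idx_b
  post_idx <- if (y_a >= y_b) idx_b else idx_a

  lateral_rim <- rp[i_lat, ]
  inf_i <- which.min(rp[, 2])
  teardrop <- rp[inf_i, ]
  ## medial sourcil: fossa edge, slightly medial of vertical, deeper than
  ## the rim (image frame: lateral = -u, superior = +v for a right hip)
  c_proj <- proj(xf(c0))[1, ]
  cup_r <- mean(rownorms(sweep(rim$points, 2, c0)))
  fa <- deg2rad(fossa_angle_deg)
  med_sourcil <- c_proj + fossa_radius_frac * cup_r *
    (sin(fa) * c(1, 0) + cos(fa) * c(0, 1))
  rot_eff <- deg2rad(pelvic_rotation)
  radiograph_landmarks(
    head_circle = list(center = c_proj, radius = head_sphere$radius),
    lateral_sourcil = lateral_rim,
    medial_sourcil = med_sourcil,
    teardrop = teardrop,
    teardrop_contralateral = teardrop + c(interteardrop, 0),
    lateral_rim = lateral_rim,
    anterior_wall = rp[ant_idx, , drop = FALSE],
    posterior_wall = rp[post_idx, , drop = FALSE],
    obturator_width_ipsi = obturator_base * (1 - sin(rot_eff)),
    obturator_width_contra = obturator_base * (1 + sin(rot_eff)),
    horizontal_ref = c(1, 0),
    side = "right")
}

## indices from i to j moving forward cyclically (inclusive)
cyclic_span <- function(i, j, n) {
  if (j >= i) i:j else c(i:n, 1:j)
}

## robust head sphere from a femur mesh: umbilic-vertex selection on the
## principal-curvature field (the same detector the 3D pipeline uses)
robust_head_sphere <- function(mesh) {
  estimate_head_sphere(mesh, estimate_curvature(mesh))
}
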
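## Head-neck junction detection and the narrowest neck cross-section.

#' Detect the femoral head-neck junction from a curvature field
#'
#' Marches down meridians from the head apex (the antipode of the neck
#' direction) and records, per azimuthal sector, the first zero-crossing of
#' the minimum principal curvature k2: on the convex head k2 > 0, at the
#' saddle-shaped junction k2 < 0.  A least-squares plane is fitted to the
#' crossing points with one MAD-based trimming pass, and the mesh is cut
#' along the plane, keeping the head side.
#'
#' @param mesh a `surface_mesh` of the proximal femur.
#' @param curv `curvature_field` from [estimate_curvature()].
#' @param head_sphere list(center, radius) from [fit_sphere()] on the head.
#' @param n_sectors number of azimuthal sectors (meridians).
#' @param neck_direction optional unit vector from head center toward the
#'   neck; defaults to the direction from the head center to the centroid of
#'   the vertices lying outside 1.05 x radius of the head sphere.
#' @return object of class `junction_result`: list with `inflection_points`
#'   (m x 3), `plane` (point + unit normal, head side positive) and
#'   `head_mesh` (`surface_mesh` cut at the plane).
#' @export
detect_head_neck_junction <- function(mesh, curv, head_sphere,
                                      n_sectors = 72,
                                      neck_direction = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(curv, "curvature_field"))
  c0 <- head_sphere$center; R <- head_sphere$radius
  v <- mesh$vertices
  d <- sweep(v, 2, c0)
  dist <- rownorms(d)

  if (is.null(neck_direction)) {
    far <- dist > 1.05 * R
    if (!any(far)) stop("no inflection ring: mesh has no neck region")
    neck_direction <- unitv(colMeans(v[far, , drop = FALSE]) - c0)
  }
  apex_dir <- -unitv(neck_direction)

  ## spherical coordinates about the apex
  u <- normalize_rows(d)
  polar <- acos(pmin(pmax(u %*% apex_dir, -1), 1))
  b1 <- unitv(pick_perp(apex_dir)); b2 <- cross3(apex_dir, b1)
  az <- atan2(as.numeric(u %*% b2), as.numeric(u %*% b1)) %% (2 * pi)
  sector <- pmin(floor(az / (2 * pi) * n_sectors) + 1L, n_sectors)

  ## consider the head and proximal-neck band only
  near <- dist < 1.6 * R & polar < deg2rad(165)
  crossings <- matrix(NA_real_, 0, 3)
  for (s in seq_len(n_sectors)) {
    idx <- which(near & sector == s & !is.na(curv$k2))
    if (length(idx) < 2) next
    idx <- idx[order(polar[idx])]
    k2 <- curv$k2[idx]
    flip <- which(k2[-length(k2)] > 0 & k2[-1] <= 0)
    if (length(flip) == 0) next
    j <- flip[1]
    i1 <- idx[j]; i2 <- idx[j + 1]
    w <- k2[j] / (k2[j] - k2[j + 1])   # linear interpolation in k2
    crossings <- rbind(crossings, v[i1, ] + w * (v[i2, ] - v[i1, ]))
  }
  if (nrow(crossings) < 8)
    stop("no inflection ring: fewer than 8 k2 zero-crossings found")

  ## plane fit with one MAD trim pass
  pl <- fit_plane(crossings)
  res <- plane_signed_distance(pl, crossings)
  s <- mad(res)
  if (s > 0) {
    keep <- abs(res - median(res)) <= 2 * s
    if (sum(keep) >= 8) pl <- fit_plane(crossings[keep, , drop = FALSE])
  }
  ## orient normal toward the apex (head side positive)
  if (sum(pl$normal * apex_dir) < 0) pl$normal <- -pl$normal
  head_mesh <- cut_mesh_by_plane(mesh, pl, keep = "positive")
  structure(list(inflection_points = crossings, plane = pl,
                 head_mesh = head_mesh),
            class = "junction_result")
}

#' @export
print.junction_result <- function(x, ...) {
  cat(sprintf("<junction_result> %d inflection points, plane normal (%.2f, %.2f, %.2f)\n",
              nrow(x$inflection_points), x$plane$normal[1], x$plane$normal[2],
              x$plane$normal[3]))
  invisible(x)
}

#' Center of the narrowest neck cross-section
#'
#' Sweeps planes perpendicular to the supplied axis (head center toward
#' shaft center) at fixed steps, computes each planar cross-section area,
#' and returns the centroid of the minimum-area section.
#'
#' @param mesh a closed, consistently wound `surface_mesh`.
#' @param axis_point point on the axis (head center), mm.
#' @param axis_dir unit direction toward the shaft.
#' @param step sampling step along the axis, mm.
#' @param range fractional scan window along `axis_point` ->
#'   projection extent (default skips the head and distal shaft).
#' @param max_radial faces farther than this from the axis are ignored;
#'   default `Inf` (sections broken open by the filter are skipped via a
#'   closure check, so filtering is rarely needed).
#' @return list with `center` (3D point), `area` (mm^2), `s` (offset along
#'   the axis) and the scanned `profile` tibble (s, area).
#' @export
narrowest_neck_center <- function(mesh, axis_point, axis_dir, step = 0.5,
                                  range = c(0.2, 0.85), max_radial = NULL) {
  axis_dir <- unitv(axis_dir)
  proj <- as.numeric(sweep(mesh$vertices, 2, axis_point) %*% axis_dir)
  s_lo <- range[1] * max(proj); s_hi <- range[2] * max(proj)
  if (s_hi <= s_lo) stop("empty scan range along the neck axis")
  if (is.null(max_radial)) max_radial <- Inf
  if (is.finite(max_radial)) {
    ctr <- face_centroids(mesh)
    dc <- sweep(ctr, 2, axis_point)
    ax_t <- as.numeric(dc %*% axis_dir)
    radial <- rownorms(dc - outer(ax_t, axis_dir))
    sub <- surface_mesh(mesh$vertices,
                        mesh$faces[radial <= max_radial, , drop = FALSE],
                        clean = FALSE)
  } else sub <- mesh
  ss <- seq(s_lo, s_hi, by = step)
  areas <- rep(NA_real_, length(ss))
  cents <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    cs <- cross_section(sub, new_plane(axis_point + ss[i] * axis_dir, axis_dir))
    ## sections broken open by the radial face filter are not usable
    if (cs$area > 0 && isTRUE(cs$closed)) {
      areas[i] <- cs$area; cents[[i]] <- cs$centroid
    }
  }
  ok <- which(!is.na(areas))
  if (length(ok) == 0) stop("no non-empty cross-sections along the axis")
  best <- ok[which.min(areas[ok])]
  list(center = cents[[best]], area = areas[best], s = ss[best],
       profile = tibble::tibble(s = ss, area = areas))
}
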
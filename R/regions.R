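## Four-region partition of the femoral head: plane1 through the head
## center, narrowest-neck center and shaft center (anterior/posterior
## divider), plane2 perpendicular to it through the head center
## (lateral/medial divider).

#' Region-dividing planes from the three anatomical centers
#'
#' Plane 1 passes through the geometric head center, the narrowest-neck
#' center and the shaft center; its normal is oriented toward +anterior
#' (+y).  Plane 2 passes through the head center, perpendicular to plane 1;
#' its normal is the component of (head - neck) orthogonal to plane 1's
#' normal, oriented toward +medial (-x).
#'
#' @param head_center,neck_center,shaft_center 3D points, mm (non-collinear).
#' @return object of class `region_planes`: list(plane1, plane2), each
#'   list(point, normal) with unit normals satisfying
#'   `plane1$normal . plane2$normal == 0`.
#' @export
region_planes <- function(head_center, neck_center, shaft_center) {
  a <- as.numeric(neck_center) - as.numeric(head_center)
  b <- as.numeric(shaft_center) - as.numeric(head_center)
  n1 <- cross3(a, b)
  if (vnorm(n1) < 1e-9 * max(vnorm(a) * vnorm(b), 1))
    stop("the three centers are collinear")
  n1 <- unitv(n1)
  if (n1[2] < 0) n1 <- -n1                      # anterior
  hm <- as.numeric(head_center) - as.numeric(neck_center)
  n2 <- hm - sum(hm * n1) * n1
  if (vnorm(n2) < 1e-12) stop("head-neck axis parallel to plane1 normal")
  n2 <- unitv(n2)
  if (n2[1] > 0) n2 <- -n2                      # medial
  structure(list(plane1 = new_plane(head_center, n1),
                 plane2 = new_plane(head_center, n2)),
            class = "region_planes")
}

#' Partition a head mesh into the four anatomical regions
#'
#' Faces straddling either plane are split geometrically so that every
#' output face lies wholly in one region; region areas therefore sum to the
#' head area exactly.  Regions: anterior/posterior by plane 1, lateral/
#' medial by plane 2 (AL, AM, PL, PM).
#'
#' @param head_mesh `surface_mesh` of the cut femoral head.
#' @param planes a `region_planes` object.
#' @return object of class `head_partition`: list with `mesh` (split
#'   `surface_mesh`), `region` (factor per face) and `planes`.
#' @export
partition_head <- function(head_mesh, planes) {
  stopifnot(inherits(planes, "region_planes"))
  m1 <- split_mesh_by_plane(head_mesh, planes$plane1)
  m2 <- split_mesh_by_plane(m1, planes$plane2)
  ## recompute side signs per final face from centroids (robust: faces were
  ## split so centroids are strictly off-plane except degenerate slivers)
  ctr <- face_centroids(m2)
  s1 <- plane_signed_distance(planes$plane1, ctr) >= 0
  s2 <- plane_signed_distance(planes$plane2, ctr) >= 0
  region <- factor(ifelse(s1, ifelse(s2, "AM", "AL"),
                          ifelse(s2, "PM", "PL")),
                   levels = c("AL", "AM", "PL", "PM"))
  structure(list(mesh = m2, region = region, planes = planes),
            class = "head_partition")
}

#' @export
print.head_partition <- function(x, ...) {
  a <- tapply(face_areas(x$mesh), x$region, sum)
  cat("<head_partition> region areas (mm^2):\n")
  print(round(a, 1))
  invisible(x)
}
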
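## Parametric synthetic hip generator.  Produces a watertight proximal-femur
## mesh (spherical head, cylindrical neck meeting the head at its analytic
## tangency circle, bent cylindrical shaft), an acetabular rim curve on a cup
## sphere concentric with the head, and analytic / Monte-Carlo ground truth
## for coverage.  Anatomical frame: right hip, +x lateral, +y anterior,
## +z superior; all lengths mm, all angles degrees.

#' Parameters of a synthetic hip
#'
#' The cup is concentric with the femoral head (congruent joint).  Its rim
#' is the spherical circle at polar half-angle `cup_depth_angle` around the
#' cup pole, optionally undulated by a period-two ("saddle") term of
#' amplitude `rim_saddle_deg` - the non-planarity of the real acetabular rim
#' that makes a radiographic crossover sign geometrically possible.  At
#' `cup_version = 0`, `cup_inclination = 0` the cup pole lies in the
#' femoral-neck plane (y = 0), perpendicular to the neck axis, pointing
#' medially.  Positive `cup_version` rotates the pole posteriorly about the
#' superior-inferior axis (anteversion); negative values produce a
#' retroverted cup.  `cup_inclination` rotates about the anterior-posterior
#' axis.
#'
#' @param head_radius femoral head radius, mm.
#' @param head_center head center, length-3, mm.
#' @param neck_radius neck radius, mm (must be < head_radius).
#' @param neck_fillet_radius meridian radius of the concave head-neck blend,
#'   mm.  The blend is tangent to both the head sphere and the neck
#'   cylinder, so the minimum principal curvature crosses zero exactly at
#'   the sphere-blend tangency circle - the analytic ground-truth junction.
#' @param neck_length neck length beyond the head-neck tangency, mm.
#' @param neck_shaft_angle angle between neck and shaft axes, degrees.
#' @param shaft_radius,shaft_length proximal shaft cylinder, mm.
#' @param cup_radius acetabular (cup) sphere radius, mm, >= head_radius.
#' @param cup_depth_angle polar half-angle of the cup rim, degrees, (0,180).
#' @param cup_version version, degrees; positive anteverted, negative
#'   retroverted.
#' @param cup_inclination inclination, degrees.
#' @param cam_bump_height radial cam lesion height at the anterosuperior
#'   head-neck junction, mm; 0 gives a spherical head.
#' @param rim_saddle_deg amplitude of the period-2 rim undulation, degrees.
#' @param rim_saddle_phase_deg phase of the undulation (body-anchored
#'   azimuth, 0 = anterior), degrees.
#' @param rim_recess_deg period-1 undulation amplitude: the anterior rim
#'   sits this much lower (smaller polar angle) than the posterior rim,
#'   degrees.
#' @param n_rim_points number of rim control points emitted.
#' @param mesh_resolution target vertex count of the femur mesh (>= 500).
#' @return a validated list of class `hip_params`.
#' @export
hip_params <- function(head_radius = 25, head_center = c(0, 0, 0),
                       neck_radius = 15, neck_fillet_radius = 4,
                       neck_length = 35,
                       neck_shaft_angle = 130,
                       shaft_radius = 16, shaft_length = 80,
                       cup_radius = 27, cup_depth_angle = 95,
                       cup_version = 15, cup_inclination = 0,
                       cam_bump_height = 0,
                       rim_saddle_deg = 8, rim_saddle_phase_deg = 120,
                       rim_recess_deg = 10,
                       n_rim_points = 64,
                       mesh_resolution = 6000) {
  p <- list(head_radius = head_radius, head_center = as.numeric(head_center),
            neck_radius = neck_radius,
            neck_fillet_radius = neck_fillet_radius,
            neck_length = neck_length,
            neck_shaft_angle = neck_shaft_angle, shaft_radius = shaft_radius,
            shaft_length = shaft_length, cup_radius = cup_radius,
            cup_depth_angle = cup_depth_angle, cup_version = cup_version,
            cup_inclination = cup_inclination,
            cam_bump_height = cam_bump_height,
            rim_saddle_deg = rim_saddle_deg,
            rim_saddle_phase_deg = rim_saddle_phase_deg,
            rim_recess_deg = rim_recess_deg,
            n_rim_points = n_rim_points,
            mesh_resolution = mesh_resolution)
  validate_hip_params(p)
  structure(p, class = "hip_params")
}

validate_hip_params <- function(p) {
  if (!(p$head_radius > p$neck_radius && p$neck_radius > 0))
    stop("need head_radius > neck_radius > 0")
  if (!(p$cup_depth_angle > 0 && p$cup_depth_angle < 180))
    stop("cup_depth_angle must lie strictly between 0 and 180 degrees")
  if (p$cup_radius < p$head_radius)
    stop("cup_radius must be >= head_radius (congruent joint)")
  if (p$mesh_resolution < 500)
    stop("mesh_resolution must be at least 500 vertices")
  if (p$neck_fillet_radius < 0) stop("neck_fillet_radius must be >= 0")
  if (p$rim_saddle_deg < 0) stop("rim_saddle_deg must be >= 0")
  und <- p$rim_saddle_deg + abs(p$rim_recess_deg)
  if (p$cup_depth_angle + und >= 180 || p$cup_depth_angle - und <= 0)
    stop("rim undulation drives the rim past a pole")
  invisible(p)
}

## ---- frame helpers ----------------------------------------------------------

## head -> neck unit direction (inferolateral), y = 0 plane
neck_direction <- function(p) {
  psi <- deg2rad(180 - p$neck_shaft_angle)
  c(sin(psi), 0, -cos(psi))
}

## cup pole and in-cup basis after version/inclination rotations.
## Reference pole a0 = -neck direction (superomedial): the femoral neck aims
## into the acetabulum, so the congruent cup is centred on the neck axis at
## zero version/inclination.  This makes the version-0 configuration mirror
## symmetric in the anterior/posterior sense (AL = PL, AM = PM).
## Reference basis u1 = +y (anterior), u2 = a0 x u1.
cup_frame <- function(p) {
  a0 <- -neck_direction(p)
  Q <- rot_y(p$cup_inclination) %*% rot_z(p$cup_version)
  a <- as.numeric(Q %*% a0)
  ## azimuth basis anchored to the body frame (anterior reference), not to
  ## the cup: the rim elevation pattern stays fixed relative to the pelvis
  ## while the cup opening rotates, as the inferior acetabular horns do
  u1 <- unitv(c(0, 1, 0) - a[2] * a)
  u2 <- cross3(a, u1)
  list(axis = a, u1 = u1, u2 = u2)
}

## rim polar angle as a function of body-anchored azimuth t (radians,
## t = 0 toward anterior): period-2 saddle plus period-1 anterior recess
## (the anterior rim sits lower than the posterior rim)
rim_polar <- function(p, t) {
  deg2rad(p$cup_depth_angle) +
    deg2rad(p$rim_saddle_deg) *
      cos(2 * (t - deg2rad(p$rim_saddle_phase_deg))) -
    deg2rad(p$rim_recess_deg) * cos(t)
}

## is a unit direction (head frame) inside the covered cap?
cup_covers <- function(p, frame, u) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 3)
  ca <- pmin(pmax(u %*% frame$axis, -1), 1)
  polar <- acos(as.numeric(ca))
  t <- atan2(as.numeric(u %*% frame$u2), as.numeric(u %*% frame$u1))
  polar <= rim_polar(p, t)
}

## ---- femur mesh -------------------------------------------------------------

## Meridian geometry of the head-neck blend: a fillet arc of radius rho_f
## tangent to the head sphere and to the neck cylinder.  In meridian
## coordinates (radial rho, axial z along the neck direction from the head
## center), the fillet center sits at (r + rho_f, z_f) with
## z_f = sqrt((R + rho_f)^2 - (r + rho_f)^2); the sphere tangency point is
## at R/(R + rho_f) * (r + rho_f, z_f).
fillet_geometry <- function(p) {
  R <- p$head_radius; r <- p$neck_radius; rf <- p$neck_fillet_radius
  zf <- sqrt((R + rf)^2 - (r + rf)^2)
  tang <- R / (R + rf) * c(r + rf, zf)   # (rho_T, z_T) sphere tangency
  list(center = c(r + rf, zf), z_cyl = zf, tangency = tang,
       theta_neck = atan2(tang[1], tang[2]))  # polar angle from neck pole
}

build_femur_mesh <- function(p) {
  R <- p$head_radius; r <- p$neck_radius; c0 <- p$head_center
  n <- neck_direction(p)
  fg <- fillet_geometry(p)
  e3 <- -n                              # apex direction
  u1 <- unitv(cross3(c(0, 1, 0), e3))
  u2 <- cross3(e3, u1)

  theta_max <- pi - fg$theta_neck       # sphere polar extent from the apex
  ## fillet arc angular extent (from sphere tangency to cylinder tangency)
  v1 <- fg$tangency - fg$center
  v2 <- c(-p$neck_fillet_radius, 0)
  phi_f <- acos(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)))
  L_sph <- R * theta_max
  L_fil <- p$neck_fillet_radius * phi_f
  L_tube <- p$neck_length + p$shaft_length
  h <- sqrt(2 * pi * R * (L_sph + L_fil + L_tube) / p$mesh_resolution)
  k <- max(16L, as.integer(round(2 * pi * R / h)))
  n_sph <- max(8L, as.integer(round(L_sph / h)))
  n_fil <- max(4L, as.integer(round(L_fil / h)))
  n_tube <- max(8L, as.integer(round(L_tube / h)))

  phi <- 2 * pi * (seq_len(k) - 1) / k
  cph <- cos(phi); sph <- sin(phi)
  ring_at <- function(center, radius, w1, w2)
    matrix(center, k, 3, byrow = TRUE) +
      radius * (outer(cph, w1) + outer(sph, w2))

  rings <- vector("list", n_sph + n_fil + n_tube)
  ## sphere rings, theta from near-apex down to the fillet tangency ring
  theta <- theta_max * seq_len(n_sph) / n_sph
  for (j in seq_len(n_sph)) {
    rc <- c0 + R * cos(theta[j]) * e3
    rings[[j]] <- ring_at(rc, R * sin(theta[j]), u1, u2)
  }
  ## fillet rings: arc in the meridian plane from the sphere tangency to
  ## the cylinder tangency
  ang0 <- atan2(v1[2], v1[1])
  ang1 <- atan2(v2[2], v2[1])
  ## sweep from ang0 to ang1 the short way
  dang <- (ang1 - ang0)
  if (dang > pi) dang <- dang - 2 * pi
  if (dang < -pi) dang <- dang + 2 * pi
  for (j in seq_len(n_fil)) {
    a <- ang0 + dang * j / n_fil
    rho <- fg$center[1] + p$neck_fillet_radius * cos(a)
    zz <- fg$center[2] + p$neck_fillet_radius * sin(a)
    rings[[n_sph + j]] <- ring_at(c0 + zz * n, rho, u1, u2)
  }
  ## tube rings: neck along n, then shaft along -z, tangent and radius
  ## blended around the neck-shaft transition
  s_grid <- L_tube * seq_len(n_tube) / n_tube
  P0 <- c0 + fg$z_cyl * n
  sd_dir <- c(0, 0, -1)
  blend_w <- max(p$shaft_radius, r) * 1.2
  w1 <- u1; w2 <- u2
  prev_t <- n
  for (j in seq_len(n_tube)) {
    s <- s_grid[j]
    ## centerline position (sharp polyline) and blended tangent
    if (s <= p$neck_length) pos <- P0 + s * n
    else pos <- P0 + p$neck_length * n + (s - p$neck_length) * sd_dir
    b <- smoothstep((s - (p$neck_length - blend_w)) / (2 * blend_w))
    tan_j <- unitv((1 - b) * n + b * sd_dir)
    ## parallel-transport the ring basis
    w1 <- unitv(w1 - sum(w1 * tan_j) * tan_j)
    w2 <- unitv(w2 - sum(w2 * tan_j) * tan_j)
    w2 <- unitv(w2 - sum(w2 * w1) * w1)
    rad_b <- smoothstep((s - p$neck_length) /
                          max(min(2 * p$shaft_radius, p$shaft_length / 2), 1))
    rad <- r + (p$shaft_radius - r) * rad_b
    rings[[n_sph + n_fil + j]] <- ring_at(pos, rad, w1, w2)
    prev_t <- tan_j
  }

  apex <- c0 + R * e3
  endp <- P0 + p$neck_length * n + p$shaft_length * sd_dir
  verts <- rbind(apex, do.call(rbind, rings), endp)
  n_rings <- length(rings)
  ring_idx <- function(j) 1L + (j - 1L) * k + seq_len(k)

  faces <- vector("list", n_rings + 1)
  ## apex fan
  r1 <- ring_idx(1)
  faces[[1]] <- cbind(1L, r1, r1[c(2:k, 1)])
  ## ring-to-ring quads
  for (j in seq_len(n_rings - 1)) {
    a <- ring_idx(j); b <- ring_idx(j + 1)
    an <- a[c(2:k, 1)]; bn <- b[c(2:k, 1)]
    faces[[j + 1]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
  }
  ## end cap fan (opposite winding)
  rl <- ring_idx(n_rings)
  ei <- nrow(verts)
  faces[[n_rings + 1]] <- cbind(ei, rl[c(2:k, 1)], rl)
  mesh <- surface_mesh(verts, do.call(rbind, faces), clean = FALSE)

  ## orient outward (positive enclosed volume)
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]

  if (p$cam_bump_height > 0) mesh <- add_cam_bump(mesh, p)
  mesh
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

## signed volume via divergence theorem
mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

## gaussian radial bump on the head sphere at the anterosuperior junction
add_cam_bump <- function(mesh, p) {
  c0 <- p$head_center; R <- p$head_radius
  d <- sweep(mesh$vertices, 2, c0)
  dist <- rownorms(d)
  on_head <- abs(dist - R) < 1e-6 * R
  bump_dir <- unitv(neck_direction(p) + c(0, 1, 0.3))
  u <- normalize_rows(d[on_head, , drop = FALSE])
  gamma <- acos(pmin(pmax(u %*% bump_dir, -1), 1))
  sigma <- deg2rad(15)
  amp <- p$cam_bump_height * exp(-(gamma / sigma)^2)
  mesh$vertices[on_head, ] <- mesh$vertices[on_head, ] + as.numeric(amp) * u
  mesh
}

## ---- rim --------------------------------------------------------------------

build_rim_points <- function(p) {
  frame <- cup_frame(p)
  t <- 2 * pi * (seq_len(p$n_rim_points) - 1) / p$n_rim_points
  th <- rim_polar(p, t)
  dirs <- outer(sin(th) * cos(t), frame$u1) +
    outer(sin(th) * sin(t), frame$u2) +
    outer(cos(th), frame$axis)
  sweep(p$cup_radius * dirs, 2, p$head_center, "+")
}

## ---- ground truth -----------------------------------------------------------

#' Monte-Carlo spherical-integration oracle for regional coverage
#'
#' Classifies uniformly sampled directions on the head sphere by cup
#' membership and by the two region planes, yielding per-region percent
#' coverage independently of any mesh.  Optionally restricted to the head
#' side of a junction plane so that it integrates over the same domain as
#' the mesh pipeline.
#'
#' @param params a `hip_params`.
#' @param planes optional `region_planes()` result; defaults to the
#'   generator's true planes.
#' @param junction_plane optional plane list(point, normal); when given,
#'   only directions on its positive side are integrated.
#' @param n_samples number of uniform sphere samples (>= 1e5).
#' @param seed integer seed for reproducibility.
#' @return tibble with one row per region (AL, AM, PL, PM, Ant, Post, TC):
#'   `area_frac` (of the integrated domain) and `percent` covered.
#' @export
mc_region_coverage <- function(params, planes = NULL, junction_plane = NULL,
                               n_samples = 1e6, seed = 1L) {
  stopifnot(inherits(params, "hip_params"))
  if (is.null(planes)) planes <- true_region_planes(params)
  frame <- cup_frame(params)
  c0 <- params$head_center; R <- params$head_radius
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- matrix(rnorm(3 * n_samples), ncol = 3)
  u <- normalize_rows(u)
  if (!is.null(junction_plane)) {
    pts <- sweep(R * u, 2, c0, "+")
    u <- u[plane_signed_distance(junction_plane, pts) > 0, , drop = FALSE]
  }
  cov <- cup_covers(params, frame, u)
  pts <- sweep(R * u, 2, c0, "+")
  s1 <- plane_signed_distance(planes$plane1, pts) > 0   # anterior
  s2 <- plane_signed_distance(planes$plane2, pts) > 0   # medial
  region <- ifelse(s1, ifelse(s2, "AM", "AL"), ifelse(s2, "PM", "PL"))
  agg <- function(mask) {
    nn <- sum(mask)
    c(area_frac = nn / nrow(u),
      percent = if (nn > 0) 100 * sum(cov[mask]) / nn else NA_real_)
  }
  rows <- rbind(AL = agg(region == "AL"), AM = agg(region == "AM"),
                PL = agg(region == "PL"), PM = agg(region == "PM"),
                Ant = agg(s1), Post = agg(!s1),
                TC = agg(rep(TRUE, nrow(u))))
  tibble::tibble(region = rownames(rows),
                 area_frac = rows[, "area_frac"],
                 percent = rows[, "percent"])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Analytic head-neck junction plane of a synthetic hip
#'
#' The plane of the circle where the head sphere meets the neck blend
#' tangentially (normal pointing toward the head apex).
#' @param p a `hip_params`.
#' @return plane list(point, normal).
#' @export
true_junction_plane <- function(p) {
  n <- neck_direction(p)
  fg <- fillet_geometry(p)
  new_plane(p$head_center + fg$tangency[2] * n, -n)
}

## the generator's true region planes (see region_planes for the detected
## counterpart): plane1 is the neck/shaft plane y = 0 (normal anterior),
## plane2 is perpendicular to it through the head center with normal along
## the medial component of the head-neck axis
true_region_planes <- function(p) {
  n <- neck_direction(p)
  list(plane1 = new_plane(p$head_center, c(0, 1, 0)),
       plane2 = new_plane(p$head_center, -n))
}

## analytic total coverage over the full head sphere, percent: the area
## fraction of {polar(t) <= theta(t)} is (1 - mean_t cos theta(t))/2,
## evaluated by quadrature; reduces to the exact spherical-cap closed form
## 100 (1 - cos theta_c)/2 for an unperturbed circular rim
analytic_total_coverage <- function(p) {
  f <- function(t) cos(rim_polar(p, t))
  m <- stats::integrate(f, 0, 2 * pi, rel.tol = 1e-12,
                        abs.tol = 1e-14)$value / (2 * pi)
  100 * (1 - m) / 2
}

#' Generate a synthetic hip
#'
#' Builds the femur surface mesh, the acetabular rim curve and the ground
#' truth (analytic total coverage, Monte-Carlo regional coverage on the full
#' head sphere, analytic head-neck junction plane, crossover expectation).
#'
#' @param params a `hip_params`.
#' @param seed integer seed (drives the Monte-Carlo ground truth; the mesh
#'   and rim are deterministic functions of `params`).
#' @param gt_samples Monte-Carlo sample count for the regional ground truth.
#' @return list of class `synthetic_hip` with `mesh` (`surface_mesh`),
#'   `rim` (`rim_curve`), `ground_truth` and `params`.
#' @export
generate_hip <- function(params, seed = 1L, gt_samples = 2e5) {
  stopifnot(inherits(params, "hip_params"))
  validate_hip_params(params)
  mesh <- build_femur_mesh(params)
  rim <- rim_curve(build_rim_points(params))
  mc <- mc_region_coverage(params, n_samples = gt_samples, seed = seed)
  reg <- mc$percent[match(c("AL", "AM", "PL", "PM"), mc$region)]
  names(reg) <- c("AL", "AM", "PL", "PM")
  gt <- list(
    expected_total_coverage_pct = analytic_total_coverage(params),
    expected_region_coverage_pct = reg,
    region_area_frac = setNames(
      mc$area_frac[match(c("AL", "AM", "PL", "PM"), mc$region)],
      c("AL", "AM", "PL", "PM")),
    junction_plane = true_junction_plane(params),
    true_version = params$cup_version,
    crossover_expected = NA  # filled by project_to_radiograph at tilt 0
  )
  hip <- structure(list(mesh = mesh, rim = rim, ground_truth = gt,
                        params = params), class = "synthetic_hip")
  lm0 <- project_to_radiograph(mesh, rim, pelvic_tilt = 0,
                               pelvic_rotation = 0)
  hip$ground_truth$crossover_expected <-
    is.finite(crossover_ratio(lm0))
  hip
}

#' @export
print.synthetic_hip <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_hip> head R %.1f mm, cup depth %.0f deg, ",
                     "version %+.0f deg; expected TC %.1f%%\n"),
              x$params$head_radius, x$params$cup_depth_angle,
              x$params$cup_version,
              x$ground_truth$expected_total_coverage_pct))
  invisible(x)
}
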
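## Coverage of the femoral head by the acetabulum: rim projection onto the
## head surface, covered/uncovered classification via a point-in-spherical-
## polygon test, and the percent-coverage report
## (100 * covered area / total region area).

#' Project the acetabular rim onto the head surface
#'
#' Samples the rim spline densely and maps every sample to its Euclidean
#' nearest point on the head mesh (point-to-triangle), producing the closed
#' "line of acetabular coverage" on the head.
#'
#' @param rim a `rim_curve`.
#' @param head_mesh `surface_mesh` of the (cut) femoral head.
#' @param n_samples number of spline samples (default 512).
#' @return m x 3 matrix of ordered on-surface points (consecutive
#'   duplicates merged).
#' @export
project_rim <- function(rim, head_mesh, n_samples = 512) {
  stopifnot(inherits(rim, "rim_curve"))
  pts <- sample_rim(rim, n_samples)
  ctr <- colMeans(head_mesh$vertices)
  rad <- max(rownorms(sweep(head_mesh$vertices, 2, ctr)))
  dmin <- min(rownorms(sweep(pts, 2, ctr)))
  if (dmin > 2 * rad + rad)
    stop("rim is farther than twice the head radius from the head mesh")
  proj <- closest_points_on_mesh(pts, head_mesh)
  if (min(proj$dist) > 2 * rad)
    stop("rim is entirely farther than 2x the head radius: wrong bone?")
  cp <- proj$points
  keep <- c(TRUE, rownorms(diff(cp)) > 1e-9)
  cp[keep, , drop = FALSE]
}

## nearest point on a triangle mesh for each query point; vectorised over
## faces per query (plane projection + barycentric clamp via edge segments).
## For near-star-shaped meshes (the femoral head), faces are prefiltered by
## angular proximity of their centroid direction to the query direction.
closest_points_on_mesh <- function(pts, mesh, prefilter_cos = 0.9) {
  fc <- face_corners(mesh)
  A_all <- fc$a; B_all <- fc$b; C_all <- fc$c
  ctr0 <- colMeans(mesh$vertices)
  cdir <- normalize_rows(sweep(face_centroids(mesh), 2, ctr0))
  out <- matrix(0, nrow(pts), 3)
  dists <- numeric(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    pd <- unitv(p - ctr0)
    sel <- which(as.numeric(cdir %*% pd) > prefilter_cos)
    if (length(sel) < 8) sel <- seq_len(nrow(A_all))
    A <- A_all[sel, , drop = FALSE]
    B <- B_all[sel, , drop = FALSE]
    C <- C_all[sel, , drop = FALSE]
    E0 <- B - A; E1 <- C - A
    nrm <- cross3(E0, E1)
    nn2 <- pmax(rowSums(nrm^2), .Machine$double.xmin)
    AP <- -sweep(A, 2, p)             # p - A
    tplane <- rowSums(AP * nrm) / nn2
    foot <- matrix(p, nrow(A), 3, byrow = TRUE) - tplane * nrm
    ## barycentric of foot
    v2 <- foot - A
    d00 <- rowSums(E0 * E0); d01 <- rowSums(E0 * E1); d11 <- rowSums(E1 * E1)
    d20 <- rowSums(v2 * E0); d21 <- rowSums(v2 * E1)
    den <- pmax(d00 * d11 - d01^2, .Machine$double.xmin)
    bv <- (d11 * d20 - d01 * d21) / den
    bw <- (d00 * d21 - d01 * d20) / den
    inside <- bv >= 0 & bw >= 0 & (bv + bw) <= 1
    cand <- foot
    d2 <- rowSums((cand - matrix(p, nrow(A), 3, byrow = TRUE))^2)
    d2[!inside] <- Inf
    ## edges for faces where the foot is outside
    seg <- function(P1, P2) {
      E <- P2 - P1
      t <- rowSums((matrix(p, nrow(P1), 3, byrow = TRUE) - P1) * E) /
        pmax(rowSums(E^2), .Machine$double.xmin)
      t <- pmin(pmax(t, 0), 1)
      X <- P1 + t * E
      list(X = X, d2 = rowSums((X - matrix(p, nrow(P1), 3, byrow = TRUE))^2))
    }
    if (any(!inside)) {
      s1 <- seg(A, B); s2 <- seg(B, C); s3 <- seg(C, A)
      de <- pmin(s1$d2, s2$d2, s3$d2)
      Xe <- s1$X
      m2 <- s2$d2 < s1$d2
      Xe[m2, ] <- s2$X[m2, ]
      m3 <- s3$d2 < pmin(s1$d2, s2$d2)
      Xe[m3, ] <- s3$X[m3, ]
      repl <- !inside
      cand[repl, ] <- Xe[repl, ]
      d2[repl] <- de[repl]
    }
    best <- which.min(d2)
    out[q, ] <- cand[best, ]
    dists[q] <- sqrt(d2[best])
  }
  list(points = out, dist = dists)
}

#' Classify head faces as covered or uncovered
#'
#' Maps face vertices and the projected rim curve to the unit sphere about
#' the head center and applies an even/odd geodesic crossing test against
#' the closed spherical polygon, with the direction of the rim centroid as
#' the interior witness.  Faces straddling the curve get a fractional
#' covered area from recursive spherical subdivision.
#'
#' @param head_mesh the (partitioned) head `surface_mesh`.
#' @param curve m x 3 matrix from [project_rim()].
#' @param head_sphere list(center, radius).
#' @param rim the `rim_curve` (fallback interior witness when `interior` is
#'   `NULL`).
#' @param interior direction (from the head center) known to lie on the
#'   covered side.  Defaults to the medial direction `c(-1, 0, 0)` of the
#'   anatomical frame: the acetabulum is medial to the femoral head.  The
#'   covered/uncovered split is intrinsically ambiguous from the rim curve
#'   alone (a cap of half-angle \eqn{\theta} about one pole has the same rim
#'   as a cap of \eqn{180-\theta} about the antipode), so the witness is an
#'   explicit convention; pass `NULL` to fall back to the rim-centroid
#'   direction, which is valid only for cups shallower than a hemisphere.
#' @param subdiv_depth recursion depth for straddling faces (4^depth
#'   sub-triangles).
#' @return numeric vector: covered area fraction per face (0..1).
#' @export
covered_region <- function(head_mesh, curve, head_sphere, rim,
                           interior = c(-1, 0, 0), subdiv_depth = 3) {
  c0 <- head_sphere$center
  poly <- normalize_rows(sweep(curve, 2, c0))
  keep <- c(TRUE, rownorms(diff(poly)) > 1e-12)
  poly <- poly[keep, , drop = FALSE]
  if (nrow(poly) < 3) stop("projected rim curve is degenerate")
  d <- if (is.null(interior))
    unitv(colMeans(sweep(rim$points, 2, c0))) else unitv(interior)

  vdir <- normalize_rows(sweep(head_mesh$vertices, 2, c0))
  vin <- in_spherical_polygon(vdir, poly, d)

  f <- head_mesh$faces
  nin <- matrix(vin[f], ncol = 3)
  frac <- rowMeans(nin)
  full <- rowSums(nin) == 3L
  none <- rowSums(nin) == 0L
  frac[full] <- 1; frac[none] <- 0
  mixed <- which(!full & !none)
  if (length(mixed) > 0) {
    for (i in mixed) {
      tri <- vdir[f[i, ], , drop = FALSE]
      cents <- subdivide_sph_triangle(tri, subdiv_depth)
      frac[i] <- mean(in_spherical_polygon(cents, poly, d))
    }
  }
  frac
}

## centroids of 4^depth recursive subdivisions of a spherical triangle
subdivide_sph_triangle <- function(tri, depth) {
  tris <- list(tri)
  for (k in seq_len(depth)) {
    nxt <- vector("list", 4 * length(tris))
    for (j in seq_along(tris)) {
      t <- tris[[j]]
      m12 <- unitv(t[1, ] + t[2, ]); m23 <- unitv(t[2, ] + t[3, ])
      m31 <- unitv(t[3, ] + t[1, ])
      nxt[[4 * j - 3]] <- rbind(t[1, ], m12, m31)
      nxt[[4 * j - 2]] <- rbind(m12, t[2, ], m23)
      nxt[[4 * j - 1]] <- rbind(m31, m23, t[3, ])
      nxt[[4 * j]]     <- rbind(m12, m23, m31)
    }
    tris <- nxt
  }
  do.call(rbind, lapply(tris, function(t) unitv(colSums(t))))
}

## even/odd geodesic crossing test: u covered iff the minor arc u -> d
## crosses the polygon an even number of times (d is interior)
in_spherical_polygon <- function(u, poly, d) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 3)
  n_pts <- nrow(u)
  ## tiny deterministic nudge of the witness avoids exact-degeneracy ties
  d <- unitv(d + c(1e-9, 2e-9, 3e-9))
  crossings <- integer(n_pts)
  ud_n <- cbind(u[, 2] * d[3] - u[, 3] * d[2],
                u[, 3] * d[1] - u[, 1] * d[3],
                u[, 1] * d[2] - u[, 2] * d[1])      # u x d per point
  upd <- sweep(u, 2, d, "+")                        # u + d
  E <- nrow(poly)
  nxt <- c(2:E, 1)
  for (e in seq_len(E)) {
    C <- poly[e, ]; D <- poly[nxt[e], ]
    nCD <- cross3(C, D)
    s_u <- u %*% nCD
    s_d <- sum(d * nCD)
    cond1 <- as.numeric(s_u) * s_d < 0
    det1 <- ud_n %*% C
    det2 <- ud_n %*% D
    cond2 <- as.numeric(det1) * as.numeric(det2) < 0
    ## same-intersection check: t = (u x d) x nCD = d (u.nCD) - u (d.nCD)
    tX <- as.numeric(s_u) * matrix(d, n_pts, 3, byrow = TRUE) - s_d * u
    t_ud <- rowSums(tX * upd)
    t_cd <- tX %*% (C + D)
    cond3 <- t_ud * as.numeric(t_cd) > 0
    crossings <- crossings + as.integer(cond1 & cond2 & cond3)
  }
  crossings %% 2L == 0L
}

#' Percent coverage per region
#'
#' @param partition a `head_partition`.
#' @param covered numeric vector from [covered_region()] (covered area
#'   fraction per face of `partition$mesh`).
#' @return tibble with one row per region (AL, AM, PL, PM, Ant, Post, TC):
#'   `total_area` and `covered_area` (mm^2) and `percent`
#'   (100 * covered / total).
#' @export
coverage_report <- function(partition, covered) {
  stopifnot(inherits(partition, "head_partition"),
            length(covered) == nrow(partition$mesh$faces))
  a <- face_areas(partition$mesh)
  ca <- a * covered
  reg <- partition$region
  tot <- tapply(a, reg, sum, default = 0)
  cov <- tapply(ca, reg, sum, default = 0)
  add <- function(name, regions) {
    t <- sum(tot[regions]); cc <- sum(cov[regions])
    tibble::tibble(region = name, total_area = t, covered_area = cc,
                   percent = if (t > 0) 100 * cc / t else NA_real_)
  }
  dplyr::bind_rows(
    tibble::tibble(region = names(tot),
                   total_area = as.numeric(tot),
                   covered_area = as.numeric(cov),
                   percent = ifelse(tot > 0, 100 * as.numeric(cov) /
                                      as.numeric(tot), NA_real_)),
    add("Ant", c("AL", "AM")),
    add("Post", c("PL", "PM")),
    add("TC", c("AL", "AM", "PL", "PM")))
}

#' Full 3D coverage pipeline for one hip
#'
#' Runs the complete measurement chain on a femur mesh and rim curve:
#' principal-curvature estimation, head sphere fit on spherical (umbilic)
#' vertices, head-neck junction detection and head cut, narrowest-neck and
#' shaft centers, region planes and partition, rim projection, covered
#' classification and the percent-coverage report.
#'
#' @param mesh proximal femur `surface_mesh`.
#' @param rim acetabular `rim_curve` (same frame as `mesh`, mm).
#' @param neighborhood_radius curvature fitting radius, mm (default 2.5 x
#'   mean edge length).
#' @param rim_samples rim spline sampling density.
#' @param neck_step neck scan step, mm.
#' @param interior covered-side witness direction, see [covered_region()].
#' @return object of class `head_coverage`: list with `report` (tibble from
#'   [coverage_report()]), `head_sphere`, `junction`, `planes`, `partition`,
#'   `covered`, `curve`, and the `centers` used.
#' @export
head_coverage <- function(mesh, rim, neighborhood_radius = NULL,
                          rim_samples = 512, neck_step = 0.5,
                          interior = c(-1, 0, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(rim, "rim_curve"))
  curv <- estimate_curvature(mesh, neighborhood_radius)
  sph <- estimate_head_sphere(mesh, curv)
  jn <- detect_head_neck_junction(mesh, curv, sph)
  sph2 <- fit_sphere(jn$head_mesh$vertices)
  ## shaft center: centroid of the distal quarter (by distance from head)
  dist <- rownorms(sweep(mesh$vertices, 2, sph2$center))
  distal <- dist > 0.75 * max(dist)
  shaft_center <- colMeans(mesh$vertices[distal, , drop = FALSE])
  ## two-pass neck scan: first along the head-to-shaft line, then refined
  ## along the head-to-neck-center line (closer to the true neck axis)
  axis_dir <- unitv(shaft_center - sph2$center)
  nk <- narrowest_neck_center(mesh, sph2$center, axis_dir, step = neck_step)
  axis2 <- nk$center - sph2$center
  if (vnorm(axis2) > 1e-6)
    nk <- narrowest_neck_center(mesh, sph2$center, unitv(axis2),
                                step = neck_step)
  planes <- region_planes(sph2$center, nk$center, shaft_center)
  part <- partition_head(jn$head_mesh, planes)
  curve <- project_rim(rim, jn$head_mesh, n_samples = rim_samples)
  covered <- covered_region(part$mesh, curve, sph2, rim, interior = interior)
  rep <- coverage_report(part, covered)
  structure(list(report = rep, head_sphere = sph2, junction = jn,
                 planes = planes, partition = part, covered = covered,
                 curve = curve,
                 centers = list(head = sph2$center, neck = nk$center,
                                shaft = shaft_center)),
            class = "head_coverage")
}

#' @export
tidy.head_coverage <- function(x, ...) x$report

#' @export
glance.head_coverage <- function(x, ...) {
  r <- x$report
  tibble::tibble(tc = r$percent[r$region == "TC"],
                 ant = r$percent[r$region == "Ant"],
                 post = r$percent[r$region == "Post"],
                 head_radius = x$head_sphere$radius,
                 head_area = r$total_area[r$region == "TC"])
}

#' @export
print.head_coverage <- function(x, ...) {
  cat("<head_coverage>\n")
  print(as.data.frame(x$report), row.names = FALSE, digits = 4)
  invisible(x)
}

## robust head sphere estimate from the curvature field: spherical vertices
## are umbilic (k1 ~ k2 > 0); fit a sphere to them with one trim pass
estimate_head_sphere <- function(mesh, curv) {
  k1 <- curv$k1; k2 <- curv$k2
  sel <- which(!is.na(k1) & !is.na(k2) & k2 > 0 &
                 (k1 - k2) < 0.35 * pmax(k1, 1e-9))
  if (length(sel) < 50) stop("too few spherical vertices to locate the head")
  kmed <- median((k1[sel] + k2[sel]) / 2)
  sel <- sel[abs((k1[sel] + k2[sel]) / 2 - kmed) < 0.25 * kmed]
  fs <- fit_sphere(mesh$vertices[sel, , drop = FALSE])
  res <- abs(rownorms(sweep(mesh$vertices[sel, , drop = FALSE], 2,
                            fs$center)) - fs$radius)
  s <- mad(res)
  if (s > 0) {
    keep <- res <= median(res) + 2.5 * s
    if (sum(keep) >= 50)
      fs <- fit_sphere(mesh$vertices[sel[keep], , drop = FALSE])
  }
  fs
}
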
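## Programmatic fixtures shared across the suite.

## lat-long sphere mesh (closed, outward winding)
uv_sphere_mesh <- function(R = 25, n_target = 10000, center = c(0, 0, 0)) {
  k <- as.integer(round(sqrt(n_target / 2)))
  kk <- 2L * k
  th <- pi * seq_len(kk - 1) / kk
  rings <- lapply(th, function(t)
    cbind(R * sin(t) * cos(2 * pi * (0:(kk - 1)) / kk),
          R * sin(t) * sin(2 * pi * (0:(kk - 1)) / kk),
          R * cos(t)))
  verts <- rbind(c(0, 0, R), do.call(rbind, rings), c(0, 0, -R))
  verts <- sweep(verts, 2, center, "+")
  ridx <- function(j) 1L + (j - 1L) * kk + seq_len(kk)
  fcs <- list(cbind(1L, ridx(1)[c(2:kk, 1)], ridx(1)))
  for (j in seq_len(length(th) - 1)) {
    a <- ridx(j); b <- ridx(j + 1)
    an <- a[c(2:kk, 1)]; bn <- b[c(2:kk, 1)]
    fcs[[j + 1]] <- rbind(cbind(a, bn, b), cbind(a, an, bn))
  }
  fcs[[length(th) + 1]] <- cbind(nrow(verts), ridx(length(th)),
                                 ridx(length(th))[c(2:kk, 1)])
  m <- surface_mesh(verts, do.call(rbind, fcs), clean = FALSE)
  if (hipcov:::mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

## closed cylinder mesh along +z, radius r, z in [z0, z1]
cylinder_mesh <- function(r = 15, z0 = -40, z1 = 40, n_phi = 96, n_z = 60) {
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  zs <- seq(z0, z1, length.out = n_z)
  rings <- lapply(zs, function(z) cbind(r * cos(phi), r * sin(phi),
                                        rep(z, n_phi)))
  verts <- rbind(c(0, 0, z0), do.call(rbind, rings), c(0, 0, z1))
  ridx <- function(j) 1L + (j - 1L) * n_phi + seq_len(n_phi)
  fcs <- list(cbind(1L, ridx(1), ridx(1)[c(2:n_phi, 1)]))
  for (j in seq_len(n_z - 1)) {
    a <- ridx(j); b <- ridx(j + 1)
    an <- a[c(2:n_phi, 1)]; bn <- b[c(2:n_phi, 1)]
    fcs[[j + 1]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
  }
  fcs[[n_z + 1]] <- cbind(nrow(verts), ridx(n_z)[c(2:n_phi, 1)], ridx(n_z))
  m <- surface_mesh(verts, do.call(rbind, fcs), clean = FALSE)
  if (hipcov:::mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

## surface of revolution rho(z) along z (closed with end fans)
revolution_mesh <- function(rho_fun, z0, z1, n_phi = 96, n_z = 120) {
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  zs <- seq(z0, z1, length.out = n_z)
  rings <- lapply(zs, function(z) cbind(rho_fun(z) * cos(phi),
                                        rho_fun(z) * sin(phi),
                                        rep(z, n_phi)))
  verts <- rbind(c(0, 0, z0), do.call(rbind, rings), c(0, 0, z1))
  ridx <- function(j) 1L + (j - 1L) * n_phi + seq_len(n_phi)
  fcs <- list(cbind(1L, ridx(1), ridx(1)[c(2:n_phi, 1)]))
  for (j in seq_len(n_z - 1)) {
    a <- ridx(j); b <- ridx(j + 1)
    an <- a[c(2:n_phi, 1)]; bn <- b[c(2:n_phi, 1)]
    fcs[[j + 1]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
  }
  fcs[[n_z + 1]] <- cbind(nrow(verts), ridx(n_z)[c(2:n_phi, 1)], ridx(n_z))
  m <- surface_mesh(verts, do.call(rbind, fcs), clean = FALSE)
  if (hipcov:::mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

## circular rim at polar angle theta_c (deg) about pole `axis`, radius rad
concentric_rim <- function(theta_c, axis = c(-1, 0, 0), rad = 25,
                           center = c(0, 0, 0), n = 64) {
  axis <- axis / sqrt(sum(axis^2))
  u1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u1 <- u1 - sum(u1 * axis) * axis
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(axis[2] * u1[3] - axis[3] * u1[2],
          axis[3] * u1[1] - axis[1] * u1[3],
          axis[1] * u1[2] - axis[2] * u1[1])
  t <- 2 * pi * (seq_len(n) - 1) / n
  th <- theta_c * pi / 180
  pts <- rad * (outer(sin(th) * cos(t), u1) + outer(sin(th) * sin(t), u2) +
                  outer(rep(cos(th), n), axis))
  rim_curve(sweep(pts, 2, center, "+"))
}

## region planes through `center` with plane1 = y-divider, plane2 = x-divider
centered_planes <- function(center = c(0, 0, 0)) {
  region_planes(center, center + c(30, 0, -20), center + c(40, 0, -100))
}

## hand-built landmark set for the 2D measures (right hip, h = (1, 0);
## lateral = -x in image coordinates)
basic_landmarks <- function(head_center = c(0, 0), head_radius = 25,
                            lateral_sourcil = NULL, medial_sourcil = c(15, 22),
                            teardrop = c(18, -20),
                            anterior_wall = NULL, posterior_wall = NULL,
                            lateral_rim = NULL,
                            obt = c(30, 30), side = "right") {
  lat <- c(-1, 0); sup <- c(0, 1)
  if (is.null(lateral_sourcil))
    lateral_sourcil <- head_center + head_radius * (0.5 * lat + sqrt(0.75) * sup)
  if (is.null(lateral_rim)) lateral_rim <- lateral_sourcil
  if (is.null(posterior_wall))
    posterior_wall <- rbind(lateral_rim, lateral_rim + c(10, -20),
                            teardrop + c(0, 10), teardrop)
  if (is.null(anterior_wall))
    anterior_wall <- rbind(lateral_rim, lateral_rim + c(14, -18),
                           teardrop + c(2, 12), teardrop)
  radiograph_landmarks(
    head_circle = list(center = head_center, radius = head_radius),
    lateral_sourcil = lateral_sourcil, medial_sourcil = medial_sourcil,
    teardrop = teardrop, teardrop_contralateral = teardrop + c(120, 0),
    lateral_rim = lateral_rim,
    anterior_wall = anterior_wall, posterior_wall = posterior_wall,
    obturator_width_ipsi = obt[1], obturator_width_contra = obt[2],
    horizontal_ref = c(1, 0), side = side)
}

## mirror a landmark set across the vertical axis u = const and swap side
mirror_landmarks <- function(lm, axis_u = 0) {
  mir2 <- function(p) c(2 * axis_u - p[1], p[2])
  mirw <- function(W) cbind(2 * axis_u - W[, 1], W[, 2])
  radiograph_landmarks(
    head_circle = list(center = mir2(lm$head_circle$center),
                       radius = lm$head_circle$radius),
    lateral_sourcil = mir2(lm$lateral_sourcil),
    medial_sourcil = mir2(lm$medial_sourcil),
    teardrop = mir2(lm$teardrop),
    teardrop_contralateral = mir2(lm$teardrop_contralateral),
    lateral_rim = mir2(lm$lateral_rim),
    anterior_wall = mirw(lm$anterior_wall),
    posterior_wall = mirw(lm$posterior_wall),
    obturator_width_ipsi = lm$obturator_width_ipsi,
    obturator_width_contra = lm$obturator_width_contra,
    horizontal_ref = c(-lm$horizontal_ref[1], lm$horizontal_ref[2]),
    side = if (lm$side == "right") "left" else "right")
}

## rigid in-plane transform of a landmark set (rotation deg + translation)
transform_landmarks <- function(lm, angle_deg = 0, shift = c(0, 0)) {
  a <- angle_deg * pi / 180
  Rm <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
  tr2 <- function(p) as.numeric(Rm %*% p + shift)
  trw <- function(W) t(apply(W, 1, tr2))
  trd <- function(d) as.numeric(Rm %*% d)
  radiograph_landmarks(
    head_circle = list(center = tr2(lm$head_circle$center),
                       radius = lm$head_circle$radius),
    lateral_sourcil = tr2(lm$lateral_sourcil),
    medial_sourcil = tr2(lm$medial_sourcil),
    teardrop = tr2(lm$teardrop),
    teardrop_contralateral = tr2(lm$teardrop_contralateral),
    lateral_rim = tr2(lm$lateral_rim),
    anterior_wall = trw(lm$anterior_wall),
    posterior_wall = trw(lm$posterior_wall),
    obturator_width_ipsi = lm$obturator_width_ipsi,
    obturator_width_contra = lm$obturator_width_contra,
    horizontal_ref = trd(lm$horizontal_ref),
    side = lm$side)
}

## independent two-way ANOVA mean-square oracle for the ICC
aov_icc_oracle <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.numeric(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

## percent coverage for one region name from a report tibble
pct <- function(report, region) report$percent[report$region == region]

## densify a polyline to n points (linear interpolation by arclength)
densify_polyline <- function(W, n = 41) {
  arc <- c(0, cumsum(sqrt(rowSums(diff(W)^2))))
  s <- seq(0, arc[length(arc)], length.out = n)
  cbind(approx(arc, W[, 1], xout = s)$y, approx(arc, W[, 2], xout = s)$y)
}

## chord-length parameter values used by rim_curve for its control points
attr_chord <- function(pts) {
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  head(c(0, cumsum(seg)) / sum(seg), -1)
}
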
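test_that("the detected junction plane sits at the analytic tangency circle", {
  p <- hip_params(mesh_resolution = 5000, rim_saddle_deg = 0,
                  rim_recess_deg = 0)
  m <- hipcov:::build_femur_mesh(p)
  cf <- estimate_curvature(m)
  sph <- hipcov:::estimate_head_sphere(m, cf)
  jn <- detect_head_neck_junction(m, cf, sph)
  tp <- true_junction_plane(p)
  n <- hipcov:::neck_direction(p)
  offset <- sum(jn$plane$point * n) - sum(tp$point * n)
  expect_lt(abs(offset), 2)
  expect_gt(abs(sum(jn$plane$normal * tp$normal)), 0.995)
  ## head mesh lies on the head side and contains the apex
  d <- hipcov:::plane_signed_distance(jn$plane, jn$head_mesh$vertices)
  expect_gt(min(d), -1e-6)
  apex <- p$head_center - p$head_radius * n
  expect_lt(min(sqrt(rowSums(sweep(jn$head_mesh$vertices, 2, apex)^2))), 2)
})

test_that("an isolated sphere has no inflection ring", {
  m <- uv_sphere_mesh(25, 4000)
  cf <- estimate_curvature(m)
  sph <- list(center = c(0, 0, 0), radius = 25)
  expect_error(detect_head_neck_junction(m, cf, sph,
                                         neck_direction = c(0, 0, -1)),
               "no inflection ring")
})

test_that("the narrowest neck section of a cylinder has the analytic area", {
  cyl <- cylinder_mesh(r = 15, z0 = 0, z1 = 100, n_phi = 128, n_z = 100)
  nk <- narrowest_neck_center(cyl, c(0, 0, -20), c(0, 0, 1),
                              range = c(0.3, 0.7))
  expect_lt(abs(nk$area - pi * 15^2) / (pi * 15^2), 0.02)
  expect_lt(sqrt(sum(nk$center[1:2]^2)), 0.5)
})

test_that("an hourglass solid's narrowest section is found at its waist", {
  m <- revolution_mesh(function(z) 10 + 0.1 * z^2, -20, 20)
  nk <- narrowest_neck_center(m, c(0, 0, -20), c(0, 0, 1),
                              range = c(0.2, 0.8))
  expect_lt(abs(nk$center[3]), 0.5)
  expect_lt(abs(nk$area - pi * 100) / (pi * 100), 0.03)
})

test_that("the neck scan is stable in its step size", {
  m <- revolution_mesh(function(z) 12 + 0.05 * (z - 3)^2, -25, 25)
  a <- narrowest_neck_center(m, c(0, 0, -25), c(0, 0, 1), step = 0.5,
                             range = c(0.2, 0.8))
  b <- narrowest_neck_center(m, c(0, 0, -25), c(0, 0, 1), step = 0.25,
                             range = c(0.2, 0.8))
  expect_lt(sqrt(sum((a$center - b$center)^2)), 0.5)
})
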
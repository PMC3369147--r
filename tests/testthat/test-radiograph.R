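hs25 <- list(center = c(0, 0, 0), radius = 25)

proj_lm <- function(params, tilt = 0, rot = 0) {
  rim <- rim_curve(hipcov:::build_rim_points(params))
  project_to_radiograph(NULL, rim, pelvic_tilt = tilt, pelvic_rotation = rot,
                        head_sphere = list(center = params$head_center,
                                           radius = params$head_radius))
}

test_that("a symmetric unperturbed cup projects without a crossover", {
  p <- hip_params(cup_version = 0, rim_saddle_deg = 0, rim_recess_deg = 0,
                  mesh_resolution = 600)
  lm <- proj_lm(p)
  expect_true(is.na(crossover_ratio(lm)))
})

test_that("retroverted cups cross over and anteverted cups do not", {
  lm_retro <- proj_lm(hip_params(cup_version = -20, cup_depth_angle = 90,
                                 mesh_resolution = 600))
  expect_true(is.finite(crossover_ratio(lm_retro)))
  lm_ante <- proj_lm(hip_params(cup_version = 15, mesh_resolution = 600))
  expect_true(is.na(crossover_ratio(lm_ante)))
})

test_that("the crossover ratio trends monotonically with pelvic tilt", {
  p <- hip_params(cup_version = -10, mesh_resolution = 600)
  tilts <- seq(0, 10, 2.5)
  cors <- sapply(tilts, function(t) crossover_ratio(proj_lm(p, tilt = t)))
  expect_true(all(is.finite(cors)))
  expect_true(all(diff(cors) < 0))
})

test_that("LCEA from projected landmarks increases with cup depth", {
  lc <- sapply(c(80, 88, 96, 104), function(d)
    lcea(proj_lm(hip_params(cup_depth_angle = d, mesh_resolution = 600))))
  expect_true(all(diff(lc) > 0))
})

test_that("crossover presence round-trips with the generator flag", {
  for (v in c(12, 18, -6, -16)) {
    p <- hip_params(cup_version = v, mesh_resolution = 600)
    hip <- generate_hip(p, seed = 4, gt_samples = 1e4)
    lm <- project_to_radiograph(NULL, hip$rim,
                                head_sphere = list(center = p$head_center,
                                                   radius = p$head_radius))
    expect_equal(is.finite(crossover_ratio(lm)),
                 hip$ground_truth$crossover_expected)
    expect_equal(hip$ground_truth$crossover_expected, v < 0)
  }
})

test_that("the projected head circle is recovered from the mesh when needed", {
  p <- hip_params(mesh_resolution = 4000)
  m <- hipcov:::build_femur_mesh(p)
  rim <- rim_curve(hipcov:::build_rim_points(p))
  lm <- project_to_radiograph(m, rim)
  expect_equal(lm$head_circle$radius, 25, tolerance = 0.2)
  expect_equal(lm$head_circle$center, c(0, 0), tolerance = 0.2)
})

test_that("excessive pelvic orientation and degenerate rims are rejected", {
  p <- hip_params(mesh_resolution = 600)
  rim <- rim_curve(hipcov:::build_rim_points(p))
  expect_error(project_to_radiograph(NULL, rim, pelvic_tilt = 45,
                                     head_sphere = hs25), "within")
  expect_error(project_to_radiograph(NULL, rim, head_sphere = NULL),
               "mesh or a head_sphere")
})

test_that("pelvic rotation drives the obturator adequacy screen", {
  p <- hip_params(mesh_resolution = 600)
  lm0 <- proj_lm(p, rot = 0)
  expect_true(obturator_index(lm0)$pass)
  lm_rot <- proj_lm(p, rot = 12)
  expect_false(obturator_index(lm_rot)$pass)
})
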
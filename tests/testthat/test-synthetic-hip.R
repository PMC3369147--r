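test_that("parameter validation rejects degenerate hips", {
  expect_error(hip_params(cup_depth_angle = 180), "cup_depth_angle")
  expect_error(hip_params(neck_radius = 30), "head_radius > neck_radius")
  expect_error(hip_params(mesh_resolution = 100), "mesh_resolution")
  expect_error(hip_params(cup_radius = 20), "cup_radius")
})

test_that("analytic total coverage matches the spherical-cap closed form", {
  for (thc in c(30, 60, 90, 120)) {
    p <- hip_params(cup_depth_angle = thc, rim_saddle_deg = 0,
                    rim_recess_deg = 0, mesh_resolution = 600)
    expect_equal(hipcov:::analytic_total_coverage(p),
                 100 * (1 - cos(thc * pi / 180)) / 2, tolerance = 1e-9)
  }
  ## a hemispherical rim keeps 50% under any undulation (mean of cos
  ## vanishes at 90 degrees only for the saddle, not the recess)
  p90 <- hip_params(cup_depth_angle = 90, rim_saddle_deg = 8,
                    rim_recess_deg = 0, mesh_resolution = 600)
  expect_gt(hipcov:::analytic_total_coverage(p90), 49.9)
})

test_that("ground truth coverage is area-weighted-consistent and symmetric", {
  p <- hip_params(cup_version = 0, cup_inclination = 0, rim_saddle_deg = 0,
                  rim_recess_deg = 0, mesh_resolution = 600)
  mc <- mc_region_coverage(p, n_samples = 4e5, seed = 2)
  w <- mc$area_frac[match(c("AL", "AM", "PL", "PM"), mc$region)]
  v <- mc$percent[match(c("AL", "AM", "PL", "PM"), mc$region)]
  tc <- unname(mc$percent[mc$region == "TC"])
  expect_equal(sum(w * v) / sum(w), tc, tolerance = 1e-9)
  expect_equal(tc, hipcov:::analytic_total_coverage(p), tolerance = 0.3)
  ## version-0 mirror symmetry: anterior and posterior twins agree
  expect_lt(abs(v[1] - v[3]), 0.5)  # AL vs PL
  expect_lt(abs(v[2] - v[4]), 0.5)  # AM vs PM
})

test_that("hips and cohorts are deterministic given their seeds", {
  p <- hip_params(mesh_resolution = 1000)
  h1 <- generate_hip(p, seed = 5, gt_samples = 2e4)
  h2 <- generate_hip(p, seed = 5, gt_samples = 2e4)
  expect_identical(h1$mesh, h2$mesh)
  expect_identical(h1$rim$points, h2$rim$points)
  expect_identical(h1$ground_truth, h2$ground_truth)

  spec <- cohort_spec(n_controls = 3, n_patients = 3, seed = 77)
  c1 <- generate_cohort(spec, include_mesh = FALSE)
  c2 <- generate_cohort(spec, include_mesh = FALSE)
  expect_identical(c1$true_version, c2$true_version)
  expect_identical(c1$landmarks[[1]]$landmarks[[2]],
                   c2$landmarks[[1]]$landmarks[[2]])
})

test_that("the cohort generator reflects the group construction", {
  spec <- cohort_spec(seed = 42)
  coh <- generate_cohort(spec, include_mesh = FALSE)
  expect_equal(nrow(coh), 34)
  expect_equal(sum(coh$group == "control"), 18)
  expect_equal(sum(coh$group == "patient"), 16)
  expect_true(all(coh$true_version[coh$group == "patient"] < 0))
  expect_true(all(coh$true_version[coh$group == "control"] > 0))
  expect_true(all(coh$crossover_expected[coh$group == "patient"]))
  expect_false(any(coh$crossover_expected[coh$group == "control"]))
})

test_that("zero reader noise makes all reads identical with ICC 1", {
  spec <- cohort_spec(n_controls = 6, n_patients = 6, reader_noise_sd = 0,
                      seed = 3)
  res <- run_cohort(spec, include_3d = FALSE)
  icc_tbl <- res$icc_table
  vals <- unlist(icc_tbl[icc_tbl$measure == "posterior_wall_distance", -1])
  expect_true(all(abs(vals - 1) < 1e-9))
  ## per-read measures are identical across reads
  pr <- res$measures_by_read
  w <- tidyr::pivot_wider(pr[, c("subject", "reader", "read", "lcea")],
                          names_from = c("reader", "read"),
                          values_from = "lcea")
  expect_equal(w[[2]], w[[3]], tolerance = 1e-12)
  expect_equal(w[[2]], w[[5]], tolerance = 1e-12)
})

test_that("the ground-truth junction plane matches the mesh construction", {
  p <- hip_params(mesh_resolution = 2000)
  m <- hipcov:::build_femur_mesh(p)
  tp <- true_junction_plane(p)
  ## the mesh has a vertex ring essentially on the plane
  d <- hipcov:::plane_signed_distance(tp, m$vertices)
  expect_lt(min(abs(d)), 0.3)
  ## and the head sphere's apex is on the positive side
  n <- hipcov:::neck_direction(p)
  apex <- p$head_center - p$head_radius * n
  expect_gt(hipcov:::plane_signed_distance(tp, rbind(apex)), 0)
})
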
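sphere_fixture <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- uv_sphere_mesh(25, 12000)
    m
  }
})

test_that("projecting a concentric rim lands on its great circle", {
  m <- sphere_fixture()
  rim <- concentric_rim(90, rad = 25)
  curve <- project_rim(rim, m)
  ## points on the x = 0 great circle (pole -x): |x| below one edge length
  expect_lt(max(abs(curve[, 1])), hipcov:::mean_edge_length(m))
})

test_that("rim projection is invariant to radial rim displacement", {
  m <- sphere_fixture()
  c1 <- project_rim(concentric_rim(75, rad = 25.5), m)
  c2 <- project_rim(concentric_rim(75, rad = 30), m)
  ## on a faceted sphere the radial-invariance is exact up to the facet
  ## scale: compare point-wise within one mean edge length
  expect_equal(nrow(c1), nrow(c2))
  dev <- max(sqrt(rowSums((c1 - c2)^2)))
  expect_lt(dev, hipcov:::mean_edge_length(m))
})

test_that("coverage percent is stable in the rim sampling density", {
  m <- sphere_fixture()
  rim <- concentric_rim(75, rad = 27)
  part <- partition_head(m, centered_planes())
  hs <- list(center = c(0, 0, 0), radius = 25)
  tc <- sapply(c(256, 1024), function(ns) {
    curve <- project_rim(rim, m, n_samples = ns)
    cov <- covered_region(part$mesh, curve, hs, rim)
    pct(coverage_report(part, cov), "TC")
  })
  expect_lt(abs(tc[1] - tc[2]), 0.2)
})

test_that("concentric caps reproduce the spherical-cap closed form", {
  m <- sphere_fixture()
  part <- partition_head(m, centered_planes())
  hs <- list(center = c(0, 0, 0), radius = 25)
  for (thc in c(60, 90)) {
    rim <- concentric_rim(thc, rad = 27)
    curve <- project_rim(rim, m)
    cov <- covered_region(part$mesh, curve, hs, rim)
    rep <- coverage_report(part, cov)
    expect_lt(abs(pct(rep, "TC") - 100 * (1 - cos(thc * pi / 180)) / 2), 1)
    ## conservation of covered area across regions
    expect_lt(abs(sum(rep$covered_area[1:4]) -
                    rep$covered_area[rep$region == "TC"]),
              1e-9 * max(rep$covered_area[rep$region == "TC"], 1))
  }
})

test_that("a laterally tilted hemispheric cup shifts lateral/medial balance only", {
  m <- sphere_fixture()
  part <- partition_head(m, centered_planes())
  hs <- list(center = c(0, 0, 0), radius = 25)
  ## pole tilted 10 degrees superiorly from medial: rotation about +y
  pole <- c(-cos(10 * pi / 180), 0, sin(10 * pi / 180))
  rim <- concentric_rim(90, axis = pole, rad = 27)
  curve <- project_rim(rim, m)
  cov <- covered_region(part$mesh, curve, hs, rim, interior = pole)
  rep <- coverage_report(part, cov)
  expect_lt(abs(pct(rep, "TC") - 50), 1)
})

test_that("degenerate reports: fully covered and fully uncovered heads", {
  m <- uv_sphere_mesh(25, 3000)
  part <- partition_head(m, centered_planes())
  rep1 <- coverage_report(part, rep(1, nrow(part$mesh$faces)))
  expect_true(all(abs(rep1$percent - 100) < 1e-12))
  rep0 <- coverage_report(part, rep(0, nrow(part$mesh$faces)))
  expect_true(all(abs(rep0$percent) < 1e-12))
})

test_that("a rim far from the head is rejected", {
  m <- uv_sphere_mesh(25, 2000)
  rim <- concentric_rim(90, rad = 500)
  expect_error(project_rim(rim, m), "head")
})
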
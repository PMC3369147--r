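test_that("region planes follow the three-center construction", {
  pl <- region_planes(c(0, 0, 0), c(30, 0, -20), c(40, 0, -100))
  expect_equal(pl$plane1$normal, c(0, 1, 0), tolerance = 1e-12)
  ## plane2 normal: unit component of (0,0,0)-(30,0,-20) orthogonal to
  ## (0,1,0), oriented medially
  expect_equal(pl$plane2$normal,
               c(-30, 0, 20) / sqrt(30^2 + 20^2), tolerance = 1e-12)
  expect_equal(sum(pl$plane1$normal * pl$plane2$normal), 0,
               tolerance = 1e-12)
  expect_error(region_planes(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})

test_that("plane normals are orthogonal for arbitrary valid centers", {
  set.seed(3)
  for (i in 1:20) {
    hc <- rnorm(3); nc <- hc + rnorm(3, sd = 10); sc <- hc + rnorm(3, sd = 30)
    pl <- tryCatch(region_planes(hc, nc, sc), error = function(e) NULL)
    if (is.null(pl)) next
    expect_lt(abs(sum(pl$plane1$normal * pl$plane2$normal)), 1e-9)
  }
})

test_that("centered planes quarter a sphere and conserve area exactly", {
  m <- uv_sphere_mesh(25, 10000)
  part <- partition_head(m, centered_planes())
  a <- tapply(face_areas(part$mesh), part$region, sum)
  expect_equal(length(a), 4L)
  for (r in names(a))
    expect_lt(abs(a[[r]] - pi * 25^2) / (pi * 25^2), 0.005)
  expect_lt(abs(sum(a) - sum(face_areas(m))) / sum(face_areas(m)), 1e-9)
})

test_that("shifting the lateral/medial divider moves area between regions", {
  m <- uv_sphere_mesh(25, 6000)
  ## axis-aligned dividers: plane1 = y-plane, plane2 normal = -x
  pl0 <- region_planes(c(0, 0, 0), c(30, 0, 0), c(30, 0, -100))
  part0 <- partition_head(m, pl0)
  a0 <- tapply(face_areas(part0$mesh), part0$region, sum)
  ## translate plane2 laterally (+x) by 5 mm: lateral regions shrink
  pl1 <- pl0
  pl1$plane2$point <- pl1$plane2$point + c(5, 0, 0)
  part1 <- partition_head(m, pl1)
  a1 <- tapply(face_areas(part1$mesh), part1$region, sum)
  expect_lt(a1[["AL"]], a0[["AL"]])
  expect_lt(a1[["PL"]], a0[["PL"]])
  expect_gt(a1[["AM"]], a0[["AM"]])
  expect_gt(a1[["PM"]], a0[["PM"]])
  expect_equal(sum(a1), sum(a0), tolerance = 1e-9)
  ## lateral pair matches the spherical-zone closed form: the zone beyond
  ## x = 5 has area 2 pi R h with h = R - 5
  expect_lt(abs((a1[["AL"]] + a1[["PL"]]) - 2 * pi * 25 * 20) /
              (2 * pi * 25 * 20), 0.005)
})
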
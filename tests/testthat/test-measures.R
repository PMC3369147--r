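test_that("extrusion index follows its hand-derived values and clamps", {
  ## head radius 25 (diameter 50), lateral edge 5 mm lateral of sourcil
  lm <- basic_landmarks(lateral_sourcil = c(-20, 10))
  expect_equal(extrusion_index(lm), 5 / 50, tolerance = 1e-12)
  ## sourcil lateral to the head edge clamps at 0
  lm0 <- basic_landmarks(lateral_sourcil = c(-30, 10))
  expect_equal(extrusion_index(lm0), 0)
  ## a = 20, diameter 100
  lm2 <- basic_landmarks(head_radius = 50, lateral_sourcil = c(-30, 10))
  expect_equal(extrusion_index(lm2), 0.2, tolerance = 1e-12)
})

test_that("LCEA measures the sourcil angle from vertical with lateral positive", {
  s30 <- 25 * c(-sin(pi / 6), cos(pi / 6))
  expect_equal(lcea(basic_landmarks(lateral_sourcil = s30)), 30,
               tolerance = 1e-9)
  expect_equal(lcea(basic_landmarks(lateral_sourcil = c(0, 25))), 0,
               tolerance = 1e-12)
  s_med <- 25 * c(sin(pi / 18), cos(pi / 18))
  expect_equal(lcea(basic_landmarks(lateral_sourcil = s_med)), -10,
               tolerance = 1e-9)
})

test_that("acetabular index and angle follow the horizontal-reference convention", {
  ## medial (0,0), lateral 10 mm lateral and level: 0 degrees
  lm <- basic_landmarks(medial_sourcil = c(0, 0), lateral_sourcil = c(-10, 0))
  expect_equal(acetabular_index(lm), 0, tolerance = 1e-12)
  ## lateral end superior by 1.763 over 10: atan(0.1763)
  lm1 <- basic_landmarks(medial_sourcil = c(0, 0),
                         lateral_sourcil = c(-10, 1.763))
  expect_equal(acetabular_index(lm1), atan(0.1763) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(acetabular_index(lm1), 10, tolerance = 0.01)
  ## lateral end inferior: negative
  lm2 <- basic_landmarks(medial_sourcil = c(0, 0),
                         lateral_sourcil = c(-10, -2))
  expect_lt(acetabular_index(lm2), 0)

  ## acetabular angle: teardrop (0,0), sourcil 20 lateral, 16.78 superior
  lm3 <- basic_landmarks(teardrop = c(0, 0), lateral_sourcil = c(-20, 16.78))
  expect_equal(acetabular_angle(lm3), atan(16.78 / 20) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(acetabular_angle(lm3), 40, tolerance = 0.05)
  lm4 <- basic_landmarks(teardrop = c(0, -20), lateral_sourcil = c(-20, -20))
  expect_equal(acetabular_angle(lm4), 0, tolerance = 1e-12)
  lm5 <- basic_landmarks(teardrop = c(0, -20), lateral_sourcil = c(0, 0))
  expect_equal(acetabular_angle(lm5), 90, tolerance = 1e-9)
})

test_that("crossover ratio detects transversal crossings with the right ratio", {
  ## walls that never cross
  lr <- c(-20, 15); td <- c(10, -25)
  aw <- densify_polyline(rbind(lr + c(0, 2), lr + c(6, -12),
                               td + c(3, 10), td + c(2, 1)))
  pw <- densify_polyline(rbind(lr + c(2, 4), lr + c(12, -10),
                               td + c(8, 12), td + c(6, 2)))
  lm <- basic_landmarks(lateral_rim = lr, teardrop = td,
                        anterior_wall = aw, posterior_wall = pw)
  expect_true(is.na(crossover_ratio(lm)))

  ## transversal crossing at a chosen point X on the lateral rim-teardrop
  ## line: a = 8, b = 80
  lr2 <- c(-30, 20)
  td2 <- lr2 + c(80, 0)  # b = 80 along +u
  diru <- (td2 - lr2) / sqrt(sum((td2 - lr2)^2))
  X <- lr2 + 8 * diru
  aw2 <- densify_polyline(rbind(X + c(-10, 10), X + c(10, -10)))
  pw2 <- densify_polyline(rbind(X + c(-10, -10), X + c(10, 10)))
  lm2 <- basic_landmarks(lateral_rim = lr2, teardrop = td2,
                         anterior_wall = aw2, posterior_wall = pw2)
  expect_equal(crossover_ratio(lm2), 0.10, tolerance = 1e-9)

  ## crossing at the lateral rim itself: ratio 0 (the walls pass through
  ## the rim mid-course, so the crossing sits inside the detection zone)
  X0 <- lr2
  aw3 <- densify_polyline(rbind(X0 + c(-10, 10), X0 + c(10, -10)))
  pw3 <- densify_polyline(rbind(X0 + c(-10, -10), X0 + c(10, 10)))
  lm3 <- basic_landmarks(lateral_rim = lr2, teardrop = td2,
                         anterior_wall = aw3, posterior_wall = pw3)
  expect_equal(crossover_ratio(lm3), 0, tolerance = 1e-9)
})

test_that("posterior wall distance is signed lateral-positive", {
  ## wall crossing 3.4 mm lateral of the center (lateral = -u)
  mk <- function(off) {
    x <- -off  # image u of the crossing point
    basic_landmarks(posterior_wall = rbind(c(x, 10), c(x, -10)))
  }
  expect_equal(posterior_wall_distance(mk(3.4)), 3.4, tolerance = 1e-12)
  expect_equal(posterior_wall_distance(mk(-5.9)), -5.9, tolerance = 1e-12)
  expect_equal(posterior_wall_distance(mk(0)), 0, tolerance = 1e-12)
  lm_no <- basic_landmarks(posterior_wall = rbind(c(0, 5), c(10, 8)))
  expect_error(posterior_wall_distance(lm_no), "does not cross")
})

test_that("the obturator index screen applies the inclusive 0.8-1.2 band", {
  expect_equal(obturator_index(basic_landmarks(obt = c(30, 30))),
               list(ratio = 1, pass = TRUE))
  oi <- obturator_index(basic_landmarks(obt = c(30, 40)))
  expect_equal(oi$ratio, 0.75, tolerance = 1e-12)
  expect_false(oi$pass)
  oi2 <- obturator_index(basic_landmarks(obt = c(36, 30)))
  expect_equal(oi2$ratio, 1.2, tolerance = 1e-12)
  expect_true(oi2$pass)
})

test_that("all measures are invariant under mirroring and rigid transforms", {
  lm <- basic_landmarks(lateral_sourcil = c(-18, 16),
                        medial_sourcil = c(10, 19))
  base <- measure_radiograph(lm)
  mirrored <- measure_radiograph(mirror_landmarks(lm))
  moved <- measure_radiograph(transform_landmarks(lm, 33, c(101, -47)))
  for (col in setdiff(names(base), "radiograph_adequate")) {
    if (is.na(base[[col]])) {
      expect_true(is.na(mirrored[[col]]))
      expect_true(is.na(moved[[col]]))
    } else {
      expect_equal(mirrored[[col]], base[[col]], tolerance = 1e-9)
      expect_equal(moved[[col]], base[[col]], tolerance = 1e-9)
    }
  }
})

test_that("landmark sets round-trip through JSON", {
  lm <- basic_landmarks()
  path <- file.path(tempdir(), "lm.json")
  write_landmarks_json(lm, path)
  lm2 <- read_landmarks_json(path)
  expect_equal(measure_radiograph(lm2), measure_radiograph(lm),
               tolerance = 1e-12)
  expect_equal(lm2$side, lm$side)
})
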
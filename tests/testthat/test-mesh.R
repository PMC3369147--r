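test_that("plane splitting conserves area exactly and separates sides", {
  m <- uv_sphere_mesh(25, 4000)
  a0 <- sum(face_areas(m))
  pl <- hipcov:::new_plane(c(3, 0, 0), c(1, 0.3, -0.2))
  s <- hipcov:::split_mesh_by_plane(m, pl)
  expect_equal(sum(face_areas(s)), a0, tolerance = 1e-12)
  side <- attr(s, "side")
  ctr <- hipcov:::face_centroids(s)
  d <- hipcov:::plane_signed_distance(pl, ctr)
  keep <- abs(d) > 1e-9
  expect_true(all(sign(d[keep]) == side[keep]))
})

test_that("cross-sections of a cylinder give the exact area and axial centroid", {
  cyl <- cylinder_mesh(r = 15, z0 = -40, z1 = 40)
  cs <- hipcov:::cross_section(cyl, hipcov:::new_plane(c(0, 0, 5), c(0, 0, 1)))
  expect_equal(cs$area, pi * 15^2, tolerance = 0.01 * pi * 15^2)
  expect_equal(cs$centroid[1:2], c(0, 0), tolerance = 1e-6)
  expect_equal(cs$centroid[3], 5, tolerance = 1e-9)
  expect_true(cs$closed)
})

test_that("synthetic femur meshes are watertight, edge-manifold and outward", {
  p <- hip_params(mesh_resolution = 2000)
  m <- hipcov:::build_femur_mesh(p)
  expect_true(hipcov:::is_watertight(m))
  expect_true(hipcov:::is_edge_manifold(m))
  expect_gt(hipcov:::mesh_volume(m), 0)
  expect_gte(nrow(m$vertices), 1500)
})

test_that("mesh files round-trip through PLY, OBJ and STL", {
  m <- uv_sphere_mesh(10, 300)
  for (ext in c("ply", "obj", "stl")) {
    path <- file.path(tempdir(), paste0("m.", ext))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(sum(face_areas(m2)), sum(face_areas(m)), tolerance = 1e-6)
    expect_equal(nrow(m2$faces), nrow(m$faces))
  }
  ## binary STL writes without error
  bpath <- file.path(tempdir(), "mb.stl")
  write_mesh(m, bpath, binary = TRUE)
  expect_gt(file.info(bpath)$size, 80)
})

test_that("rim curves round-trip through JSON and interpolate their points", {
  p <- hip_params(mesh_resolution = 2000)
  pts <- hipcov:::build_rim_points(p)
  path <- file.path(tempdir(), "rim.json")
  write_rim_json(pts, path)
  pts2 <- read_rim_json(path)
  expect_equal(pts2, unname(pts), tolerance = 1e-12)
  rim <- rim_curve(pts)
  ## the periodic spline passes through the control points
  s <- rim$spline(attr_chord(pts))
  expect_equal(s, unname(pts), tolerance = 1e-8)
})
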
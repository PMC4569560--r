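test_that("icosphere face counts and area convergence", {
  expect_equal(nrow(make_icosphere(um(4), 0)$faces), 20)
  expect_equal(nrow(make_icosphere(um(4), 3)$faces), 1280)
  expect_error(make_icosphere(-1e-6, 2), "positive")
  ## total area converges to 4 pi r^2 with monotone error decrease
  r <- um(4)
  err <- vapply(0:4, function(s)
    abs(mesh_area(make_icosphere(r, s)) - 4 * pi * r^2) / (4 * pi * r^2), 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[4], 0.02)  # subdivisions >= 3
  ## max edge decreases monotonically with subdivision
  edges <- vapply(0:4, function(s) mesh_max_edge(make_icosphere(r, s)), 0)
  expect_true(all(diff(edges) < 0))
})

test_that("icosphere is closed, outward oriented, centroid-on-surface", {
  m <- make_icosphere(um(4), 3)
  expect_equal(mesh_volume(m), 4 / 3 * pi * um(4)^3, tolerance = 0.01)
  expect_equal(mesh_volume_centroid(m), c(0, 0, 0), tolerance = 1e-12)
  cen <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
            m$vertices[m$faces[, 3], ]) / 3
  expect_equal(mean(sqrt(rowSums(cen^2))), um(4), tolerance = 1e-12)
})

test_that("PMN cap rests on the substrate with hemisphere centroid height", {
  cap <- make_pmn_cap(um(5), um(5), 8)
  expect_gte(min(cap$vertices[, 2]), 0)
  ## solid hemisphere centroid sits 3r/8 above the base
  expect_equal(mesh_volume_centroid(cap)[2], 3 * um(5) / 8, tolerance = 0.01)
  expect_equal(mesh_volume(cap), 2 / 3 * pi * um(5)^3, tolerance = 0.01)
  ## refinement monotonicity
  cap2 <- make_pmn_cap(um(5), um(5), 16)
  expect_gt(nrow(cap2$faces), nrow(cap$faces))
  expect_lt(max(triangle_areas_oracle(cap2)), max(triangle_areas_oracle(cap)))
  expect_error(make_pmn_cap(0, um(5)), "positive")
})

test_that("face properties transform rigidly", {
  m <- make_icosphere(um(2), 2)
  f0 <- face_properties(m)
  ## identity pose: world centroids equal body-frame centroids
  cen <- (m$vertices[m$faces[, 1], ] + m$vertices[m$faces[, 2], ] +
            m$vertices[m$faces[, 3], ]) / 3
  expect_equal(f0$centroids, cen, tolerance = 1e-14)
  ## pure translation shifts centroids, leaves areas and normals alone
  t <- c(1e-6, -2e-6, 3e-6)
  ft <- face_properties(m, list(x = t, q = quat_identity()))
  expect_equal(ft$centroids, sweep(f0$centroids, 2, t, "+"), tolerance = 1e-14)
  expect_equal(ft$areas, f0$areas, tolerance = 1e-12)
  expect_equal(ft$normals, f0$normals, tolerance = 1e-12)
  ## 90 degree rotation about z rotates normals, preserves total area and
  ## within-body distances
  qz <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  fr <- face_properties(m, list(x = c(0, 0, 0), q = qz))
  R <- quat_to_matrix(qz)
  expect_equal(fr$normals, f0$normals %*% t(R), tolerance = 1e-9)
  expect_equal(fr$areas, triangle_areas_oracle(m), tolerance = 1e-12)
  expect_equal(sum(fr$areas), sum(f0$areas), tolerance = 1e-12)
  i <- c(1, 5, 40); j <- c(7, 100, 200)
  d0 <- sqrt(rowSums((f0$centroids[i, ] - f0$centroids[j, ])^2))
  dr <- sqrt(rowSums((fr$centroids[i, ] - fr$centroids[j, ])^2))
  expect_equal(dr, d0, tolerance = 1e-12)
})

test_that("gated pairs match the 3-4-5 example and gate strictly", {
  tc <- point_faces(c(0, 0, 0), "tc")
  pm <- point_faces(c(3e-6, 4e-6, 0), "pmn")
  p <- gated_face_pairs(tc, pm, 6e-6)
  expect_equal(p$d, 5e-6)
  expect_equal(c(p$ex, p$ey, p$ez), c(-3, -4, 0) / 5)
  ## all pairs farther than the cutoff: empty result
  expect_equal(nrow(gated_face_pairs(tc, pm, 1.2e-6)), 0)
})

test_that("gated pairs equal the brute-force oracle on random clouds", {
  set.seed(42)
  for (rep in 1:100) {
    tc <- point_faces(matrix(runif(50 * 3, 0, 8e-6), ncol = 3), "tc")
    pm <- point_faces(matrix(runif(50 * 3, 0, 8e-6), ncol = 3), "pmn")
    cutoff <- runif(1, 0.5e-6, 3e-6)
    got <- gated_face_pairs(tc, pm, cutoff)
    want <- brute_pairs(tc, pm, cutoff)
    expect_identical(got$tc_face, want$tc_face)
    expect_identical(got$pmn_face, want$pmn_face)
    expect_equal(got$d, want$d, tolerance = 1e-12)
  }
  ## unit vector is anti-symmetric under swapping the two bodies
  tc <- point_faces(matrix(runif(30), ncol = 3) * 1e-6, "tc")
  pm <- point_faces(matrix(runif(30), ncol = 3) * 1e-6, "pmn")
  ab <- gated_face_pairs(tc, pm, 2e-6)
  ba <- gated_face_pairs(pm, tc, 2e-6)
  key_ab <- paste(ab$tc_face, ab$pmn_face)
  key_ba <- paste(ba$pmn_face, ba$tc_face)
  m <- match(key_ab, key_ba)
  expect_false(anyNA(m))
  expect_equal(as.matrix(ab[, c("ex", "ey", "ez")]),
               -as.matrix(ba[m, c("ex", "ey", "ez")]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("OBJ round trip and mesh writers emit readable text", {
  m <- make_icosphere(um(2), 1)
  tmp <- tempfile(fileext = ".obj")
  writeLines(c(apply(m$vertices * 1e6, 1, function(v)
    paste("v", v[1], v[2], v[3])),
    apply(m$faces, 1, function(f) paste("f", f[1], f[2], f[3]))), tmp)
  m2 <- read_obj(tmp, scale = 1e-6)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m2$faces, m$faces, ignore_attr = TRUE)
  off <- tempfile(fileext = ".off")
  write_mesh_off(m, off)
  expect_identical(readLines(off, n = 1), "OFF")
  expect_equal(scan(off, skip = 1, n = 2, quiet = TRUE),
               c(nrow(m$vertices), nrow(m$faces)))
  vtk <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, vtk)
  expect_match(readLines(vtk, n = 1), "vtk DataFile")
})
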
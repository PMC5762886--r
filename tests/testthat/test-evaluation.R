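test_that("icp on an identical mesh returns the identity", {
  mesh <- extractMesh(sphere_mask(6, 0.3))
  tf <- registerICP(mesh, mesh)
  expect_lt(max(abs(tf@rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tf@translation)), 1e-6)
  dev <- deviationRMS(applyTransform(mesh, tf), mesh)
  expect_lt(dev@rms, 1e-9)
})

test_that("icp recovers a known rigid perturbation", {
  mesh <- extractMesh(VoxelMask(array(c(rep(TRUE, 200), rep(FALSE, 312)),
                                      c(8, 8, 8)), spacing = 0.5))
  th <- 5 * pi / 180
  ax <- c(1, 2, 2) / 3
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  Rp <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  moved <- TriangleMesh(sweep(mesh@vertices %*% t(Rp), 2, c(1, 0.3, -0.2), "+"),
                        mesh@triangles)
  tf <- registerICP(moved, mesh, maxIters = 100L)
  comp_R <- tf@rotation %*% Rp
  comp_t <- tf@rotation %*% c(1, 0.3, -0.2) + tf@translation
  expect_lt(max(abs(comp_R - diag(3))), 1e-3)
  expect_lt(max(abs(comp_t)), 1e-3)
  dev <- deviationRMS(applyTransform(moved, tf), mesh)
  expect_lt(dev@rms, 1e-3)
})

test_that("degenerate meshes are rejected by registration", {
  two <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      matrix(c(1, 2, 3), 1))
  ok <- box_mesh()
  expect_error(registerICP(two, ok), "collinear")
  expect_error(registerICP(TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0)),
                                        matrix(integer(0), 0, 3)), ok),
               "fewer than 3")
})

test_that("cej cutting keeps the apical part at the right height", {
  cyl <- cylinder_mesh(radius = 3, height = 20, z0 = 0)
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  cej <- cbind(3 * cos(th), 3 * sin(th), 12)   # 12 mm above the apical end
  cut <- cutAtCEJ(cyl, cyl, cej, apicalDirection = c(0, 0, -1))
  zr <- range(cut$reference@vertices[, 3])
  expect_equal(zr[1], 0, tolerance = 1e-9)
  expect_equal(zr[2], 12, tolerance = 1e-6)
  # clip postcondition: no retained vertex beyond the plane
  expect_lte(max(cut$reference@vertices[, 3]), 12 + 1e-9)
  expect_true(all(cut$test@vertices[, 3] <= 12 + 1e-9))
})

test_that("a cej plane missing the mesh is a warned no-op", {
  cyl <- cylinder_mesh(height = 5)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  cej <- cbind(3 * cos(th), 3 * sin(th), 50)
  expect_warning(cut <- cutAtCEJ(cyl, cyl, cej, apicalDirection = c(0, 0, -1)),
                 "does not intersect")
  expect_equal(nrow(cut$reference@triangles), nrow(cyl@triangles))
})

test_that("cej input validation rejects tiny curves", {
  cyl <- cylinder_mesh()
  expect_error(cutAtCEJ(cyl, cyl, rbind(c(0, 0, 1), c(1, 0, 1))), "at least 3")
})

test_that("deviation of a mesh against itself is exactly zero", {
  mesh <- extractMesh(sphere_mask(5, 0.3))
  dev <- deviationRMS(mesh, mesh)
  expect_identical(dev@rms, 0)
  expect_true(all(dev@distances == 0))
})

test_that("a 0.4 mm offset plane patch has rms exactly 0.4", {
  g <- as.matrix(expand.grid(x = 0:10, y = 0:10))
  V <- cbind(g, 0)
  idx <- function(i, j) i + 11 * (j - 1) + 1
  F <- NULL
  for (j in 1:10) for (i in 0:9)
    F <- rbind(F, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
               c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  ref <- TriangleMesh(V, F)
  # interior sub-patch, offset 0.4 along the normal
  Vi <- V[V[, 1] >= 2 & V[, 1] <= 8 & V[, 2] >= 2 & V[, 2] <= 8, ]
  Vi[, 3] <- 0.4
  test <- TriangleMesh(Vi, matrix(c(1, 2, 3), 1))
  dev <- deviationRMS(test, ref)
  expect_equal(dev@rms, 0.4, tolerance = 1e-9)
  expect_true(all(abs(dev@distances - 0.4) < 1e-9))
})

test_that("rms satisfies the conservation identity rms^2 * N = sum(Xi^2)", {
  ref <- extractMesh(sphere_mask(6, 0.3))
  test <- extractMesh(sphere_mask(5, 0.3))
  dev <- deviationRMS(test, ref)
  N <- length(dev@distances)
  expect_equal(dev@rms^2 * N, sum(dev@distances^2), tolerance = 1e-12)
  expect_true(all(dev@distances >= 0))
  expect_equal(abs(dev@signed), dev@distances)
})

test_that("nearest distances match the exhaustive brute-force oracle", {
  set.seed(77)
  for (rep in 1:3) {
    V <- matrix(runif(3 * 22, -5, 5), ncol = 3)
    F <- matrix(sample(22, 90, replace = TRUE), ncol = 3)
    F <- F[F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3], , drop = FALSE]
    F <- F[1:min(30, nrow(F)), , drop = FALSE]
    mesh <- TriangleMesh(V, F, dropDegenerate = FALSE)
    pts <- matrix(runif(3 * 25, -6, 6), ncol = 3)
    nn <- pdlroot:::.cpp_mesh_nearest(pts, mesh@vertices, mesh@triangles)
    for (q in seq_len(nrow(pts))) {
      expect_lt(abs(nn$distance[q] - oracle_mesh_distance(pts[q, ], mesh)),
                1e-9)
    }
  }
})

test_that("deviation is directional: swapping the meshes changes the samples", {
  ref <- extractMesh(sphere_mask(6, 0.3))
  test <- extractMesh(sphere_mask(4, 0.3))
  d1 <- deviationRMS(test, ref)@rms
  d2 <- deviationRMS(ref, test)@rms
  expect_false(isTRUE(all.equal(d1, d2)))
})

test_that("the local frame of a box recovers its principal dimensions", {
  b <- box_mesh(c(9, 6, 16))
  fr <- buildLocalFrame(b)
  expect_equal(abs(fr@axes[, 3]), c(0, 0, 1), tolerance = 1e-9)
  dims <- boundingBoxDims(b, fr)
  expect_equal(unname(dims["rl"]), 16, tolerance = 1e-9)
  expect_equal(sort(unname(dims[c("bl", "md")])), c(6, 9), tolerance = 1e-9)
  expect_equal(det(fr@axes), 1, tolerance = 1e-12)
})

test_that("measured dimensions are invariant to rigid motion of the mesh", {
  b <- box_mesh(c(9, 6, 16))
  dims0 <- boundingBoxDims(b, buildLocalFrame(b))
  for (s in 1:5) {
    Rr <- rand_rotation(seed = s)
    moved <- TriangleMesh(sweep(b@vertices %*% t(Rr), 2, c(3, -2, 7), "+"),
                          b@triangles)
    dims <- boundingBoxDims(moved, buildLocalFrame(moved))
    expect_equal(sort(unname(dims)), sort(unname(dims0)), tolerance = 1e-9)
  }
})

test_that("axis overrides and hints steer the frame", {
  b <- box_mesh(c(9, 6, 16))
  fr <- buildLocalFrame(b)
  expect_identical(buildLocalFrame(b, axisOverride = fr), fr)
  frh <- buildLocalFrame(b, buccalHint = c(1, 0.2, 0))
  expect_gt(abs(sum(frh@axes[, 1] * c(1, 0, 0))), 0.9)
  flat <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
                       rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_error(buildLocalFrame(flat), "collinear")
})

test_that("bounding-box dims are translation invariant and exact on a unit cube", {
  cube <- box_mesh(c(1, 1, 1))
  fr <- new("LocalFrame", axes = diag(3), origin = c(0, 0, 0))
  expect_equal(unname(boundingBoxDims(cube, fr)), c(1, 1, 1))
  moved <- TriangleMesh(sweep(cube@vertices, 2, c(5, 6, 7), "+"), cube@triangles)
  expect_equal(boundingBoxDims(moved, fr), boundingBoxDims(cube, fr))
})

test_that("size errors follow the reference-minus-test sign convention", {
  # construction mirrors the first two reference roots of the packaged table
  r1 <- sizeErrors(c(bl = 9.57, md = 5.82, rl = 16.13),
                   c(bl = 9.95, md = 6.15, rl = 14.59))
  expect_equal(unname(unlist(r1[c("bl_error", "md_error", "rl_error")])),
               c(-0.38, -0.33, 1.54), tolerance = 1e-9)
  r2 <- sizeErrors(c(bl = 10.4, md = 7.09, rl = 9.31),
                   c(bl = 10.79, md = 7.5, rl = 7.74))
  expect_equal(unname(unlist(r2[c("bl_error", "md_error", "rl_error")])),
               c(-0.39, -0.41, 1.57), tolerance = 1e-9)
  same <- sizeErrors(c(bl = 1, md = 2, rl = 3), c(bl = 1, md = 2, rl = 3))
  expect_equal(unname(unlist(same[c("bl_error", "md_error", "rl_error")])),
               c(0, 0, 0))
  # a box built at the reference dims measures back those dims exactly
  b <- box_mesh(c(9.57, 5.82, 16.13))
  fr <- new("LocalFrame", axes = diag(3), origin = c(0, 0, 0))
  expect_equal(unname(boundingBoxDims(b, fr)), c(9.57, 5.82, 16.13))
})
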
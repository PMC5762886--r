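# All phantom tests use reduced grids (32-64 voxels per axis); the scene
# geometry scales with the grid so the anatomy is preserved.

# a 48-voxel grid spans 14.4 mm, so the tooth is scaled to fit
small_spec <- function(...) phantomSpec(dim_voxels = 48, root_length_mm = 7,
                                        crown_height_mm = 4,
                                        root_radius_cej_mm = 2.8, ...)

test_that("phantom generation is deterministic for a fixed spec", {
  a <- generatePhantom(small_spec(rng_seed = 5L))
  b <- generatePhantom(small_spec(rng_seed = 5L))
  expect_identical(a@volume@data, b@volume@data)
  expect_identical(a@truthRoot@data, b@truthRoot@data)
  c2 <- generatePhantom(small_spec(rng_seed = 6L))
  expect_false(identical(a@volume@data, c2@volume@data))
})

test_that("spec validity is enforced", {
  expect_error(phantomSpec(pdl_thickness_mm = 0.01), "pdl_thickness")
  expect_error(phantomSpec(n_roots = 3), "n_roots")
  expect_error(phantomSpec(grey_pdl = 1200), "grey_pdl")
  expect_error(phantomSpec(noise_sd = -1), "noise_sd")
})

test_that("sub-voxel PDL shell rasterizes into a discontinuous shadow", {
  case <- generatePhantom(small_spec(noise_sd = 0))
  pdl <- thresholdMask(case@volume, GreyWindow(150, 900))
  lab <- pdlroot:::.cpp_label26(pdl@data, dim(pdl@data))
  expect_gt(attr(lab, "ncomp"), 1)
})

test_that("degenerate zero-thickness PDL leaves the ligament window empty", {
  sp <- small_spec(pdl_thickness_mm = 0, noise_sd = 0, grey_background = 500)
  case <- generatePhantom(sp)
  m <- thresholdMask(case@volume, GreyWindow(200, 400))
  expect_equal(sum(m@data), 0)
})

test_that("truth masks satisfy the containment/disjointness invariants", {
  case <- generatePhantom(small_spec())
  expect_true(all(case@truthRoot@data <= case@truthTooth@data))
  expect_equal(sum(case@truthRoot@data & case@truthBone@data), 0)
  expect_equal(sum(case@truthPdl@data & case@truthTooth@data), 0)
  expect_gte(nrow(case@cejCurve), 12)
  # closed loop: all points on the CEJ plane, distinct angles
  expect_equal(diff(range(case@cejCurve[, 3])), 0)
})

test_that("ground-truth mesh is watertight and matches the analytic solid", {
  spec <- small_spec(noise_sd = 0)
  case <- generatePhantom(spec)
  mesh <- groundTruthMesh(case)
  expect_true(is_watertight(mesh))
  vol_analytic <- oracle_root_volume(spec)
  expect_lt(abs(meshVolume(mesh) - vol_analytic) / vol_analytic, 0.02)
  # vertices lie on the zero set of an independently coded signed distance
  set.seed(3)
  idx <- sample.int(nrow(vertices(mesh)), 200)
  d <- oracle_root_sdf(spec, vertices(mesh)[idx, ])
  expect_lt(max(abs(d)), 0.1)
})

test_that("voxelizing the truth mesh reproduces the truth root mask", {
  spec <- small_spec(noise_sd = 0)
  case <- generatePhantom(spec)
  mesh <- groundTruthMesh(case)
  # inside test at voxel centres via the analytic signed distance is the
  # mask definition; instead classify by mesh side (nearest-triangle normal)
  idx <- which(array(TRUE, dim(case@volume)), arr.ind = TRUE) - 1
  ctrs <- voxelToWorld(case@volume, idx)
  bb_lo <- apply(vertices(mesh), 2, min) - 0.5
  bb_hi <- apply(vertices(mesh), 2, max) + 0.5
  nearbb <- ctrs[, 1] >= bb_lo[1] & ctrs[, 1] <= bb_hi[1] &
    ctrs[, 2] >= bb_lo[2] & ctrs[, 2] <= bb_hi[2] &
    ctrs[, 3] >= bb_lo[3] & ctrs[, 3] <= bb_hi[3]
  nn <- pdlroot:::.cpp_mesh_nearest(ctrs[nearbb, ], vertices(mesh),
                                    triangles(mesh))
  Fm <- triangles(mesh); Vm <- vertices(mesh)
  a <- Vm[Fm[nn$triangle, 1], ]; b <- Vm[Fm[nn$triangle, 2], ]
  cc <- Vm[Fm[nn$triangle, 3], ]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  inside <- rowSums((ctrs[nearbb, ] - nn$closest) * nrm) < 0
  vox <- logical(nrow(ctrs))
  vox[nearbb] <- inside
  voxMask <- VoxelMask(array(vox, dim(case@volume)), like = case@volume)
  expect_gte(diceCoefficient(voxMask, case@truthRoot), 0.98)
})

test_that("rasterization converges as the supersampling rate doubles", {
  v <- function(ss) generatePhantom(phantomSpec(dim_voxels = 32, noise_sd = 0,
                                                supersample = ss))@volume@data
  d12 <- max(abs(v(1) - v(2)))
  d24 <- max(abs(v(2) - v(4)))
  expect_lt(d24, d12)
})

test_that("dentine and bone grey distributions overlap under default noise", {
  case <- generatePhantom(small_spec())
  root_g <- case@volume@data[case@truthRoot@data]
  bone_g <- case@volume@data[case@truthBone@data]
  # histogram intersection is non-empty: no single window separates them
  expect_gt(min(max(root_g), max(bone_g)) - max(min(root_g), min(bone_g)), 0)
  br <- range(bone_g)
  expect_gt(sum(root_g >= br[1] & root_g <= br[2]), 0)
})

test_that("two-root phantoms keep both roots inside the tooth truth", {
  case <- generatePhantom(small_spec(n_roots = 2L, noise_sd = 0))
  expect_true(all(case@truthRoot@data <= case@truthTooth@data))
  mesh <- groundTruthMesh(case)
  expect_true(is_watertight(mesh))
  # two apices: root voxels at the apical end split into two components
  zmin <- min(which(apply(case@truthRoot@data, 3, any)))
  sl <- case@truthRoot@data[, , zmin + 3, drop = FALSE]
  lab <- pdlroot:::.cpp_label26(sl, dim(sl))
  expect_equal(attr(lab, "ncomp"), 2)
})
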
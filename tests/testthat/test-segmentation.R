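seg_spec <- function(...) phantomSpec(dim_voxels = 64, root_length_mm = 8,
                                      crown_height_mm = 5,
                                      root_radius_cej_mm = 3.2, ...)

test_that("thresholding uses closed-interval semantics", {
  v <- VoxelVolume(array(100, c(3, 3, 3)))
  expect_true(all(thresholdMask(v, GreyWindow(50, 150))@data))
  expect_true(all(thresholdMask(v, GreyWindow(100, 100))@data))
  expect_false(any(thresholdMask(v, GreyWindow(150, 200))@data))
  v2 <- VoxelVolume(array(0:26, c(3, 3, 3)))
  m <- thresholdMask(v2, GreyWindow(10, 20))
  expect_equal(sum(m@data), 11)                     # 10..20 inclusive
  expect_equal(which(as.vector(m@data)), 11:21)     # exhaustive enumeration
})

test_that("dilate26 matches the structuring-element definition", {
  d <- array(FALSE, c(5, 5, 5)); d[3, 3, 3] <- TRUE
  m <- VoxelMask(d, 1)
  expect_equal(sum(dilate26(m, 1)@data), 27)
  expect_identical(dilate26(m, 0)@data, m@data)
  empty <- VoxelMask(array(FALSE, c(4, 4, 4)), 1)
  expect_equal(sum(dilate26(empty, 2)@data), 0)
  d2 <- array(FALSE, c(5, 5, 5)); d2[1, 1, 1] <- TRUE; d2[3, 3, 3] <- TRUE
  expect_equal(sum(dilate26(VoxelMask(d2, 1), 1)@data), 34)  # 8 + 27 - 1
  expect_error(dilate26(m, -1), "iterations")
})

test_that("dilate26 equals the brute-force oracle on random masks", {
  for (s in 1:25) {
    dims <- sample(3:10, 3, replace = TRUE)
    m <- rand_mask(dims, p = runif(1, 0.05, 0.5), seed = s)
    it <- sample(0:2, 1)
    expect_identical(dilate26(m, it)@data, oracle_dilate26(m@data, it),
                     info = paste("seed", s))
  }
})

test_that("dilation is monotone: output contains input, iterations nest", {
  m <- rand_mask(c(8, 8, 8), 0.2, seed = 99)
  d1 <- dilate26(m, 1); d2 <- dilate26(m, 2)
  expect_true(all(m@data <= d1@data))
  expect_true(all(d1@data <= d2@data))
})

test_that("boolean subtraction equals the voxel-wise oracle", {
  a <- rand_mask(c(4, 4, 4), 0.5, seed = 1)
  b <- rand_mask(c(4, 4, 4), 0.5, seed = 2)
  r <- booleanSubtract(a, b)
  expect_identical(r@data, a@data & !b@data)
  expect_true(all(r@data <= a@data))
  expect_equal(sum(r@data & b@data), 0)
  empty <- VoxelMask(array(FALSE, c(4, 4, 4)), 1)
  expect_identical(booleanSubtract(a, empty)@data, a@data)
  expect_false(any(booleanSubtract(a, a)@data))
})

test_that("region growing returns exactly the seed's 26-component", {
  d <- array(FALSE, c(7, 7, 7))
  d[2:3, 2:3, 2:3] <- TRUE           # cluster 1
  d[6:7, 6:7, 6:7] <- TRUE           # cluster 2, >= 2 voxels away
  m <- VoxelMask(d, 1)
  g <- regionGrow(m, voxelToWorld(m, c(1, 1, 1)))   # inside cluster 1
  expect_identical(g@data, oracle_flood26(d, c(2, 2, 2)))
  expect_equal(sum(g@data), 8)
  # single component: growing returns the whole mask
  one <- VoxelMask(oracle_dilate26(array(c(rep(FALSE, 13), TRUE,
                                           rep(FALSE, 13)), c(3, 3, 3))), 1)
  expect_identical(regionGrow(one, voxelToWorld(one, c(1, 1, 1)))@data, one@data)
  expect_error(regionGrow(m, voxelToWorld(m, c(4, 4, 4))), "TRUE voxel")
  expect_error(regionGrow(m, c(100, 100, 100)), "outside")
})

test_that("region growing matches the BFS oracle on random masks", {
  for (s in 1:15) {
    m <- rand_mask(sample(4:10, 3, replace = TRUE), p = 0.35, seed = 100 + s)
    w <- which(m@data, arr.ind = TRUE)
    if (nrow(w) == 0) next
    seed_ijk <- w[sample(nrow(w), 1), ]
    g <- regionGrow(m, voxelToWorld(m, seed_ijk - 1))
    expect_identical(g@data, oracle_flood26(m@data, seed_ijk),
                     info = paste("seed", s))
  }
})

test_that("edits apply in order with set-algebra semantics", {
  m <- rand_mask(c(5, 5, 5), 0.5, seed = 3)
  expect_identical(applyEdits(m, list())@data, m@data)
  reg <- rand_mask(c(5, 5, 5), 0.3, seed = 4)
  addThenRemove <- applyEdits(m, list(editOp("add", reg), editOp("remove", reg)))
  expect_false(any(addThenRemove@data & reg@data))       # remove wins by order
  expect_identical(addThenRemove@data, m@data & !reg@data)
  # random edit sequences vs sequential set algebra
  set.seed(5)
  cur_oracle <- m@data
  edits <- list()
  for (i in 1:6) {
    r <- rand_mask(c(5, 5, 5), 0.3, seed = 50 + i)
    mode <- sample(c("add", "remove"), 1)
    edits <- c(edits, list(editOp(mode, r)))
    cur_oracle <- if (mode == "add") cur_oracle | r@data else cur_oracle & !r@data
  }
  expect_identical(applyEdits(m, edits)@data, cur_oracle)
})

test_that("expansion degenerates correctly at the parameter extremes", {
  v <- rand_volume(c(6, 6, 6), seed = 9)
  seed <- rand_mask(c(6, 6, 6), 0.1, seed = 10)
  expect_identical(smartExpand(v, seed, smartExpandParams(0L, gradCap = 1))@data,
                   seed@data)
  # infinite caps + full window for one step == one dilation
  p <- smartExpandParams(1L, gradCap = Inf, windowSlack = 1e9)
  expect_identical(smartExpand(v, seed, p)@data, dilate26(seed, 1)@data)
  empty <- VoxelMask(array(FALSE, c(6, 6, 6)), 1)
  expect_error(smartExpand(v, empty, p), "empty")
})

test_that("expansion fills a flat region exactly up to a sharp edge", {
  # slab: flat plateau at 1000 bounded by a drop to 200
  d <- array(200, c(10, 10, 5))
  d[3:8, 3:8, 2:4] <- 1000
  v <- VoxelVolume(d, 1)
  seedArr <- array(FALSE, dim(d)); seedArr[5:6, 5:6, 3] <- TRUE
  seed <- VoxelMask(seedArr, 1)
  # edge gradient is ~(1000-200)/2 = 400/voxel; cap below that
  p <- smartExpandParams(20L, gradCap = 150, windowSlack = 10)
  out <- smartExpand(v, seed, p)
  interior <- array(FALSE, dim(d)); interior[4:7, 4:7, 3] <- TRUE
  # the flat interior (where the central-difference stencil stays flat)
  expect_true(all(out@data[interior]))
  expect_false(any(out@data & d == 200))
  expect_identical(out@data,
                   oracle_smart_expand(d, seedArr, 990, 1010, 150, 20))
})

test_that("expansion matches the geodesic BFS oracle on random volumes", {
  for (s in 1:20) {
    dims <- sample(4:10, 3, replace = TRUE)
    v <- rand_volume(dims, seed = 200 + s)
    m <- rand_mask(dims, 0.15, seed = 300 + s)
    if (!any(m@data)) next
    glo <- quantile(v@data[m@data], 0.01, names = FALSE)
    ghi <- quantile(v@data[m@data], 0.99, names = FALSE)
    slack <- runif(1, 0, 30)
    cap <- runif(1, 5, 60)
    steps <- sample(0:4, 1)
    got <- smartExpand(v, m, smartExpandParams(steps, cap, slack))
    want <- oracle_smart_expand(v@data, m@data, glo - slack, ghi + slack,
                                cap, steps)
    expect_identical(got@data, want, info = paste("seed", s))
  }
})

test_that("the pipeline separates root from bone and recovers the tooth", {
  case <- generatePhantom(seg_spec())
  cfg <- suggestConfig(case)
  masks <- segmentRoots(case@volume, cfg)
  fin <- masks[[1]]
  expect_equal(sum(fin@data & case@truthBone@data), 0)
  # this is a 64-voxel reduced-scale scene; the full-scale (128^3, default
  # anatomy) Dice >= 0.90 check lives in the acceptance suite
  expect_gte(diceCoefficient(fin, case@truthTooth), 0.88)
  log <- attr(masks, "stageLog")
  expect_true(all(c("root_bone_mask", "pdl_mask", "extended_pdl_mask",
                    "root_seed_mask", "individual_seed_1", "final_mask_1")
                  %in% names(log)))
  expect_gt(log$extended_pdl_mask, log$pdl_mask)
  expect_lt(log$root_seed_mask, log$root_bone_mask)
  expect_gte(log$final_mask_1, log$individual_seed_1)
})

test_that("the PDL-dilation stage is what prevents merging into bone", {
  case <- generatePhantom(seg_spec(noise_sd = 0))
  cfg <- suggestConfig(case)
  ab <- separationAblation(case, cfg)
  expect_equal(ab$overlap_with_dilation, 0)
  expect_gt(ab$overlap_without_dilation, 0)
})

test_that("degenerate phantom without a ligament fails with a clear error", {
  sp <- seg_spec(pdl_thickness_mm = 0, noise_sd = 0, grey_background = 500)
  case <- generatePhantom(sp)
  cfg <- suggestConfig(case)
  cfg@pdlWindow <- GreyWindow(200, 400)
  expect_error(segmentRoots(case@volume, cfg), "PDL window selects no voxels")
})

test_that("segmentation is deterministic end to end", {
  case1 <- generatePhantom(seg_spec(rng_seed = 7L))
  case2 <- generatePhantom(seg_spec(rng_seed = 7L))
  m1 <- segmentRoots(case1@volume, suggestConfig(case1))
  m2 <- segmentRoots(case2@volume, suggestConfig(case2))
  expect_identical(m1[[1]]@data, m2[[1]]@data)
})
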
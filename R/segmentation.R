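# Per-root segmentation: threshold -> PDL dilation -> Boolean subtraction
# -> seeded region growing -> gradient-limited expansion.

#' Threshold a volume into a mask
#'
#' Closed-interval thresholding: TRUE exactly where
#' `low <= grey <= high` (both bounds inclusive). An empty result is
#' allowed.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param w a \linkS4class{GreyWindow}.
#' @return a \linkS4class{VoxelMask} on the volume's grid.
#' @export
thresholdMask <- function(v, w) {
  stopifnot(is(v, "VoxelVolume"), is(w, "GreyWindow"))
  VoxelMask(v@data >= w@low & v@data <= w@high, like = v)
}

#' Binary dilation with the full 3x3x3 structuring element
#'
#' 26-connectivity dilation applied `iterations` times; the output is
#' always a superset of the input and `iterations = 0` is the identity.
#' This is the operation that closes the gaps of the discontinuous PDL
#' shadow into a continuous separating shell.
#'
#' @param m a \linkS4class{VoxelMask}.
#' @param iterations integer >= 0.
#' @return the dilated \linkS4class{VoxelMask}.
#' @export
dilate26 <- function(m, iterations = 1L) {
  stopifnot(is(m, "VoxelMask"))
  if (iterations < 0) stop("iterations must be >= 0")
  out <- .cpp_dilate26(m@data, dim(m@data), as.integer(iterations))
  VoxelMask(out, like = m)
}

# in-plane 8-connectivity dilation (ablation option): full 3x3 structuring
# element within each axial slice
.dilate8InPlane <- function(m, iterations = 1L) {
  d <- m@data
  for (it in seq_len(iterations)) {
    acc <- d
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      sh <- array(FALSE, dim(d))
      src_i <- max(1, 1 - di):min(dim(d)[1], dim(d)[1] - di)
      src_j <- max(1, 1 - dj):min(dim(d)[2], dim(d)[2] - dj)
      sh[src_i + di, src_j + dj, ] <- d[src_i, src_j, ]
      acc <- acc | sh
    }
    d <- acc
  }
  VoxelMask(d, like = m)
}

#' Boolean mask subtraction
#'
#' Voxel-wise `a AND NOT b`. This is the step that removes the extended
#' PDL shell (and with it every root-bone bridge) from the root-bone mask.
#'
#' @param a,b \linkS4class{VoxelMask} objects on the same grid.
#' @return a \linkS4class{VoxelMask}, subset of `a`, disjoint from `b`.
#' @export
booleanSubtract <- function(a, b) {
  .checkSameGeometry(a, b, "masks")
  VoxelMask(a@data & !b@data, like = a)
}

#' Seeded region growing (26-connected component)
#'
#' Returns the 26-connected component of the mask containing the seed
#' point, and nothing else: this isolates the individual root seed region
#' of one tooth after the Boolean subtraction.
#'
#' @param m a \linkS4class{VoxelMask}.
#' @param seed world point (mm triple) mapping to a TRUE voxel of `m`.
#' @return a \linkS4class{VoxelMask}.
#' @export
regionGrow <- function(m, seed) {
  stopifnot(is(m, "VoxelMask"))
  idx <- .worldToGridIndex(m, seed)
  if (is.null(idx)) stop("seed point lies outside the grid")
  if (!m@data[idx[1], idx[2], idx[3]])
    stop("seed point does not fall on a TRUE voxel of the mask")
  d <- dim(m@data)
  flat <- (idx[1] - 1) + d[1] * ((idx[2] - 1) + d[2] * (idx[3] - 1))
  VoxelMask(.cpp_flood26(m@data, d, flat), like = m)
}

#' Create a manual mask edit
#'
#' @param mode "add" (union) or "remove" (subtraction).
#' @param region \linkS4class{VoxelMask} to add or remove.
#' @return an \linkS4class{EditOp}.
#' @export
editOp <- function(mode = c("add", "remove"), region) {
  new("EditOp", mode = match.arg(mode), region = region)
}

#' Apply manual edits to a mask
#'
#' Edits are applied in list order; each is idempotent (`add` = union,
#' `remove` = set difference), so a later edit wins on overlap.
#'
#' @param m a \linkS4class{VoxelMask}.
#' @param edits list of \linkS4class{EditOp}.
#' @return the edited \linkS4class{VoxelMask}.
#' @export
applyEdits <- function(m, edits = list()) {
  for (e in edits) {
    stopifnot(is(e, "EditOp"))
    .checkSameGeometry(m, e@region, "mask and edit region")
    m <- if (e@mode == "add") VoxelMask(m@data | e@region@data, like = m)
         else VoxelMask(m@data & !e@region@data, like = m)
  }
  m
}

#' Expansion parameters
#'
#' @param maxStep maximum number of synchronous growth rounds (default 6).
#' @param gradCap maximum admissible gradient magnitude (grey units per
#'   voxel).
#' @param windowSlack widening of the seed grey window (grey units,
#'   default 0).
#' @return a \linkS4class{SmartExpandParams}.
#' @export
smartExpandParams <- function(maxStep = 6L, gradCap, windowSlack = 0) {
  new("SmartExpandParams", maxStep = as.integer(maxStep),
      gradCap = as.numeric(gradCap), windowSlack = as.numeric(windowSlack))
}

#' Grey-gradient-limited region expansion
#'
#' Controllable 3D voxel expansion of a seed region toward the true
#' root-bone boundary. The admissible grey window is the 1st-99th
#' percentile range of the volume over the seed, widened by
#' `windowSlack`; gradient magnitude is the Euclidean norm of central
#' differences in grey units per voxel. Each of at most `maxStep`
#' synchronous rounds adds every 26-neighbour of the current region whose
#' grey lies in the window and whose gradient does not exceed `gradCap`.
#' The output is a superset of the seed and deterministic.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param seed a non-empty \linkS4class{VoxelMask} on the same grid.
#' @param p a \linkS4class{SmartExpandParams}.
#' @return the expanded \linkS4class{VoxelMask}.
#' @export
smartExpand <- function(v, seed, p) {
  stopifnot(is(v, "VoxelVolume"), is(seed, "VoxelMask"), is(p, "SmartExpandParams"))
  .checkSameGeometry(v, seed, "volume and seed")
  if (!any(seed@data)) stop("seed mask is empty")
  g <- quantile(v@data[seed@data], c(0.01, 0.99), names = FALSE, type = 7)
  out <- .cpp_smart_expand(v@data, seed@data, dim(v@data),
                           g[1] - p@windowSlack, g[2] + p@windowSlack,
                           p@gradCap, p@maxStep)
  VoxelMask(out, like = v)
}

#' Estimate the noise SD of a volume
#'
#' Robust estimate from the median absolute deviation of the discrete
#' Laplacian: for i.i.d. Gaussian noise the 6-neighbour Laplacian has
#' variance 42 sigma^2, so sigma_hat = MAD(Laplacian) / sqrt(42). Structure
#' edges inflate the estimate only mildly because the MAD ignores the
#' tails.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @return estimated noise SD in grey units.
#' @export
estimateNoiseSd <- function(v) {
  d <- v@data
  n <- dim(d)
  if (any(n < 3L)) stop("volume too small for noise estimation")
  core <- d[2:(n[1] - 1), 2:(n[2] - 1), 2:(n[3] - 1)]
  lap <- d[1:(n[1] - 2), 2:(n[2] - 1), 2:(n[3] - 1)] +
         d[3:n[1], 2:(n[2] - 1), 2:(n[3] - 1)] +
         d[2:(n[1] - 1), 1:(n[2] - 2), 2:(n[3] - 1)] +
         d[2:(n[1] - 1), 3:n[2], 2:(n[3] - 1)] +
         d[2:(n[1] - 1), 2:(n[2] - 1), 1:(n[3] - 2)] +
         d[2:(n[1] - 1), 2:(n[2] - 1), 3:n[3]] - 6 * core
  mad(as.vector(lap)) / sqrt(42)
}

#' Segmentation configuration
#'
#' @param rootBoneWindow,pdlWindow \linkS4class{GreyWindow} objects; the
#'   windows may overlap.
#' @param seeds world point (mm triple) or k x 3 matrix, one row per tooth.
#' @param dilationIters PDL dilation iterations, 1 or 2 (default 2); 0 is
#'   accepted for ablation runs.
#' @param connectivity "26" (default) or "8" (in-plane, ablation).
#' @param expand a \linkS4class{SmartExpandParams}.
#' @return a \linkS4class{SegmentationConfig}.
#' @export
segmentationConfig <- function(rootBoneWindow, pdlWindow, seeds,
                               dilationIters = 2L, connectivity = c("26", "8"),
                               expand) {
  if (!is.matrix(seeds)) seeds <- matrix(seeds, ncol = 3, byrow = TRUE)
  new("SegmentationConfig", rootBoneWindow = rootBoneWindow,
      pdlWindow = pdlWindow, dilationIters = as.integer(dilationIters),
      connectivity = match.arg(connectivity), expand = expand, seeds = seeds)
}

#' Derive a segmentation configuration for a phantom
#'
#' Stands in for the interactive threshold selection on real data: windows
#' and expansion parameters are derived from the known phantom grey levels.
#' The root-bone window spans hard tissues (from midway between the PDL
#' grey and the darkest dentine up to well above enamel); the PDL window
#' spans the partial-volume shadow (from just above background up to the
#' lower edge of the root-bone window); `gradCap` is half of the
#' dentine-to-PDL grey drop (in grey units per voxel), `windowSlack` twice
#' the nominal noise SD, `maxStep` 6; the seed is the tooth centroid.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @return a \linkS4class{SegmentationConfig}.
#' @export
suggestConfig <- function(case) {
  spec <- case@spec
  lo_hard <- (spec@grey_pdl + spec@grey_dentine_apex) / 2 + 0.5 *
    (spec@grey_dentine_apex - (spec@grey_pdl + spec@grey_dentine_apex) / 2)
  hi_hard <- spec@grey_enamel + 6 * max(spec@noise_sd, 1)
  lo_pdl <- spec@grey_background + 0.25 * (spec@grey_pdl - spec@grey_background) + 1
  idx <- which(case@truthTooth@data, arr.ind = TRUE) - 1
  seed <- colMeans(voxelToWorld(case@volume, idx))
  segmentationConfig(
    rootBoneWindow = GreyWindow(lo_hard, hi_hard),
    pdlWindow = GreyWindow(lo_pdl, lo_hard),
    seeds = seed,
    dilationIters = 2L,
    expand = smartExpandParams(
      maxStep = 6L,
      gradCap = (spec@grey_dentine_apex - spec@grey_pdl) / 2,
      windowSlack = 2 * spec@noise_sd))
}

#' Segment individual tooth roots from a volume
#'
#' The full pipeline: (1) threshold the root-bone window; (2) threshold the
#' PDL window; (3) dilate the PDL mask (26-connectivity, 1-2 iterations)
#' into a continuous shell; (4) Boolean-subtract the extended PDL mask from
#' the root-bone mask to obtain the root seed mask; (5) apply optional
#' manual edits; (6) grow the 26-connected component at each seed point
#' (individual root seed mask); (7) expand each seed region under the
#' grey-window/gradient constraints back to the root-bone boundary.
#'
#' @param v a \linkS4class{VoxelVolume}.
#' @param cfg a \linkS4class{SegmentationConfig}.
#' @param edits optional list of \linkS4class{EditOp} applied after the
#'   subtraction.
#' @return named list of final \linkS4class{VoxelMask} objects, one per
#'   seed ("tooth1", ...), with a per-stage voxel-count log in
#'   `attr(, "stageLog")`.
#' @examples
#' case <- generatePhantom(phantomSpec(dim_voxels = 64, noise_sd = 0))
#' masks <- segmentRoots(case@volume, suggestConfig(case))
#' attr(masks, "stageLog")
#' @export
segmentRoots <- function(v, cfg, edits = list()) {
  stopifnot(is(v, "VoxelVolume"), is(cfg, "SegmentationConfig"))
  log <- list()
  rootBone <- thresholdMask(v, cfg@rootBoneWindow)
  if (!any(rootBone@data)) stop("root-bone window selects no voxels")
  log$root_bone_mask <- sum(rootBone@data)
  pdl <- thresholdMask(v, cfg@pdlWindow)
  if (!any(pdl@data)) stop("PDL window selects no voxels")
  log$pdl_mask <- sum(pdl@data)
  extended <- if (cfg@connectivity == "26") dilate26(pdl, cfg@dilationIters)
              else .dilate8InPlane(pdl, cfg@dilationIters)
  log$extended_pdl_mask <- sum(extended@data)
  seedMask <- booleanSubtract(rootBone, extended)
  log$root_seed_mask <- sum(seedMask@data)
  if (length(edits)) {
    seedMask <- applyEdits(seedMask, edits)
    log$root_seed_mask_edited <- sum(seedMask@data)
  }
  out <- vector("list", nrow(cfg@seeds))
  names(out) <- paste0("tooth", seq_len(nrow(cfg@seeds)))
  for (s in seq_len(nrow(cfg@seeds))) {
    indiv <- regionGrow(seedMask, cfg@seeds[s, ])
    log[[paste0("individual_seed_", s)]] <- sum(indiv@data)
    if (sum(indiv@data) > 0.5 * sum(rootBone@data))
      warning("seed region ", s, " spans most of the root-bone mask; ",
              "it has probably merged with the alveolar bone")
    final <- smartExpand(v, indiv, cfg@expand)
    log[[paste0("final_mask_", s)]] <- sum(final@data)
    out[[s]] <- final
  }
  attr(out, "stageLog") <- log
  out
}
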
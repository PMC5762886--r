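# Synthetic CBCT phantom: analytic tooth + periodontal ligament + alveolar
# bone scene, rasterized with a box-filter partial-volume model.

#' Build a phantom specification
#'
#' Defaults emulate the imaging situation the segmentation exploits: 0.3 mm
#' isotropic voxels; a 0.25 mm PDL shell (thinner than one voxel, so its
#' rasterized shadow is discontinuous); alveolar bone grey inside the
#' dentine grey range (so a single threshold window cannot separate root
#' from bone); a crown-to-apex dentine density gradient; additive Gaussian
#' noise. Grey levels are 12-bit-like stand-ins (background 0, PDL 300,
#' bone 1150, dentine 1100 at the apex to 1250 at the CEJ, enamel 1900,
#' noise SD 40): only their ordering and overlap structure matter.
#'
#' @param voxel_mm isotropic voxel size (default 0.3 mm).
#' @param dim_voxels grid size, scalar or integer(3) (default 128^3).
#' @param pdl_thickness_mm PDL shell thickness, default 0.25 mm; 0 gives a
#'   degenerate phantom with no ligament.
#' @param n_roots 1 (default) or 2.
#' @param root_length_mm apex-to-CEJ length, default 13 mm.
#' @param crown_height_mm default 7 mm.
#' @param root_radius_cej_mm,root_radius_apex_mm lateral radii, defaults
#'   4.2 / 1.0 mm (for two roots each cone uses 0.55x the CEJ radius).
#' @param grey_enamel,grey_dentine_crown,grey_dentine_apex,grey_pdl,grey_bone,grey_background
#'   tissue grey levels.
#' @param noise_sd Gaussian noise SD in grey units (default 40).
#' @param supersample sub-samples per axis for the partial-volume box
#'   filter (default 3).
#' @param rng_seed seed for the noise field (default 1).
#' @return a validated \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(voxel_mm = 0.3, dim_voxels = c(128L, 128L, 128L),
                        pdl_thickness_mm = 0.25, n_roots = 1L,
                        root_length_mm = 13, crown_height_mm = 7,
                        root_radius_cej_mm = 4.2, root_radius_apex_mm = 1.0,
                        grey_enamel = 1900, grey_dentine_crown = 1250,
                        grey_dentine_apex = 1100, grey_pdl = 300,
                        grey_bone = 1150, grey_background = 0,
                        noise_sd = 40, supersample = 3L, rng_seed = 1L) {
  if (length(dim_voxels) == 1L) dim_voxels <- rep(dim_voxels, 3L)
  new("PhantomSpec", voxel_mm = voxel_mm, dim_voxels = as.integer(dim_voxels),
      pdl_thickness_mm = pdl_thickness_mm, n_roots = as.integer(n_roots),
      root_length_mm = root_length_mm, crown_height_mm = crown_height_mm,
      root_radius_cej_mm = root_radius_cej_mm,
      root_radius_apex_mm = root_radius_apex_mm,
      grey_enamel = grey_enamel, grey_dentine_crown = grey_dentine_crown,
      grey_dentine_apex = grey_dentine_apex, grey_pdl = grey_pdl,
      grey_bone = grey_bone, grey_background = grey_background,
      noise_sd = noise_sd, supersample = as.integer(supersample),
      rng_seed = as.integer(rng_seed))
}

# scene parameters (world mm) derived from a spec
.phantomScene <- function(spec) {
  ext <- spec@dim_voxels * spec@voxel_mm
  cx <- (spec@dim_voxels[1] - 1) / 2 * spec@voxel_mm
  cy <- (spec@dim_voxels[2] - 1) / 2 * spec@voxel_mm
  z_cej <- min(0.52 * ext[3], ext[3] - spec@crown_height_mm - 2)
  ra <- spec@root_radius_apex_mm
  if (spec@n_roots == 1L) {
    rb <- spec@root_radius_cej_mm
    apex_c <- z_cej - spec@root_length_mm + ra
    cones <- matrix(c(cx, cy, apex_c, cx, cy, z_cej, ra, rb), nrow = 1)
  } else {
    rb <- 0.55 * spec@root_radius_cej_mm
    apex_c <- z_cej - spec@root_length_mm + ra
    split_ap <- 0.45 * spec@root_radius_cej_mm + 1.2
    split_ce <- 0.45 * spec@root_radius_cej_mm
    cones <- rbind(
      c(cx - split_ap, cy, apex_c, cx - split_ce, cy, z_cej, ra, rb),
      c(cx + split_ap, cy, apex_c, cx + split_ce, cy, z_cej, ra, rb))
  }
  crown_r <- if (spec@n_roots == 1L) spec@root_radius_cej_mm + 0.8 else
    split_ce + rb + 0.8
  list(
    root_cones = cones,
    z_cej = z_cej,
    pdl_thickness = spec@pdl_thickness_mm,
    z_bone_lo = 1.0,
    z_crest = z_cej - 1.5,
    crown_cx = cx, crown_cy = cy, crown_cz = z_cej + 0.42 * spec@crown_height_mm,
    crown_rx = crown_r, crown_ry = spec@root_radius_cej_mm + 0.8,
    crown_rz = 0.62 * spec@crown_height_mm,
    grey_enamel = spec@grey_enamel, grey_dentine_crown = spec@grey_dentine_crown,
    grey_dentine_apex = spec@grey_dentine_apex, grey_pdl = spec@grey_pdl,
    grey_bone = spec@grey_bone, grey_background = spec@grey_background,
    centre = c(cx, cy))
}

# run expr with a locally seeded RNG, restoring the caller's stream
.withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic CBCT phantom case
#'
#' Rasterizes the analytic scene: every output voxel is the mean of
#' `supersample`^3 sub-samples of the noise-free scene grey (partial-volume
#' box filter) plus Gaussian noise. Because the PDL shell is thinner than a
#' voxel, the averaged shadow it leaves is faint and discontinuous — the
#' property the segmentation pipeline is built around. Deterministic for a
#' fixed spec.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomCase} with the volume, voxel-centre truth
#'   masks, the sub-voxel analytic root surface mesh, the CEJ curve and the
#'   tooth axis.
#' @examples
#' case <- generatePhantom(phantomSpec(dim_voxels = 48, noise_sd = 0))
#' case@volume
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  sc <- .phantomScene(spec)
  dims <- spec@dim_voxels
  spacing <- rep(spec@voxel_mm, 3)
  origin <- c(0, 0, 0)
  ras <- .cpp_phantom_raster(sc, dims, spacing, origin, spec@supersample)
  grey <- ras$grey
  if (spec@noise_sd > 0) {
    noise <- .withLocalSeed(spec@rng_seed,
                            rnorm(length(grey), 0, spec@noise_sd))
    grey <- grey + array(noise, dims)
  }
  vol <- VoxelVolume(grey, spacing, origin)
  mk <- function(x) VoxelMask(x, like = vol)
  mesh <- .truthRootMesh(spec, sc)
  new("PhantomCase", volume = vol,
      truthTooth = mk(ras$tooth), truthRoot = mk(ras$root),
      truthPdl = mk(ras$pdl), truthBone = mk(ras$bone),
      truthRootMesh = mesh, cejCurve = .cejCurve(sc),
      toothAxis = c(0, 0, 1), spec = spec)
}

# closed CEJ loop: lateral silhouette of the root union at the CEJ plane
.cejCurve <- function(sc, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  cones <- sc$root_cones
  pts <- t(vapply(th, function(a) {
    dx <- cos(a); dy <- sin(a)
    r <- max(vapply(seq_len(nrow(cones)), function(i) {
      ccx <- cones[i, 4] - sc$centre[1]
      ccy <- cones[i, 5] - sc$centre[2]
      rr <- cones[i, 8]
      # ray from scene centre: farthest intersection with this CEJ circle
      b <- dx * ccx + dy * ccy
      disc <- b^2 - (ccx^2 + ccy^2 - rr^2)
      if (disc < 0) -Inf else b + sqrt(disc)
    }, numeric(1)))
    c(sc$centre[1] + r * dx, sc$centre[2] + r * dy, sc$z_cej)
  }, numeric(3)))
  pts
}

# sub-voxel isosurface of the analytic capped-root signed distance
.truthRootMesh <- function(spec, sc) {
  h <- spec@voxel_mm / 2
  cones <- sc$root_cones
  xr <- range(c(cones[, 1] - cones[, 7], cones[, 1] + cones[, 7],
                cones[, 4] - cones[, 8], cones[, 4] + cones[, 8]))
  yr <- range(c(cones[, 2] - cones[, 7], cones[, 2] + cones[, 7],
                cones[, 5] - cones[, 8], cones[, 5] + cones[, 8]))
  zr <- c(min(cones[, 3] - cones[, 7]), sc$z_cej)
  pad <- 3 * h
  org <- c(xr[1], yr[1], zr[1]) - pad
  dims <- as.integer(ceiling((c(xr[2], yr[2], zr[2]) + pad - org) / h)) + 1L
  sdf <- .cpp_root_sdf_grid(sc, dims, rep(h, 3), org)
  iso <- .cpp_marching_tetra(-sdf, dims, 0, rep(h, 3), org)
  TriangleMesh(iso$vertices, iso$triangles)
}

#' Ground-truth root surface mesh of a phantom case
#'
#' Watertight triangle mesh of the analytic root solid (round-cone union
#' capped at the CEJ plane), extracted from the exact signed-distance field
#' at half-voxel resolution, i.e. independent of the rasterized volume.
#'
#' @param case a \linkS4class{PhantomCase}.
#' @return a \linkS4class{TriangleMesh}.
#' @export
groundTruthMesh <- function(case) case@truthRootMesh

# analytic signed distance of the capped root solid at arbitrary points
# (used by tests as the surface oracle)
.rootSignedDistance <- function(spec, pts) {
  sc <- .phantomScene(spec)
  .cpp_root_sdf_points(sc, as.matrix(pts))
}
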
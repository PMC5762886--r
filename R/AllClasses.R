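# S4 classes for the voxel / mesh data model.

#' Virtual parent for objects living on a voxel grid
#'
#' Carries the grid geometry: isotropic or anisotropic voxel size in mm and
#' the world position (mm) of the centre of voxel (0,0,0). World coordinates
#' follow the voxel-centre convention: world = origin + index * spacing with
#' 0-based indices.
#'
#' @slot spacing numeric(3), per-axis voxel size in mm, all > 0.
#' @slot origin numeric(3), world position of the first voxel centre in mm.
#' @exportClass VoxelGrid
setClass("VoxelGrid", representation("VIRTUAL",
  spacing = "numeric",
  origin = "numeric"
))

.validGeometry <- function(object) {
  msg <- character()
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  d <- dim(object@data)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "data must be a 3D array with >= 1 voxel per axis")
  if (length(msg)) msg else TRUE
}

#' Greyscale voxel volume
#'
#' A 3D scalar grid (arbitrary scanner-relative grey units) with voxel
#' geometry; the in-memory stand-in for a CBCT scan. No Hounsfield
#' calibration is attempted: CBCT grey values are scanner-relative and the
#' segmentation thresholds raw grey.
#'
#' @slot data 3D numeric array, dims (x, y, z); axis 3 is axial for
#'   phantoms, native orientation for imported data.
#' @slot spacing,origin grid geometry, see \linkS4class{VoxelGrid}.
#' @seealso [VoxelVolume()] for construction, [readVolume()] for file input.
#' @exportClass VoxelVolume
setClass("VoxelVolume", contains = "VoxelGrid", representation(data = "array"),
  validity = function(object) {
    v <- .validGeometry(object)
    if (!isTRUE(v)) return(v)
    if (!is.numeric(object@data)) return("data must be numeric")
    TRUE
  })

#' Binary voxel mask
#'
#' A boolean labelling on the grid of a parent \linkS4class{VoxelVolume};
#' every intermediate product of the segmentation pipeline (root-bone mask,
#' PDL mask, extended PDL mask, root seed mask, ...) is a VoxelMask. Masks
#' carry the parent geometry and all mask operations refuse geometry
#' mismatches.
#'
#' @slot data 3D logical array.
#' @slot spacing,origin grid geometry shared with the parent volume.
#' @exportClass VoxelMask
setClass("VoxelMask", contains = "VoxelGrid", representation(data = "array"),
  validity = function(object) {
    v <- .validGeometry(object)
    if (!isTRUE(v)) return(v)
    if (!is.logical(object@data)) return("mask data must be logical")
    if (anyNA(object@data)) return("mask data must not contain NA")
    TRUE
  })

#' Grey-value threshold window
#'
#' Closed interval of grey values; thresholding keeps voxels with
#' low <= grey <= high (both bounds inclusive).
#'
#' @slot low,high numeric(1) grey units, low <= high.
#' @exportClass GreyWindow
setClass("GreyWindow", representation(low = "numeric", high = "numeric"),
  validity = function(object) {
    if (length(object@low) != 1L || length(object@high) != 1L)
      return("low and high must be scalars")
    if (is.na(object@low) || is.na(object@high)) return("window bounds must not be NA")
    if (object@low > object@high) return("low must be <= high")
    TRUE
  })

#' Triangle mesh in mm
#'
#' Indexed triangle set: vertex coordinates in mm plus 1-based triangle
#' indices. Carrier of the extracted root surfaces (test models) and the
#' reference models.
#'
#' @slot vertices numeric matrix n x 3 (mm).
#' @slot triangles integer matrix m x 3, 1-based indices into vertices.
#' @exportClass TriangleMesh
setClass("TriangleMesh",
  representation(vertices = "matrix", triangles = "matrix"),
  validity = function(object) {
    V <- object@vertices; F <- object@triangles
    if (ncol(V) != 3L) return("vertices must be an n x 3 matrix")
    if (ncol(F) != 3L) return("triangles must be an m x 3 matrix")
    if (nrow(F) > 0) {
      if (min(F) < 1L || max(F) > nrow(V))
        return("triangle indices out of range")
    }
    TRUE
  })

#' Rigid-body transform
#'
#' Rotation (proper orthonormal) plus translation, mapping test-model
#' coordinates into the reference frame.
#'
#' @slot rotation 3 x 3 matrix, R R^T = I, det(R) = +1 (within 1e-9).
#' @slot translation numeric(3) mm.
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
    if (max(abs(R %*% t(R) - diag(3))) > 1e-9) return("rotation is not orthonormal")
    if (abs(det(R) - 1) > 1e-9) return("rotation must have det +1")
    if (length(object@translation) != 3L) return("translation must be length 3")
    TRUE
  })

#' Per-tooth local coordinate frame
#'
#' Right-handed orthonormal triad: X = bucco-lingual, Y = mesio-distal,
#' Z = root-length direction (apex negative, crown positive), plus an
#' origin at the mesh centroid.
#'
#' @slot axes 3 x 3 matrix whose columns are the X, Y, Z unit vectors.
#' @slot origin numeric(3) mm.
#' @exportClass LocalFrame
setClass("LocalFrame", representation(axes = "matrix", origin = "numeric"),
  validity = function(object) {
    A <- object@axes
    if (!all(dim(A) == c(3L, 3L))) return("axes must be 3 x 3")
    if (max(abs(t(A) %*% A - diag(3))) > 1e-9) return("axes are not orthonormal")
    if (abs(det(A) - 1) > 1e-9) return("frame must be right-handed (det +1)")
    if (length(object@origin) != 3L) return("origin must be length 3")
    TRUE
  })

#' Surface deviation result
#'
#' Nearest-point distances between a test and a reference surface and their
#' root-mean-square: RMS = sqrt(sum(Xi^2)/N) over the N sampled
#' correspondences Xi.
#'
#' @slot distances numeric, unsigned nearest distances Xi in mm.
#' @slot signed numeric, same distances signed by the side of the reference
#'   surface (for colour-map display).
#' @slot rms numeric(1) mm.
#' @exportClass DeviationResult
setClass("DeviationResult",
  representation(distances = "numeric", signed = "numeric", rms = "numeric"),
  validity = function(object) {
    if (any(object@distances < 0)) return("distances must be unsigned (>= 0)")
    if (length(object@signed) != length(object@distances))
      return("signed and distances must have equal length")
    if (length(object@rms) != 1L) return("rms must be a scalar")
    r <- sqrt(mean(object@distances^2))
    if (abs(object@rms - r) > 1e-12 * max(1, r))
      return("rms is inconsistent with distances")
    TRUE
  })

#' Synthetic CBCT phantom specification
#'
#' Parameters of the analytic tooth + periodontal ligament + alveolar bone
#' scene and of its rasterization. Defaults emulate a large-field-of-view
#' CBCT at 0.3 mm isotropic voxels with a PDL shell (0.25 mm) thinner than
#' one voxel, dentine grey overlapping bone grey, and an axial crown-to-apex
#' dentine density gradient. Grey levels are 12-bit-like structural
#' stand-ins; only their ordering and overlap matter.
#'
#' @slot voxel_mm isotropic voxel size (mm).
#' @slot dim_voxels integer(3) grid size.
#' @slot pdl_thickness_mm PDL shell thickness (mm), 0 allowed (degenerate),
#'   otherwise 0.05-0.6.
#' @slot n_roots 1 or 2.
#' @slot root_length_mm,crown_height_mm tooth dimensions (mm).
#' @slot root_radius_cej_mm,root_radius_apex_mm lateral root radii (mm).
#' @slot grey_enamel,grey_dentine_crown,grey_dentine_apex,grey_pdl,grey_bone,grey_background
#'   tissue grey levels.
#' @slot noise_sd additive Gaussian noise SD (grey units).
#' @slot supersample sub-samples per axis per voxel for the partial-volume
#'   box filter (>= 1).
#' @slot rng_seed integer seed for the noise.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
    voxel_mm = "numeric", dim_voxels = "integer", pdl_thickness_mm = "numeric",
    n_roots = "integer", root_length_mm = "numeric", crown_height_mm = "numeric",
    root_radius_cej_mm = "numeric", root_radius_apex_mm = "numeric",
    grey_enamel = "numeric", grey_dentine_crown = "numeric",
    grey_dentine_apex = "numeric", grey_pdl = "numeric", grey_bone = "numeric",
    grey_background = "numeric", noise_sd = "numeric", supersample = "integer",
    rng_seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@voxel_mm <= 0) msg <- c(msg, "voxel_mm must be > 0")
    if (length(object@dim_voxels) != 3L || any(object@dim_voxels < 8L))
      msg <- c(msg, "dim_voxels must be 3 integers >= 8")
    p <- object@pdl_thickness_mm
    if (p != 0 && (p < 0.05 || p > 0.6))
      msg <- c(msg, "pdl_thickness_mm must be 0 or within [0.05, 0.6]")
    if (!object@n_roots %in% c(1L, 2L)) msg <- c(msg, "n_roots must be 1 or 2")
    if (object@grey_pdl >= min(object@grey_dentine_apex, object@grey_bone))
      msg <- c(msg, "grey_pdl must be below dentine and bone grey")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (object@supersample < 1L) msg <- c(msg, "supersample must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Generated phantom case: volume plus ground truth
#'
#' A rasterized phantom volume with voxel-level truth masks, the sub-voxel
#' analytic root surface mesh (the in-silico analogue of a scanned
#' extracted-tooth reference model), the CEJ curve, and the tooth axis.
#'
#' @slot volume \linkS4class{VoxelVolume}.
#' @slot truthTooth,truthRoot,truthPdl,truthBone \linkS4class{VoxelMask}
#'   memberships at voxel centres.
#' @slot truthRootMesh \linkS4class{TriangleMesh}, analytic root surface.
#' @slot cejCurve k x 3 matrix (mm), closed loop on the CEJ.
#' @slot toothAxis unit vector, apex-to-crown direction.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @exportClass PhantomCase
setClass("PhantomCase", representation(
  volume = "VoxelVolume", truthTooth = "VoxelMask", truthRoot = "VoxelMask",
  truthPdl = "VoxelMask", truthBone = "VoxelMask",
  truthRootMesh = "TriangleMesh", cejCurve = "matrix", toothAxis = "numeric",
  spec = "PhantomSpec"))

#' Parameters of the grey-gradient-limited expansion
#'
#' Controls the controllable 3D voxel expansion that regrows a root seed
#' region to the true root-bone boundary: the seed's grey range (1st-99th
#' percentile, widened by `windowSlack`) defines admissible greys, voxels
#' with gradient magnitude above `gradCap` are rejected, and at most
#' `maxStep` synchronous rounds of 26-neighbour growth are performed (the
#' "maximum step size").
#'
#' @slot maxStep integer >= 0.
#' @slot gradCap grey units per voxel, > 0.
#' @slot windowSlack grey units, >= 0.
#' @exportClass SmartExpandParams
setClass("SmartExpandParams",
  representation(maxStep = "integer", gradCap = "numeric", windowSlack = "numeric"),
  validity = function(object) {
    if (object@maxStep < 0L) return("maxStep must be >= 0")
    if (!(object@gradCap > 0)) return("gradCap must be > 0")
    if (object@windowSlack < 0) return("windowSlack must be >= 0")
    TRUE
  })

#' Manual mask edit
#'
#' One add/remove correction applied to a mask, standing in for the small
#' interactive edits needed to disconnect adjacent crowns or residual
#' bone contacts.
#'
#' @slot mode "add" or "remove".
#' @slot region \linkS4class{VoxelMask} on the target geometry.
#' @exportClass EditOp
setClass("EditOp", representation(mode = "character", region = "VoxelMask"),
  validity = function(object) {
    if (!object@mode %in% c("add", "remove")) return("mode must be 'add' or 'remove'")
    TRUE
  })

#' Segmentation pipeline configuration
#'
#' Thresholds and parameters of the full per-root segmentation: the
#' root-bone and PDL threshold windows (allowed to overlap), the number of
#' 26-connectivity dilation iterations applied to the PDL mask (1 or 2; 0
#' only for ablation studies), the dilation connectivity (26 spatial,
#' default, or 8 in-plane for the ablation), the expansion parameters, and
#' one seed world-point per target tooth.
#'
#' @slot rootBoneWindow,pdlWindow \linkS4class{GreyWindow}.
#' @slot dilationIters integer.
#' @slot connectivity "26" or "8".
#' @slot expand \linkS4class{SmartExpandParams}.
#' @slot seeds k x 3 matrix of world points (mm).
#' @exportClass SegmentationConfig
setClass("SegmentationConfig", representation(
    rootBoneWindow = "GreyWindow", pdlWindow = "GreyWindow",
    dilationIters = "integer", connectivity = "character",
    expand = "SmartExpandParams", seeds = "matrix"),
  validity = function(object) {
    if (object@dilationIters < 0L) return("dilationIters must be >= 0")
    if (!object@connectivity %in% c("26", "8"))
      return("connectivity must be '26' or '8'")
    if (ncol(object@seeds) != 3L || nrow(object@seeds) < 1L)
      return("seeds must be a non-empty k x 3 matrix of world points")
    TRUE
  })
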
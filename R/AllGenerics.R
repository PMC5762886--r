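# Generics shared across the package.

#' Grid and mesh accessors
#'
#' `gridData` returns the raw array of a volume or mask, `voxelSpacing` and
#' `gridOrigin` the geometry, `vertices` and `triangles` the mesh arrays,
#' `nVoxels` the number of TRUE voxels of a mask.
#'
#' @param x a \linkS4class{VoxelVolume}, \linkS4class{VoxelMask} or
#'   \linkS4class{TriangleMesh}.
#' @return array, numeric vector or matrix as appropriate.
#' @aliases gridData voxelSpacing gridOrigin vertices triangles nVoxels
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
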
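# Constructors, accessors and geometry conventions for voxel data.

#' Create a greyscale voxel volume
#'
#' @param data 3D numeric array (grey units), dims (x, y, z).
#' @param spacing per-axis voxel size in mm (scalar recycled to 3).
#' @param origin world position (mm) of the centre of voxel (0,0,0).
#' @return a \linkS4class{VoxelVolume}.
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 4)), spacing = 0.3)
#' voxelToWorld(v, c(1, 1, 1))
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(data) <- "double"
  new("VoxelVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a binary voxel mask
#'
#' @param data 3D logical (or coercible) array.
#' @param spacing,origin grid geometry in mm.
#' @param like optional \linkS4class{VoxelGrid} whose geometry is copied.
#' @return a \linkS4class{VoxelMask}.
#' @export
VoxelMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0), like = NULL) {
  if (!is.null(like)) {
    spacing <- like@spacing
    origin <- like@origin
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim(data)
  data <- as.logical(data)
  dim(data) <- d
  new("VoxelMask", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a grey threshold window
#'
#' @param low,high inclusive grey bounds, low <= high.
#' @return a \linkS4class{GreyWindow}.
#' @export
GreyWindow <- function(low, high) new("GreyWindow", low = as.numeric(low),
                                      high = as.numeric(high))

#' Create a triangle mesh
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param dropDegenerate drop zero-area triangles (default TRUE).
#' @return a \linkS4class{TriangleMesh}.
#' @export
TriangleMesh <- function(vertices, triangles, dropDegenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (dropDegenerate && nrow(triangles) > 0) {
    a <- vertices[triangles[, 1], , drop = FALSE]
    b <- vertices[triangles[, 2], , drop = FALSE]
    cc <- vertices[triangles[, 3], , drop = FALSE]
    u <- b - a; w <- cc - a
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    area2 <- sqrt(rowSums(cr^2))
    triangles <- triangles[area2 > 1e-20, , drop = FALSE]
  }
  new("TriangleMesh", vertices = vertices, triangles = triangles)
}

#' @rdname accessors
setMethod("gridData", "VoxelVolume", function(x) x@data)
#' @rdname accessors
setMethod("gridData", "VoxelMask", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname accessors
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("triangles", "TriangleMesh", function(x) x@triangles)
#' @rdname accessors
setMethod("nVoxels", "VoxelMask", function(x) sum(x@data))

setMethod("dim", "VoxelGrid", function(x) dim(x@data))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume %d x %d x %d, spacing %s mm, grey range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelMask %d x %d x %d, spacing %s mm, %d TRUE voxels\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = " x "),
              sum(object@data)))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "DeviationResult", function(object) {
  cat(sprintf("DeviationResult: N = %d samples, RMS = %.4f mm (max %.4f mm)\n",
              length(object@distances), object@rms,
              if (length(object@distances)) max(object@distances) else NA_real_))
})

# shared geometry guard
.checkSameGeometry <- function(a, b, what = "operands") {
  if (!identical(dim(a@data), dim(b@data)) ||
      max(abs(a@spacing - b@spacing)) > 1e-9 ||
      max(abs(a@origin - b@origin)) > 1e-9)
    stop(what, " do not share grid geometry (shape/spacing/origin)")
  invisible(TRUE)
}

#' Voxel index to world coordinates and back
#'
#' Affine voxel-centre mapping: world = origin + index * spacing with
#' 0-based integer indices. The two functions are exact inverses; indices
#' outside the grid are allowed.
#'
#' @param x a \linkS4class{VoxelGrid} (volume or mask).
#' @param index numeric triple or n x 3 matrix of 0-based voxel indices.
#' @param world numeric triple or n x 3 matrix of mm coordinates.
#' @return matching triple or matrix, mm (voxelToWorld) or fractional
#'   0-based voxel indices (worldToVoxel).
#' @export
voxelToWorld <- function(x, index) {
  if (is.matrix(index))
    sweep(sweep(index, 2, x@spacing, "*"), 2, x@origin, "+")
  else x@origin + index * x@spacing
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(x, world) {
  if (is.matrix(world))
    sweep(sweep(world, 2, x@origin, "-"), 2, x@spacing, "/")
  else (world - x@origin) / x@spacing
}

# nearest in-grid voxel (1-based R index) of a world point; NULL if outside
.worldToGridIndex <- function(x, world) {
  i <- round(worldToVoxel(x, world)) + 1
  d <- dim(x@data)
  if (any(i < 1) || any(i > d)) return(NULL)
  as.integer(i)
}

#' Dice overlap coefficient between two masks
#'
#' 2|A n B| / (|A| + |B|); 1 for identical non-empty masks.
#'
#' @param a,b \linkS4class{VoxelMask} objects on the same grid.
#' @return numeric scalar in [0, 1] (NaN if both empty).
#' @export
diceCoefficient <- function(a, b) {
  .checkSameGeometry(a, b, "masks")
  2 * sum(a@data & b@data) / (sum(a@data) + sum(b@data))
}
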
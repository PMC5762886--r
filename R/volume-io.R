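# Volume file I/O: NIfTI-1 (via RNifti), NRRD (raw little-endian codec),
# DICOM series (read-only, uncompressed little-endian).

.VOL_FORMATS <- c("nifti", "nrrd", "dicom-series")

.guessFormat <- function(path) {
  if (dir.exists(path)) return("dicom-series")
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.nrrd$", low)) return("nrrd")
  stop("cannot guess volume format from path: ", path)
}

#' Read a voxel volume from disk
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`), NRRD (raw encoding,
#' little-endian) and uncompressed DICOM series directories (explicit or
#' implicit VR little endian; per-slice rescale slope/intercept applied).
#' DICOM slices are sorted along the normal so that array axis 3 is the
#' axial direction; slice spacing must be uniform within 1%.
#'
#' @param path file (nifti/nrrd) or directory (dicom-series).
#' @param format one of "nifti", "nrrd", "dicom-series"; guessed from the
#'   path by default.
#' @return a \linkS4class{VoxelVolume} with spacing in mm.
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "nrrd", "dicom-series")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guessFormat(path)
  if (format == "dicom-series") {
    if (!dir.exists(path)) stop("DICOM series path must be an existing directory: ", path)
    return(.readDicomSeries(path))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    nifti = .readNiftiVolume(path),
    nrrd = .readNrrdVolume(path))
}

#' Write a voxel volume (or mask) to disk
#'
#' Round-trips are lossless for integer-valued grids in both formats
#' (data stored as float64 for NIfTI, int32/float64 for NRRD). Masks are
#' written as 0/1 payloads. DICOM output is not supported.
#'
#' @param v a \linkS4class{VoxelVolume} or \linkS4class{VoxelMask}.
#' @param path output file path (parent directory must exist).
#' @param format "nifti" or "nrrd"; guessed from the extension by default.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(v, path, format = c("auto", "nifti", "nrrd")) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path))
    stop("path must be a non-empty file path")
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported output format"))
  if (format == "auto") format <- .guessFormat(path)
  if (format == "dicom-series") stop("unsupported output format: dicom-series is read-only")
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  if (is(v, "VoxelMask")) {
    d <- v@data + 0
    v <- VoxelVolume(d, v@spacing, v@origin)
  }
  switch(format,
    nifti = .writeNiftiVolume(v, path),
    nrrd = .writeNrrdVolume(v, path))
  invisible(path)
}

# ---- NIfTI ----------------------------------------------------------------

.readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- abs(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4])
  a <- as.array(img)
  a <- array(as.numeric(a), dim(a))   # strip niftiImage attributes
  if (length(dim(a)) > 3L) a <- a[, , , 1]
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  VoxelVolume(a, spacing = sp, origin = org)
}

.writeNiftiVolume <- function(v, path) {
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing
  xf <- rbind(cbind(diag(v@spacing), v@origin), c(0, 0, 0, 1))
  RNifti::`sform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(xf, code = 2L)) -> img
  RNifti::writeNifti(img, path)
}

# ---- NRRD -----------------------------------------------------------------
# Minimal NRRD codec: detached headers, compressed encodings and
# non-axis-aligned space directions are out of scope.

.readNrrdVolume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed NRRD header (no blank line)")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  type <- fields[["type"]]
  if (is.null(type)) stop("NRRD header missing type")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD supported")
  if (!identical(fields[["encoding"]], "raw")) stop("only raw NRRD encoding supported")
  spacing <- c(1, 1, 1)
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  data <- switch(type,
    "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "float" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "int" = , "int32" = , "signed int" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "short" = , "int16" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "uchar" = , "uint8" = readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little"),
    stop("unsupported NRRD type: ", type))
  if (length(data) < n) stop("truncated NRRD payload")
  dim(data) <- sizes
  VoxelVolume(data, spacing = spacing, origin = origin)
}

.writeNrrdVolume <- function(v, path) {
  d <- v@data
  integral <- all(d == round(d)) && max(abs(d)) < 2^31 - 1
  type <- if (integral) "int" else "double"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(d), collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   v@spacing[1], v@spacing[2], v@spacing[3])),
    "endian: little",
    "encoding: raw",
    paste0("space origin: ", sprintf("(%.17g,%.17g,%.17g)",
           v@origin[1], v@origin[2], v@origin[3])),
    "")
  writeLines(hdr, con, sep = "\n")
  if (integral) writeBin(as.integer(d), con, size = 4, endian = "little")
  else writeBin(as.vector(d), con, size = 8, endian = "little")
}

# ---- DICOM series (read-only) --------------------------------------------
# Minimal single-frame parser for uncompressed explicit/implicit VR little
# endian. Handles the tags the pipeline needs (geometry, rescale, pixels);
# sequences and encapsulated transfer syntaxes are rejected.

.dcmReadFile <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) u16(at) + 65536 * u16(at + 2L)
  tags <- list()
  # peek first element to detect implicit VR (VR bytes not alphabetic)
  if (pos + 7L <= length(raw)) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) explicit <- FALSE
  }
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    key <- sprintf("%04x%04x", group, elem)
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("DICOM undefined-length elements are not supported")
    val_at <- pos + hdr
    if (val_at + len - 1L > length(raw)) stop("truncated DICOM element at tag ", key)
    bytes <- if (len > 0L) raw[val_at:(val_at + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, bytes = bytes)
    pos <- val_at + len
    if (key == "7fe00010") break
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(t$bytes))
  }
  get_num <- function(key) {
    s <- get_str(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_u16 <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    readBin(t$bytes, "integer", size = 2, signed = FALSE, endian = "little")
  }
  ts <- get_str("00020010")
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax: ", ts)
  rows <- get_u16("00280010"); cols <- get_u16("00280011")
  if (is.null(rows) || is.null(cols)) stop("DICOM file lacks Rows/Columns: ", path)
  ps <- get_num("00280030")
  if (is.null(ps) || length(ps) != 2L) stop("DICOM file lacks PixelSpacing: ", path)
  ipp <- get_num("00200032")
  if (is.null(ipp)) ipp <- c(0, 0, get_num("00201041") %||% 0)
  bits <- get_u16("00280100") %||% 16L
  pixrep <- get_u16("00280103") %||% 0L
  slope <- (get_num("00281053") %||% 1)[1]
  intercept <- (get_num("00281052") %||% 0)[1]
  px <- tags[["7fe00010"]]
  if (is.null(px)) stop("DICOM file lacks PixelData: ", path)
  n <- as.integer(rows) * as.integer(cols)
  vals <- if (bits == 8L) {
    readBin(px$bytes, "integer", n = n, size = 1, signed = pixrep == 1L)
  } else {
    readBin(px$bytes, "integer", n = n, size = 2, signed = pixrep == 1L,
            endian = "little")
  }
  if (length(vals) < n) stop("truncated DICOM PixelData: ", path)
  # PixelData is row-major: first Columns values are image row 0
  slice <- matrix(as.numeric(vals) * slope + intercept, nrow = cols, ncol = rows)
  list(slice = slice, rows = rows, cols = cols,
       spacing_xy = c(ps[2], ps[1]),   # PixelSpacing is (row, column) = (y, x)
       position = ipp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readDicomSeries <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no DICOM files in directory: ", dir)
  slices <- lapply(files, .dcmReadFile)
  xy <- t(vapply(slices, `[[`, numeric(2), "spacing_xy"))
  if (max(xy) - min(xy) > 1e-9 * max(xy) &&
      (diff(range(xy[, 1])) > 0.01 * mean(xy[, 1]) ||
       diff(range(xy[, 2])) > 0.01 * mean(xy[, 2])))
    stop("inconsistent in-plane spacing across DICOM slices")
  z <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  dz <- if (length(z) > 1L) diff(z) else numeric(0)
  if (length(dz)) {
    if (any(dz <= 0)) stop("duplicate or unsorted DICOM slice positions")
    if ((max(dz) - min(dz)) > 0.01 * mean(dz))
      stop("inconsistent DICOM slice spacing (> 1% variation)")
  }
  dzm <- if (length(dz)) mean(dz) else mean(xy)
  nx <- slices[[1]]$cols; ny <- slices[[1]]$rows
  a <- array(0, c(nx, ny, length(slices)))
  for (k in seq_along(slices)) a[, , k] <- slices[[k]]$slice
  VoxelVolume(a, spacing = c(slices[[1]]$spacing_xy, dzm),
              origin = c(slices[[1]]$position[1:2], z[1]))
}
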
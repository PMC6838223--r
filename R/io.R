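# Volume, mask and field I/O: NIfTI-1 via RNifti, plus a minimal uncompressed
# MetaImage (.mha/.mhd) reader/writer. Clinical orientation matrices are
# normalized to the package's axis-aligned convention on load: spacing is
# taken as the (absolute) voxel size and origin as the stored offset.

.ext_of <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p) || grepl("\\.nii$", p)) return("nifti")
  if (grepl("\\.mha$", p)) return("mha")
  if (grepl("\\.mhd$", p)) return("mhd")
  stop(sprintf("unsupported volume format for '%s' (expect .nii, .nii.gz, .mha or .mhd)",
               path))
}

.met_types <- list(MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
                   MET_CHAR = list(what = "integer", size = 1, signed = TRUE),
                   MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
                   MET_USHORT = list(what = "integer", size = 2, signed = FALSE),
                   MET_INT = list(what = "integer", size = 4, signed = TRUE),
                   MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE),
                   MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE))

.read_meta <- function(path, header_only = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("I/O error reading MetaImage '%s': no ElementDataFile key",
                   path))
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) next
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)))
    stop(sprintf("I/O error: '%s' is not a 3D MetaImage", path))
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  ty <- .met_types[[hdr$ElementType]]
  if (is.null(ty))
    stop(sprintf("I/O error: unsupported MetaImage ElementType '%s' in '%s'",
                 hdr$ElementType, path))
  if (identical(hdr$CompressedData, "True"))
    stop(sprintf("I/O error: compressed MetaImage '%s' is not supported", path))
  endian <- if (identical(hdr$ElementByteOrderMSB, "True") ||
                identical(hdr$BinaryDataByteOrderMSB, "True")) "big" else "little"
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop(sprintf("I/O error: raw data file '%s' for '%s' not found",
                   raw_path, path))
    raw_con <- file(raw_path, "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, what = ty$what, n = n, size = ty$size,
                  signed = ty$signed, endian = endian)
  if (length(vals) < n)
    stop(sprintf("I/O error: truncated MetaImage data in '%s' (%d of %d voxels)",
                 path, length(vals), n))
  list(voxels = array(as.numeric(vals), dims), spacing = spacing,
       origin = origin)
}

.write_meta <- function(volume, path, type) {
  ty <- .met_types[[type]]
  d <- dim(volume$voxels)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.10g %.10g %.10g", volume$spacing[1],
                   volume$spacing[2], volume$spacing[3]),
           sprintf("Offset = %.10g %.10g %.10g", volume$origin[1],
                   volume$origin[2], volume$origin[3]),
           sprintf("ElementType = %s", type))
  if (grepl("\\.mhd$", tolower(path))) {
    raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(hdr, sprintf("ElementDataFile = %s", raw_name))
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), raw_name), "wb")
  } else {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    writeLines(hdr, con)
  }
  on.exit(close(con), add = TRUE)
  vals <- as.numeric(volume$voxels)
  if (ty$what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = ty$size, endian = "little")
  invisible(NULL)
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Spacing and origin are taken from the file header; intensities are
#' preserved at stored precision. Orientation is normalized to the package's
#' axis-aligned convention.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @param mask logical; return a [binary_mask()] (values must be 0/1).
#' @return An [image_volume()] or [binary_mask()].
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    stop(sprintf("I/O error: file '%s' does not exist", path))
  fmt <- .ext_of(path)
  if (fmt == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop(sprintf(
                      "I/O error reading NIfTI '%s': %s", path,
                      conditionMessage(e))))
    vox <- array(as.numeric(img), dim(img)[1:3])
    spacing <- abs(RNifti::pixdim(img))[1:3]
    xf <- RNifti::xform(img)
    origin <- as.numeric(xf[1:3, 4])
    out <- list(voxels = vox, spacing = spacing, origin = origin)
  } else {
    out <- .read_meta(path)
  }
  if (mask) binary_mask(out$voxels, out$spacing, out$origin)
  else image_volume(out$voxels, out$spacing, out$origin)
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The format is chosen from the extension. Round-trips through
#' [read_volume()] reproduce intensities, spacing and origin at the chosen
#' native precision.
#'
#' @param volume An [image_volume()] or [binary_mask()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @param datatype storage type: `"double"`, `"float"`, `"int16"` or
#'   `"uint8"`. Masks default to `"uint8"`, volumes to `"double"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, datatype = NULL) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("I/O error: directory '%s' does not exist", dirname(path)))
  if (is.null(datatype))
    datatype <- if (inherits(volume, "binary_mask")) "uint8" else "double"
  fmt <- .ext_of(path)
  if (fmt == "nifti") {
    dt <- switch(datatype, double = "double", float = "float",
                 int16 = "int16", uint8 = "uint8",
                 stop("unsupported datatype ", datatype))
    xf <- diag(4)
    diag(xf)[1:3] <- volume$spacing
    xf[1:3, 4] <- volume$origin
    arr <- volume$voxels
    attr(arr, "pixdim") <- volume$spacing
    img <- RNifti::asNifti(arr, datatype = dt)
    RNifti::sform(img) <- structure(xf, code = 2L)
    RNifti::qform(img) <- structure(xf, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    ty <- switch(datatype, double = "MET_DOUBLE", float = "MET_FLOAT",
                 int16 = "MET_SHORT", uint8 = "MET_UCHAR",
                 stop("unsupported datatype ", datatype))
    .write_meta(volume, path, ty)
  }
  invisible(path)
}

#' Write a displacement field as a 3-component NIfTI
#' @param field A [vector_field()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_field <- function(field, path) {
  arr <- field$u
  attr(arr, "pixdim") <- c(field$spacing, 1)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3-component NIfTI displacement field
#' @param path `.nii`/`.nii.gz` path holding an `(nx, ny, nz, 3)` array.
#' @return A [vector_field()].
#' @export
read_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop(sprintf("I/O error: '%s' is not a 3-component field", path))
  vector_field(array(as.numeric(img), d), abs(RNifti::pixdim(img))[1:3])
}

#' Save a rigid transform as JSON
#' @param transform A [rigid_transform()].
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(rotation = transform$rotation,
                            translation = transform$translation),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load a rigid transform from JSON
#' @param path `.json` path written by [write_transform()].
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(unlist(x$rotation), 3, 3), unlist(x$translation))
}

# ---- VTK legacy ASCII export (rendering interface only) ----

#' Export a centerline as a VTK legacy polyline
#' @param cl A [centerline()].
#' @param path output `.vtk` path.
#' @return Invisibly, `path`.
#' @export
write_vtk_polyline <- function(cl, path) {
  n <- nrow(cl$points)
  lines <- c("# vtk DataFile Version 3.0", "centerline", "ASCII",
             "DATASET POLYDATA", sprintf("POINTS %d double", n),
             apply(cl$points, 1, function(p) paste(format(p, digits = 10),
                                                   collapse = " ")),
             sprintf("LINES 1 %d", n + 1),
             paste(c(n, seq_len(n) - 1L), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Export a vector field as a VTK structured-points dataset
#'
#' Writes the displacement (or strain unit-vector) field as a `VECTORS` array
#' on a structured grid, suitable for glyph rendering.
#'
#' @param field A [vector_field()].
#' @param path output `.vtk` path.
#' @param name array name in the VTK file.
#' @return Invisibly, `path`.
#' @export
write_vtk_field <- function(field, path, name = "displacement") {
  d <- dim(field$u)[1:3]
  u <- matrix(aperm(field$u, c(4, 1, 2, 3)), nrow = 3)
  lines <- c("# vtk DataFile Version 3.0", "field", "ASCII",
             "DATASET STRUCTURED_POINTS",
             sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
             sprintf("ORIGIN %.10g %.10g %.10g", field$origin[1],
                     field$origin[2], field$origin[3]),
             sprintf("SPACING %.10g %.10g %.10g", field$spacing[1],
                     field$spacing[2], field$spacing[3]),
             sprintf("POINT_DATA %d", prod(d)),
             sprintf("VECTORS %s double", name))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  writeLines(apply(u, 2, function(p) paste(format(p, digits = 8),
                                           collapse = " ")), con)
  invisible(path)
}

#' Export a centerline as CSV (x, y, z, branch)
#' @param cl A [centerline()].
#' @param path output `.csv` path.
#' @return Invisibly, `path`.
#' @export
write_centerline_csv <- function(cl, path) {
  df <- data.frame(x = cl$points[, 1], y = cl$points[, 2], z = cl$points[, 3],
                   branch = cl$branch)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
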
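## Minimal NIfTI-1 and GIFTI readers/writers. No NIfTI/GIFTI package is
## assumed: volumes are written as little-endian NIfTI-1 with a diagonal
## RAS+ sform (scaled identity affine), surfaces and per-vertex data as
## GIFTI XML with ASCII-encoded data arrays. Only what the package itself
## writes is guaranteed to round-trip.

.nifti_datatype <- function(data) {
  if (is.integer(data) || (is.logical(data))) list(code = 8L, bitpix = 32L)
  else list(code = 64L, bitpix = 64L)
}

#' Write a 3D volume as NIfTI-1
#'
#' Little-endian `.nii` (or `.nii.gz`), diagonal voxel-size affine, RAS+
#' orientation, sform code 1. Doubles are stored as FLOAT64 (lossless),
#' integers and logicals as INT32.
#'
#' @param vol 3D array (numeric, integer or logical).
#' @param path output path; gzip compression if it ends in `.gz`.
#' @param voxel_size_mm isotropic voxel size.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, voxel_size_mm = 1) {
  d <- dim(vol)
  stopifnot(length(d) == 3)
  dt <- .nifti_datatype(vol)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wF <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wC <- function(n) writeBin(raw(n), con)
  wI(348L, 4)                      # sizeof_hdr
  wC(10); wC(18)                   # data_type, db_name
  wI(0L, 4); wI(0L, 2)             # extents, session_error
  writeBin(charToRaw("r"), con); wC(1) # regular, dim_info
  wI(c(3L, d, 1L, 1L, 1L, 1L), 2)  # dim
  wF(c(0, 0, 0)); wI(0L, 2)        # intent_p1-3, intent_code
  wI(dt$code, 2); wI(dt$bitpix, 2) # datatype, bitpix
  wI(0L, 2)                        # slice_start
  wF(c(1, rep(voxel_size_mm, 3), 0, 0, 0, 0)) # pixdim (qfac = 1)
  wF(352); wF(1); wF(0)            # vox_offset, scl_slope, scl_inter
  wI(0L, 2); wC(1)                 # slice_end, slice_code
  writeBin(as.raw(2L), con)        # xyzt_units = mm
  wF(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wI(c(0L, 0L), 4)                 # glmax, glmin
  wC(80); wC(24)                   # descrip, aux_file
  wI(0L, 2); wI(1L, 2)             # qform_code, sform_code
  wF(c(0, 0, 0, 0, 0, 0))          # quatern b,c,d + qoffset x,y,z
  wF(c(voxel_size_mm, 0, 0, 0))    # srow_x
  wF(c(0, voxel_size_mm, 0, 0))    # srow_y
  wF(c(0, 0, voxel_size_mm, 0))    # srow_z
  wC(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  wC(4)                            # extension flag (none)
  if (dt$code == 8L) wI(as.integer(vol), 4)
  else writeBin(as.double(vol), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array), `voxel_size_mm`, `datatype`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("parse error in ", path, ": truncated header")
  rI <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rF <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (rI(0, 4) != 348L) stop("parse error in ", path, ": not NIfTI-1 (offset 0)")
  dim_ <- rI(40, 2, 8)
  nd <- dim_[1]
  d <- dim_[2:(1 + nd)]
  datatype <- rI(70, 2)
  pixdim <- rF(76, 8)
  vox_offset <- rF(108)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  data <- switch(as.character(datatype),
                 "8" = readBin(con, "integer", n = n, size = 4, endian = "little"),
                 "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
                 "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
                 stop("parse error in ", path, ": unsupported datatype ", datatype))
  if (length(data) != n) stop("parse error in ", path, ": truncated data")
  dim(data) <- d
  list(data = data, voxel_size_mm = pixdim[2], datatype = datatype)
}

.gifti_root <- function() {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0")
  doc
}

.gifti_add_array <- function(doc, values, intent, datatype, dims) {
  da <- xml2::xml_add_child(doc, "DataArray",
                            Intent = intent, DataType = datatype,
                            ArrayIndexingOrder = "RowMajorOrder",
                            Dimensionality = as.character(length(dims)),
                            Encoding = "ASCII", Endian = "LittleEndian",
                            ExternalFileName = "", ExternalFileOffset = "")
  for (k in seq_along(dims))
    xml2::xml_set_attr(da, paste0("Dim", k - 1), as.character(dims[k]))
  txt <- if (datatype == "NIFTI_TYPE_INT32") paste(as.integer(values), collapse = " ")
         else paste(sprintf("%.17g", values), collapse = " ")
  xml2::xml_add_child(da, "Data", txt)
  doc
}

#' Write a surface mesh as a GIFTI surface file
#'
#' @param mesh list with `vertices` (n x 3 mm) and `triangles` (m x 3,
#'   1-based; stored 0-based per the GIFTI convention).
#' @param path output `.surf.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_surface <- function(mesh, path) {
  doc <- .gifti_root()
  .gifti_add_array(doc, t(mesh$vertices), "NIFTI_INTENT_POINTSET",
                   "NIFTI_TYPE_FLOAT64", dim(mesh$vertices))
  .gifti_add_array(doc, t(mesh$triangles - 1L), "NIFTI_INTENT_TRIANGLE",
                   "NIFTI_TYPE_INT32", dim(mesh$triangles))
  xml2::xml_set_attr(doc, "NumberOfDataArrays", "2")
  xml2::write_xml(doc, path)
  invisible(path)
}

.gifti_array_values <- function(da) {
  txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
  vals <- as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  nd <- as.integer(xml2::xml_attr(da, "Dimensionality"))
  dims <- vapply(seq_len(nd) - 1L,
                 function(k) as.integer(xml2::xml_attr(da, paste0("Dim", k))),
                 integer(1))
  if (nd == 2) t(matrix(vals, nrow = dims[2])) else vals
}

#' Read a GIFTI surface file written by [write_gifti_surface()]
#' @param path `.surf.gii` file.
#' @return mesh list (`vertices`, `triangles` 1-based).
#' @export
read_gifti_surface <- function(path) {
  doc <- xml2::read_xml(path)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  intents <- vapply(das, function(d) xml2::xml_attr(d, "Intent"), character(1))
  v <- .gifti_array_values(das[[which(intents == "NIFTI_INTENT_POINTSET")]])
  f <- .gifti_array_values(das[[which(intents == "NIFTI_INTENT_TRIANGLE")]])
  list(vertices = v, triangles = matrix(as.integer(f), ncol = 3) + 1L)
}

#' Write per-vertex scalars as a GIFTI metric file
#' @param values per-vertex numeric vector.
#' @param path output `.func.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_metric <- function(values, path) {
  doc <- .gifti_root()
  .gifti_add_array(doc, values, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT64",
                   length(values))
  xml2::xml_set_attr(doc, "NumberOfDataArrays", "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI metric file
#' @param path `.func.gii` file.
#' @return numeric per-vertex vector.
#' @export
read_gifti_metric <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  as.numeric(.gifti_array_values(da))
}

#' Write per-vertex integer labels as a GIFTI label file
#' @param labels integer per-vertex vector.
#' @param path output `.label.gii` path.
#' @return `path`, invisibly.
#' @export
write_gifti_label <- function(labels, path) {
  doc <- .gifti_root()
  lt <- xml2::xml_add_child(doc, "LabelTable")
  for (l in sort(unique(labels)))
    xml2::xml_add_child(lt, "Label", Key = as.character(l),
                        paste0("parcel_", l))
  .gifti_add_array(doc, as.integer(labels), "NIFTI_INTENT_LABEL",
                   "NIFTI_TYPE_INT32", length(labels))
  xml2::xml_set_attr(doc, "NumberOfDataArrays", "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a GIFTI label file
#' @param path `.label.gii` file.
#' @return integer per-vertex vector.
#' @export
read_gifti_label <- function(path) {
  doc <- xml2::read_xml(path)
  da <- xml2::xml_find_first(doc, ".//DataArray")
  as.integer(.gifti_array_values(da))
}
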
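# Minimal NIfTI-1 codec. The pre-installed R stack ships no NIfTI package, so
# reading/writing is implemented directly against the 348-byte header layout.
# Supported on read: uint8/int16/int32/uint16/float32/float64, single-file
# .nii or .nii.gz, either endianness, axis-aligned sform/qform orientation
# (reoriented to the package's L->R / P->A / I->S convention). Written files
# are little-endian uint8 with identity orientation.

.nii_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

.read_nifti1 <- function(path) {
  con <- .nii_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  rd <- function(what, n, size, off, endian, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):length(hdr_raw)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd("integer", 1, 4, 0, "little") != 348L) {
    if (rd("integer", 1, 4, 0, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic '", magic, "'): ", path)
  dim0 <- rd("integer", 8, 2, 40, endian)
  ndim <- dim0[1]
  if (ndim < 3L) stop("expected a 3D volume, got ", ndim, "D: ", path)
  d <- dim0[2:4]
  if (ndim > 3L && any(dim0[5:(ndim + 1)] > 1L))
    stop("expected a single 3D volume, file has extra non-singleton dimensions")
  datatype <- rd("integer", 1, 2, 70, endian)
  pixdim <- rd("numeric", 8, 4, 76, endian)
  vox_offset <- rd("numeric", 1, 4, 108, endian)
  scl_slope <- rd("numeric", 1, 4, 112, endian)
  scl_inter <- rd("numeric", 1, 4, 116, endian)
  qform_code <- rd("integer", 1, 2, 252, endian)
  sform_code <- rd("integer", 1, 2, 254, endian)
  quatern <- rd("numeric", 3, 4, 256, endian)
  qoffset <- rd("numeric", 3, 4, 268, endian)
  srow <- rbind(rd("numeric", 4, 4, 280, endian),
                rd("numeric", 4, 4, 296, endian),
                rd("numeric", 4, 4, 312, endian))
  if (any(pixdim[2:4] <= 0) && sform_code <= 0L)
    stop("missing or non-positive voxel spacing in header: ", path)

  # affine voxel-index -> world (mm), 3 x 4
  if (sform_code > 0L) {
    A <- srow
  } else if (qform_code > 0L) {
    b <- quatern[1]; c_ <- quatern[2]; dq <- quatern[3]
    a2 <- 1 - b^2 - c_^2 - dq^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(a^2 + b^2 - c_^2 - dq^2, 2*(b*c_ - a*dq), 2*(b*dq + a*c_),
                  2*(b*c_ + a*dq), a^2 + c_^2 - b^2 - dq^2, 2*(c_*dq - a*b),
                  2*(b*dq - a*c_), 2*(c_*dq + a*b), a^2 + dq^2 - b^2 - c_^2),
                nrow = 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    A <- cbind(R %*% diag(c(pixdim[2:3], qfac * pixdim[4])), qoffset)
  } else {
    A <- cbind(diag(pixdim[2:4]), c(0, 0, 0))
  }

  skip <- max(vox_offset, 352) - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(d)
  dat <- switch(as.character(datatype),
    "2"   = readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian),
    "4"   = readBin(con, "integer", n, size = 2, signed = TRUE, endian = endian),
    "8"   = readBin(con, "integer", n, size = 4, endian = endian),
    "512" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = endian),
    "16"  = readBin(con, "numeric", n, size = 4, endian = endian),
    "64"  = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, ": ", path))
  if (length(dat) < n) stop("truncated voxel data: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  list(data = array(dat, dim = d), affine = A)
}

# reorient an array + affine to the fixed axis convention (world axes +x/+y/+z)
.reorient_ras <- function(arr, A) {
  R <- A[, 1:3, drop = FALSE]
  cn <- sqrt(colSums(R^2))
  if (any(cn == 0)) stop("degenerate orientation matrix")
  world_axis <- integer(3); sgn <- numeric(3)
  for (j in 1:3) {
    i <- which.max(abs(R[, j]))
    off <- abs(R[-i, j])
    if (any(off > 1e-4 * cn[j]))
      stop("oblique (non-axis-aligned) orientation is not supported; ",
           "resample the volume to an axis-aligned grid first")
    world_axis[j] <- i
    sgn[j] <- sign(R[i, j])
  }
  if (anyDuplicated(world_axis)) stop("degenerate orientation matrix")
  perm <- match(1:3, world_axis)      # new axis w comes from old axis perm[w]
  arr <- aperm(arr, perm)
  flip <- sgn[perm] < 0
  idx <- lapply(1:3, function(w) if (flip[w]) rev(seq_len(dim(arr)[w]))
                else seq_len(dim(arr)[w]))
  arr <- arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # world position of the new first voxel = old voxel at the flipped corners
  corner <- numeric(3)
  for (w in 1:3) corner[perm[w]] <- if (flip[w]) dim(arr)[w] - 1 else 0
  origin <- as.vector(A %*% c(corner, 1))
  spacing <- cn[perm]
  list(arr = arr, spacing = spacing, origin = origin)
}

#' Read a segmentation label volume from a NIfTI-1 file
#'
#' Reads a `.nii` or `.nii.gz` label map, reorients it to the package's fixed
#' axis convention (axis 1 left-to-right, axis 2 posterior-to-anterior,
#' axis 3 inferior-to-superior), and validates the label coding. Voxel values
#' outside \{0, 1, 2\} or non-integer values raise an error rather than being
#' remapped silently.
#'
#' @param path file path; plain or gzip NIfTI-1.
#' @param case_id case identifier; defaults to the file name without
#'   extension.
#' @return A [label_volume()].
#' @seealso [write_label_volume()]
#' @export
read_label_volume <- function(path, case_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- .read_nifti1(path)
  ro <- .reorient_ras(nii$data, nii$affine)
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  label_volume(ro$arr, spacing = ro$spacing, origin = ro$origin,
               case_id = case_id)
}

#' Write a segmentation label volume to a NIfTI-1 file
#'
#' Writes a single-file little-endian NIfTI-1 volume (uint8 data, identity
#' orientation, sform and qform set) whose header spacing and origin equal
#' the volume's. `read_label_volume(write_label_volume(vol, p))` is the
#' identity on labels exactly and on spacing/origin to float32 precision.
#'
#' @param vol a [label_volume()].
#' @param path output path; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$labels)
  con <- tryCatch(.nii_open(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  wr <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(n) writeBin(raw(n), con)
  wr(348L, 4)                                   # sizeof_hdr
  pad(35)                                       # data_type, db_name, extents...
  writeBin(as.raw(0L), con)                     # dim_info
  wr(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2)   # dim[8]
  wr(numeric(3), 4)                             # intent_p1..p3
  wr(0L, 2)                                     # intent_code
  wr(2L, 2)                                     # datatype uint8
  wr(8L, 2)                                     # bitpix
  wr(0L, 2)                                     # slice_start
  wr(c(1, vol$spacing, 0, 0, 0, 0), 4)          # pixdim (qfac = 1)
  wr(352, 4)                                    # vox_offset
  wr(c(1, 0), 4)                                # scl_slope, scl_inter
  wr(0L, 2)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)              # slice_code, xyzt_units (mm)
  wr(numeric(4), 4)                             # cal_max/min, slice_dur, toffset
  wr(c(0L, 0L), 4)                              # glmax, glmin
  desc <- charToRaw("fhnquant label map")
  writeBin(c(desc, raw(80 - length(desc))), con)  # descrip
  pad(24)                                       # aux_file
  wr(c(1L, 1L), 2)                              # qform_code, sform_code
  wr(numeric(3), 4)                             # quatern b, c, d
  wr(vol$origin, 4)                             # qoffset x, y, z
  wr(c(vol$spacing[1], 0, 0, vol$origin[1]), 4) # srow_x
  wr(c(0, vol$spacing[2], 0, vol$origin[2]), 4) # srow_y
  wr(c(0, 0, vol$spacing[3], vol$origin[3]), 4) # srow_z
  pad(16)                                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  pad(4)                                        # extension flag
  writeBin(as.raw(as.vector(vol$labels)), con)
  invisible(path)
}

#' Read/write the per-case JSON sidecar
#'
#' The sidecar stores `case_id`, `arco_grade` and `source` next to each
#' volume file.
#'
#' @param record a [case_record()].
#' @param path JSON file path.
#' @return `read_case_record()` returns a [case_record()];
#'   `write_case_record()` returns `path` invisibly.
#' @export
write_case_record <- function(record, path) {
  stopifnot(inherits(record, "case_record"))
  jsonlite::write_json(record[c("case_id", "arco_grade", "source")], path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_case_record
#' @export
read_case_record <- function(path) {
  x <- jsonlite::read_json(path)
  case_record(x$case_id, x$arco_grade, x$source)
}
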
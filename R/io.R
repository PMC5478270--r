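# File export/import: minimal NIfTI-1 volumes, TSV tables, HDF5 epochs.
# No NIfTI package ships with the analysis stack this package targets,
# so a small self-contained NIfTI-1 (single-file .nii, float32,
# little-endian) writer/reader is provided for the volume interfaces.

#' Write a 3-D or 4-D array as a NIfTI-1 file
#'
#' Uncompressed single-file `.nii`, float32, with an isotropic diagonal
#' sform.  Intended for exporting masks, maps and synthetic series at
#' desk scale.
#'
#' @param img numeric/logical array (3-D or 4-D).
#' @param path output path.
#' @param voxel_mm voxel size, default 3.
#' @param tr_s repetition time stored in pixdim\[4\] for 4-D images.
#' @param descrip description string (<= 79 chars) embedded in the
#'   header.
#' @return the path, invisibly.
#' @export
write_nifti <- function(img, path, voxel_mm = 3, tr_s = 2,
                        descrip = "threatconn synthetic") {
  nd <- length(dim(img))
  if (!nd %in% c(3L, 4L)) stop("img must be 3-D or 4-D")
  dims <- dim(img)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s[seq_len(min(len, length(raw_s)))],
               raw(max(0L, len - length(raw_s)))), con)
  }
  wi(348, 4)                              # sizeof_hdr
  wc("", 10); wc("", 18)                  # data_type, db_name
  wi(0, 4); wi(0, 2)                      # extents, session_error
  writeBin(charToRaw("r"), con); writeBin(raw(1), con)  # regular, dim_info
  wi(c(nd, dims, rep(1L, 7 - nd)), 2)     # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)                # intent_p1..3, intent_code
  wi(16, 2); wi(32, 2); wi(0, 2)          # datatype float32, bitpix, slice_start
  wf(c(1, rep(voxel_mm, 3), tr_s, 0, 0, 0))  # pixdim[8]
  wf(352); wf(1); wf(0)                   # vox_offset, scl_slope, scl_inter
  wi(0, 2); writeBin(raw(1), con)         # slice_end, slice_code
  writeBin(as.raw(10L), con)              # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                       # cal_max..toffset
  wi(c(0, 0), 4)                          # glmax, glmin
  wc(descrip, 80); wc("", 24)             # descrip, aux_file
  wi(0, 2); wi(1, 2)                      # qform_code, sform_code
  wf(rep(0, 6))                           # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_mm, 0, 0, 0))                # srow_x
  wf(c(0, voxel_mm, 0, 0))                # srow_y
  wf(c(0, 0, voxel_mm, 0))                # srow_z
  wc("", 16)                              # intent_name
  wc("n+1", 4)                            # magic
  writeBin(raw(4), con)                   # extension indicator
  writeBin(as.numeric(img), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()]
#'
#' Supports the subset written by this package (float32, single file,
#' little-endian).
#'
#' @param path input `.nii` path.
#' @return list with `img` array, `voxel_mm`, `tr_s`, `descrip`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = "little")
  if (sz != 348) stop("not a NIfTI-1 file (or wrong endianness)")
  dim8 <- readBin(hdr[41:56], "integer", 8, 2, endian = "little")
  datatype <- readBin(hdr[71:72], "integer", 1, 2, endian = "little")
  if (datatype != 16) stop("unsupported datatype (only float32)")
  pixdim <- readBin(hdr[77:108], "numeric", 8, 4, endian = "little")
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  img <- array(readBin(con, "numeric", prod(dims), 4, endian = "little"),
               dim = dims)
  list(img = img, voxel_mm = pixdim[2], tr_s = pixdim[5],
       descrip = descrip)
}

#' Write a data frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Export a MEG cohort to an HDF5 container
#'
#' Datasets per subject: `epochs` (trial x sensor x time), `condition`,
#' `fs`; shared `sensor_pos`, `leadfields`, `source_pos`; generator
#' seed stored as an attribute-like dataset.  Requires the `rhdf5`
#' package.
#'
#' @param cohort result of [make_meg_cohort()].
#' @param path output `.h5` path.
#' @return the path, invisibly.
#' @export
export_meg_cohort_h5 <- function(cohort, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("rhdf5 is required for HDF5 export")
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(cohort$subjects[[1]]$sensor_pos, path, "sensor_pos")
  rhdf5::h5write(cohort$source_model$leadfield, path, "leadfields")
  rhdf5::h5write(cohort$source_model$pos, path, "source_pos")
  rhdf5::h5write(cohort$ground_truth$config$seed, path, "seed")
  for (s in seq_along(cohort$subjects)) {
    g <- sprintf("subject%02d", s)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(cohort$subjects[[s]]$epochs, path,
                   paste0(g, "/epochs"))
    rhdf5::h5write(cohort$subjects[[s]]$condition, path,
                   paste0(g, "/condition"))
    rhdf5::h5write(cohort$subjects[[s]]$fs_hz, path, paste0(g, "/fs"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

# Cluster table in the layout of the voxelwise results tables:
# label, size, mass, peak coordinate (LPI mm, grid-centred), corrected p.
cluster_table <- function(result, coords = NULL) {
  cl <- result$clusters
  if (!nrow(cl))
    return(data.frame(label = character(0), size = integer(0),
                      mass = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), p = numeric(0)))
  pk <- if (!is.null(coords)) coords[cl$peak, , drop = FALSE]
        else matrix(NA_real_, nrow(cl), 3)
  data.frame(label = sprintf("cluster%02d", seq_len(nrow(cl))),
             sign = cl$sign, size = cl$size, mass = cl$mass,
             x = pk[, 1], y = pk[, 2], z = pk[, 3],
             p = if ("p" %in% names(cl)) cl$p else NA_real_)
}
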
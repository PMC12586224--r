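# Plain-text input/output. All tabular artifacts are tab-delimited UTF-8 TSV
# with a header row; boundaries and manifests are JSON; voxel maps can also
# be exported as single-slice NIfTI-1 volumes. Writers and readers round-trip
# exactly (TSV/JSON) or to float32 precision (NIfTI).
#
# Coordinate convention: voxel indices are 1-based grid indices; millimetre
# coordinates are relative to the anterior commissure at [0, 0].

counts_cols <- c("subject_id", "scan_age_months", "side", "voxel_x",
                 "voxel_y", "area_id", "count")
metadata_cols <- c("subject_id", "sex", "cohort", "scan_age_months")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

read_tsv_checked <- function(path, required, what) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(what, " file has unknown column(s), ignored: ",
            paste(extra, collapse = ", "))
  }
  df
}

#' Write streamline counts as long-format TSV
#'
#' One row per (scan, side, voxel, area) with columns `subject_id`,
#' `scan_age_months`, `side`, `voxel_x`, `voxel_y`, `area_id`, `count`.
#' Zero counts are written too, so the file alone determines the full
#' matrices.
#'
#' @param dataset a `cc_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
cc_write_counts <- function(dataset, path) {
  stopifnot(inherits(dataset, "cc_dataset"))
  vox <- dataset$grid$voxels
  blocks <- lapply(dataset$scans, function(s) {
    data.frame(subject_id = s$subject_id, scan_age_months = s$scan_age,
               side = s$side,
               voxel_x = rep(vox$x, ncol(s$counts)),
               voxel_y = rep(vox$y, ncol(s$counts)),
               area_id = rep(colnames(s$counts), each = nrow(vox)),
               count = as.integer(s$counts),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, blocks), path)
  invisible(path)
}

#' Read streamline counts from long-format TSV
#'
#' @param path counts TSV written by [cc_write_counts()] (or exported from a
#'   real tractography run in the same schema).
#' @param grid the `cc_grid` the voxels live on.
#' @param metadata optional metadata data frame (from [cc_read_metadata()]);
#'   attached to the dataset when given.
#' @return A `cc_dataset` (without templates).
#' @export
cc_read_counts <- function(path, grid, metadata = NULL) {
  stopifnot(inherits(grid, "cc_grid"))
  df <- read_tsv_checked(path, counts_cols, "counts")
  if (any(df$count < 0)) stop("negative streamline counts in ", path)
  if (!all(df$side %in% c("left", "right"))) {
    stop("side must be 'left' or 'right'")
  }
  vox <- grid$voxels
  vkey <- paste(vox$x, vox$y)
  row_idx <- match(paste(df$voxel_x, df$voxel_y), vkey)
  if (anyNA(row_idx)) {
    bad <- which(is.na(row_idx))[1]
    stop("voxel (", df$voxel_x[bad], ", ", df$voxel_y[bad],
         ") at row ", bad, " is outside the grid mask")
  }
  areas <- sort(unique(df$area_id))
  scan_key <- paste(df$subject_id, df$scan_age_months, df$side, sep = "\r")
  scans <- lapply(split(seq_len(nrow(df)), scan_key), function(ix) {
    d <- df[ix, ]
    m <- matrix(0, nrow(vox), length(areas), dimnames = list(NULL, areas))
    m[cbind(row_idx[ix], match(d$area_id, areas))] <- d$count
    new_cc_counts(m, d$subject_id[1], d$scan_age_months[1], d$side[1], grid)
  })
  ord <- order(vapply(scans, function(s) s$subject_id, character(1)),
               vapply(scans, function(s) s$scan_age, numeric(1)),
               vapply(scans, function(s) s$side, character(1)))
  scans <- unname(scans[ord])
  if (is.null(metadata)) {
    metadata <- unique(data.frame(
      subject_id = vapply(scans, function(s) s$subject_id, character(1)),
      sex = NA_character_, cohort = NA_character_,
      scan_age_months = vapply(scans, function(s) s$scan_age, numeric(1)),
      stringsAsFactors = FALSE))
  }
  structure(list(grid = grid, templates = NULL, scans = scans,
                 subjects = unique(metadata[, c("subject_id", "sex", "cohort")]),
                 metadata = metadata, design = NULL),
            class = "cc_dataset")
}

#' Write / read the subject metadata table
#'
#' Columns: `subject_id`, `sex`, `cohort`, `scan_age_months` (one row per
#' realized scan).
#'
#' @param dataset a `cc_dataset` (writer) or TSV path (reader).
#' @param path output TSV path.
#' @return The writer returns `path` invisibly; the reader a data frame.
#' @export
cc_write_metadata <- function(dataset, path) {
  stopifnot(inherits(dataset, "cc_dataset"))
  write_tsv(dataset$metadata[, metadata_cols], path)
  invisible(path)
}

#' @rdname cc_write_metadata
#' @export
cc_read_metadata <- function(path) {
  df <- read_tsv_checked(path, metadata_cols, "metadata")
  if (!all(df$sex %in% c("male", "female", NA))) {
    stop("sex must be 'male' or 'female'")
  }
  df
}

#' Write a population map as TSV
#'
#' One row per (masked voxel, area): `voxel_x`, `voxel_y`, `area_id`,
#' `p_hat`.
#'
#' @param pop a `cc_popmap`.
#' @param grid the `cc_grid`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
cc_write_popmap <- function(pop, grid, path) {
  stopifnot(inherits(pop, "cc_popmap"), inherits(grid, "cc_grid"))
  vox <- grid$voxels
  df <- data.frame(voxel_x = rep(vox$x, ncol(pop$values)),
                   voxel_y = rep(vox$y, ncol(pop$values)),
                   area_id = rep(colnames(pop$values), each = nrow(vox)),
                   p_hat = as.numeric(pop$values))
  write_tsv(df, path)
  invisible(path)
}

#' Write passage-field boundaries as JSON
#'
#' Each field is serialized with its area id, voxel count, threshold, and a
#' list of closed boundary paths in both grid indices and millimetres
#' relative to the anterior-commissure origin.
#'
#' @param fields list of `cc_field` objects.
#' @param grid the `cc_grid`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
cc_write_boundaries <- function(fields, grid, path) {
  stopifnot(inherits(grid, "cc_grid"))
  ox <- grid$origin[["x"]]; oy <- grid$origin[["y"]]; vs <- grid$voxel_size
  obj <- lapply(fields, function(f) {
    list(area_id = f$area_id, size_voxels = f$size, thr_sq = f$thr_sq,
         boundaries = lapply(f$boundaries, function(b) {
           list(grid = unname(apply(b, 1L, function(r) c(r[1], r[2]),
                                    simplify = FALSE)),
                mm = unname(apply(b, 1L, function(r)
                  c((r[1] - ox) * vs, (r[2] - oy) * vs), simplify = FALSE)))
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 single-slice export. Only what the pipeline needs: float32
# data, one z-slice, voxel size in pixdim, anterior-commissure origin in the
# sform affine. Little-endian throughout.

pad_raw <- function(s, n) {
  r <- charToRaw(s)
  c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r))))
}

#' Write a voxel map as a single-slice NIfTI-1 volume
#'
#' The 2-D grid is embedded as an `n_x` x `n_y` x 1 float32 volume. The sform
#' affine encodes the voxel size and places the anterior commissure at world
#' coordinate [0, 0, 0].
#'
#' @param values full-grid numeric matrix (`n_x` x `n_y`), e.g. a field mask
#'   or a population map embedded via its grid.
#' @param grid the `cc_grid`.
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
cc_write_nifti <- function(values, grid, path) {
  stopifnot(inherits(grid, "cc_grid"), is.matrix(values),
            nrow(values) == grid$n_x, ncol(values) == grid$n_y)
  vs <- grid$voxel_size
  ox <- grid$origin[["x"]]; oy <- grid$origin[["y"]]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(c(3L, grid$n_x, grid$n_y, 1L, 1L, 1L, 1L, 1L), 2)   # dim
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p*, intent_code
  wi(16L, 2); wi(32L, 2); wi(0L, 2)             # datatype float32, bitpix
  wf(c(1, vs, vs, vs, 0, 0, 0, 0))              # pixdim (qfac = 1)
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope/inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(pad_raw("cctopo CC voxel map", 80), con)      # descrip
  writeBin(raw(24), con)                        # aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code 0, sform_code 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))                # quaternion, qoffset
  wf(c(vs, 0, 0, (1 - ox) * vs))                # srow_x
  wf(c(0, vs, 0, (1 - oy) * vs))                # srow_y
  wf(c(0, 0, vs, 0))                            # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  wf(as.numeric(values))
  invisible(path)
}

#' Read a single-slice NIfTI-1 volume written by [cc_write_nifti()]
#'
#' @param path `.nii` path.
#' @return List with `values` (`n_x` x `n_y` matrix), `voxel_size` and
#'   `origin` (grid index implied by the sform affine).
#' @export
cc_read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a NIfTI-1 file (sizeof_hdr != 348)")
  invisible(readBin(con, "raw", 36))
  dim <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))
  datatype <- ri(1, 2)
  if (datatype != 16L) stop("unsupported NIfTI datatype: ", datatype)
  invisible(ri(2, 2))
  pixdim <- rf(8)
  vox_offset <- rf(1)
  invisible(rf(2)); invisible(ri(1, 2)); invisible(readBin(con, "raw", 2))
  invisible(rf(4)); invisible(ri(2, 4))
  invisible(readBin(con, "raw", 104))           # descrip + aux_file
  invisible(ri(2, 2))                           # qform, sform codes
  invisible(rf(6))
  srow_x <- rf(4); srow_y <- rf(4)
  seek(con, vox_offset)
  nx <- dim[2]; ny <- dim[3]
  values <- matrix(rf(nx * ny), nx, ny)
  vs <- pixdim[2]
  list(values = values,
       voxel_size = vs,
       origin = c(x = round(1 - srow_x[4] / vs), y = round(1 - srow_y[4] / vs)))
}
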
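# Bilateral passage-field parcellation.
#
# A cortical area's CC passage field is the set of voxels where the product
# of the left- and right-origin population maps strictly exceeds thr_sq
# (default 0.05^2 = 0.0025). Boundaries are traced per 8-connected component
# (4-connected background), outer contours only: interior holes contribute no
# contour, matching the hole-free convention of standard boundary tracing.

#' Combine left and right population maps into a passage field
#'
#' The field mask keeps the voxels where the voxelwise product of the two
#' hemispheres' population values strictly exceeds `thr_sq`. Requiring both
#' sides suppresses unilateral noise: a voxel with no streamlines from one
#' side is excluded no matter how strong the other side is.
#'
#' @param left,right `cc_popmap` objects sharing the grid and area set.
#' @param area_id the target area to parcel.
#' @param thr_sq product threshold, default `0.05^2 = 0.0025`.
#' @param grid the `cc_grid` the maps live on (used to embed the masked-voxel
#'   vector back into the 2-D grid and to trace boundaries).
#' @return Object of class `cc_field`: list with `area_id`, `mask` (full-grid
#'   logical matrix), `boundaries` (see [cc_trace_boundaries()]), `size`
#'   (number of mask voxels) and `thr_sq`.
#' @export
cc_combine_bilateral <- function(left, right, area_id, grid, thr_sq = 0.0025) {
  stopifnot(inherits(left, "cc_popmap"), inherits(right, "cc_popmap"),
            inherits(grid, "cc_grid"))
  for (m in list(left, right)) {
    if (!area_id %in% colnames(m$values)) {
      stop("area '", area_id, "' absent from a population map")
    }
  }
  if (nrow(left$values) != nrow(grid$voxels) ||
      nrow(right$values) != nrow(grid$voxels)) {
    stop("population maps do not match the grid mask")
  }
  # strict inequality with a tiny relative guard so that exact ties
  # (e.g. 0.05 * 0.05 vs 0.0025) are excluded despite floating-point
  # rounding; population values are multiples of 1/(S*M), so true
  # above-threshold products clear the guard by many orders of magnitude
  guard <- max(thr_sq, 1e-12) * 1e-9
  inside <- left$values[, area_id] * right$values[, area_id] > thr_sq + guard
  mask <- matrix(FALSE, grid$n_x, grid$n_y)
  mask[cbind(grid$voxels$x, grid$voxels$y)] <- inside
  structure(list(area_id = area_id, mask = mask,
                 boundaries = cc_trace_boundaries(mask),
                 size = sum(mask), thr_sq = thr_sq),
            class = "cc_field")
}

#' @export
print.cc_field <- function(x, ...) {
  cat(sprintf("<cc_field> %s: %d voxels, %d component(s), thr_sq=%g\n",
              x$area_id, x$size, length(x$boundaries), x$thr_sq))
  invisible(x)
}

#' Voxel count of a passage field
#'
#' @param field a `cc_field`.
#' @return Integer number of voxels in the field mask.
#' @export
cc_field_size <- function(field) {
  stopifnot(inherits(field, "cc_field"))
  as.integer(sum(field$mask))
}

#' Trace hole-free outer boundaries of a binary mask
#'
#' Returns one ordered closed path per 8-connected component of the mask,
#' traversing the component's outer boundary (Moore neighbourhood tracing).
#' The traced pixels are exactly the mask pixels with a 4-neighbour in the
#' outer background (the grid edge counts as outside); pixels adjacent only
#' to interior holes are not boundary pixels and holes produce no contour.
#'
#' @param mask logical matrix.
#' @return List of integer matrices, one per component, each with columns
#'   `x`, `y` giving the boundary pixels in traversal order (closed path; the
#'   first pixel is not repeated at the end). A single-pixel component gives
#'   a one-row path. An empty mask gives an empty list.
#' @export
cc_trace_boundaries <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) return(list())
  nx <- nrow(mask); ny <- ncol(mask)

  # pad with one background ring so the grid edge behaves as outside
  pad <- matrix(FALSE, nx + 2L, ny + 2L)
  pad[2:(nx + 1L), 2:(ny + 1L)] <- mask

  labels <- cc_label_components(mask, connectivity = 8L)

  # clockwise Moore neighbourhood, starting north (grid x = row = AP axis;
  # treat +y as "up"): N, NE, E, SE, S, SW, W, NW in (dx, dy)
  dxs <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dys <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

  out <- vector("list", max(labels))
  for (comp in seq_len(max(labels))) {
    px <- which(labels == comp, arr.ind = TRUE)
    # start pixel: lowest y, then lowest x -> the pixel below it is outside
    o <- order(px[, 2L], px[, 1L])
    sx <- px[o[1L], 1L]; sy <- px[o[1L], 2L]
    if (nrow(px) == 1L) {
      out[[comp]] <- matrix(c(sx, sy), 1L, dimnames = list(NULL, c("x", "y")))
      next
    }
    # backtrack = background pixel we came "from" (south of the start)
    path_x <- integer(0); path_y <- integer(0)
    cx <- sx; cy <- sy
    bdir <- 5L  # direction from current pixel towards the backtrack (S)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    repeat {
      state <- paste(cx, cy, bdir)
      if (!is.null(seen[[state]])) break  # contour closed (cycle in states)
      assign(state, TRUE, envir = seen)
      path_x <- c(path_x, cx); path_y <- c(path_y, cy)
      # scan clockwise starting just after the backtrack direction
      found <- FALSE
      for (k in seq_len(8L)) {
        d <- ((bdir - 1L + k) %% 8L) + 1L
        nxp <- cx + dxs[d]; nyp <- cy + dys[d]
        if (pad[nxp + 1L, nyp + 1L]) {
          # direction back towards the previously examined (background) cell
          prev <- ((d - 2L) %% 8L) + 1L
          bx <- cx + dxs[prev]; by <- cy + dys[prev]
          cx <- nxp; cy <- nyp
          # new backtrack direction: from new pixel towards (bx, by)
          bdir <- which(dxs == bx - cx & dys == by - cy)
          found <- TRUE
          break
        }
      }
      if (!found) break  # isolated pixel (cannot happen for nrow > 1)
    }
    keep <- !duplicated(cbind(path_x, path_y))
    out[[comp]] <- cbind(x = path_x[keep], y = path_y[keep])
  }
  out
}

#' Per-scan passage-field sizes for longitudinal analysis
#'
#' For each scan of a dataset (requiring both hemispheres), runs the
#' normalization / multi-threshold / averaging pipeline with that single scan
#' as the only sample unit (S = 1), combines the two sides bilaterally, and
#' records the field size. Alternatively pools all scans of each age group
#' into one population map per age (`mode = "per_age_group"`).
#'
#' @param dataset a `cc_dataset`.
#' @param area_id cortical area to parcel.
#' @param scheme threshold scheme (default [cc_threshold_scheme()]).
#' @param thr_sq bilateral product threshold, default 0.0025.
#' @param mode `"per_scan"` (default) or `"per_age_group"`.
#' @return Data frame keyed for the statistics stage:
#'   `subject_id`, `scan_age_months`, `sex`, `cohort`, `area_id`,
#'   `size_voxels` (per-scan mode), or `scan_age_months`, `n_scans`,
#'   `area_id`, `size_voxels` (per-age-group mode).
#' @export
cc_per_scan_fields <- function(dataset, area_id,
                               scheme = cc_threshold_scheme(),
                               thr_sq = 0.0025,
                               mode = c("per_scan", "per_age_group")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "cc_dataset"))
  keys <- vapply(dataset$scans, function(s)
    paste(s$subject_id, s$scan_age, sep = "@"), character(1))
  sides <- vapply(dataset$scans, function(s) s$side, character(1))

  if (mode == "per_age_group") {
    ages <- sort(unique(vapply(dataset$scans, function(s) s$scan_age, numeric(1))))
    rows <- lapply(ages, function(a) {
      sel <- vapply(dataset$scans, function(s) s$scan_age == a, logical(1))
      norm_l <- lapply(dataset$scans[sel & sides == "left"], cc_normalize)
      norm_r <- lapply(dataset$scans[sel & sides == "right"], cc_normalize)
      pl <- cc_population_average(norm_l, scheme, side = "left")
      pr <- cc_population_average(norm_r, scheme, side = "right")
      fld <- cc_combine_bilateral(pl, pr, area_id, dataset$grid, thr_sq)
      data.frame(scan_age_months = a, n_scans = length(norm_l),
                 area_id = area_id, size_voxels = fld$size)
    })
    return(do.call(rbind, rows))
  }

  rows <- list()
  pairs <- list()
  for (k in unique(keys)) {
    il <- which(keys == k & sides == "left")
    ir <- which(keys == k & sides == "right")
    n_pair <- min(length(il), length(ir))
    if (n_pair == 0L) {
      warning("scan ", k, " is missing one hemisphere; skipped")
      next
    }
    for (i in seq_len(n_pair)) pairs[[length(pairs) + 1L]] <- c(il[i], ir[i])
    if (length(il) != length(ir)) {
      warning("scan ", k, " has unpaired hemisphere entries; extras skipped")
    }
  }
  for (pr_idx in pairs) {
    sl <- dataset$scans[[pr_idx[1]]]; sr <- dataset$scans[[pr_idx[2]]]
    pl <- cc_population_average(list(cc_normalize(sl)), scheme, side = "left")
    pr <- cc_population_average(list(cc_normalize(sr)), scheme, side = "right")
    fld <- cc_combine_bilateral(pl, pr, area_id, dataset$grid, thr_sq)
    info <- dataset$metadata[dataset$metadata$subject_id == sl$subject_id &
                             dataset$metadata$scan_age_months == sl$scan_age, ][1, ]
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = sl$subject_id, scan_age_months = sl$scan_age,
      sex = info$sex, cohort = info$cohort,
      area_id = area_id, size_voxels = fld$size,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(subject_id = character(), scan_age_months = numeric(),
                      sex = character(), cohort = character(),
                      area_id = character(), size_voxels = integer()))
  }
  do.call(rbind, rows)
}
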
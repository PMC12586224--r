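# Midsagittal CC voxel grid and area templates for the synthetic cohort
# generator. The grid is 2-D: x runs anterior -> posterior, y ventral ->
# dorsal. World coordinates are millimetres relative to the anterior
# commissure, which sits at grid index `origin` and maps to [0, 0].

#' Construct a midsagittal corpus-callosum voxel grid
#'
#' Builds an elongated, arc-shaped boolean mask mimicking the midsagittal
#' profile of the mouse corpus callosum, on an `n_x` (anterior-posterior) by
#' `n_y` (ventral-dorsal) grid of isotropic voxels. The anterior-commissure
#' reference point is placed inside the grid and anchors the millimetre
#' coordinate system (it maps to `[0, 0]`).
#'
#' @param n_x number of voxels along the anterior-posterior axis.
#' @param n_y number of voxels along the ventral-dorsal axis. The shape must
#'   be elongated: `n_x >= 4 * n_y` and `n_y >= 2`.
#' @param voxel_size isotropic voxel edge length in millimetres (default 0.18,
#'   a typical rodent DWI resolution).
#' @return An object of class `cc_grid`: a list with `n_x`, `n_y`,
#'   `voxel_size`, `origin` (grid index of the anterior commissure), `mask`
#'   (`n_x` x `n_y` logical matrix, a single 8-connected component) and
#'   `voxels`, a data frame of masked voxel indices and their millimetre
#'   coordinates in mask order (the row order of all count matrices).
#' @examples
#' g <- cc_grid(60, 12)
#' sum(g$mask)
#' @export
cc_grid <- function(n_x, n_y, voxel_size = 0.18) {
  if (length(n_x) != 1L || length(n_y) != 1L || n_x <= 0 || n_y <= 0 ||
      n_x != round(n_x) || n_y != round(n_y)) {
    stop("grid dimensions must be positive integers")
  }
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_y < 2L || n_x < 4L * n_y) {
    stop("grid must be elongated: require n_x >= 4 * n_y and n_y >= 2")
  }

  # Arc-shaped mask: the centreline rises in the mid-body (sin bulge) and the
  # sheet thins slightly towards genu and splenium.
  mask <- matrix(FALSE, n_x, n_y)
  t <- (seq_len(n_x) - 1) / (n_x - 1)
  centre <- 1 + (n_y - 1) * (0.30 + 0.40 * sin(pi * t))
  half <- pmax(0.55, n_y * (0.18 + 0.12 * sin(pi * t)))
  for (i in seq_len(n_x)) {
    lo <- max(1L, as.integer(round(centre[i] - half[i])))
    hi <- min(n_y, as.integer(round(centre[i] + half[i])))
    if (hi < lo) hi <- lo
    mask[i, lo:hi] <- TRUE
  }

  origin <- c(x = as.integer(round(0.3 * n_x)), y = 1L)

  grid <- structure(
    list(n_x = n_x, n_y = n_y, voxel_size = voxel_size,
         origin = origin, mask = mask),
    class = "cc_grid"
  )
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  grid$voxels <- data.frame(
    x = as.integer(idx[, 1L]), y = as.integer(idx[, 2L]),
    x_mm = (idx[, 1L] - origin[["x"]]) * voxel_size,
    y_mm = (idx[, 2L] - origin[["y"]]) * voxel_size
  )

  comps <- cc_label_components(mask, connectivity = 8L)
  if (max(comps) != 1L) {
    stop("internal error: generated mask is not a single 8-connected component")
  }
  grid
}

#' @export
print.cc_grid <- function(x, ...) {
  cat(sprintf("<cc_grid> %d x %d voxels (%.3g mm), %d in mask, origin at [%d, %d]\n",
              x$n_x, x$n_y, x$voxel_size, nrow(x$voxels),
              x$origin[["x"]], x$origin[["y"]]))
  invisible(x)
}

n_mask_voxels <- function(grid) nrow(grid$voxels)

#' Label connected components of a binary mask
#'
#' Flood-fill labelling of the `TRUE` pixels of a logical matrix, with
#' foreground connectivity 8 (objects) or 4 (used for background when tracing
#' hole-free boundaries).
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape: 0 for background, 1..k component
#'   labels.
#' @export
cc_label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  if (connectivity == 8L) {
    dx <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dy <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dx <- c(-1L, 1L, 0L, 0L)
    dy <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  for (sx in seq_len(nx)) for (sy in seq_len(ny)) {
    if (!mask[sx, sy] || lab[sx, sy] != 0L) next
    cur <- cur + 1L
    stack_x <- sx; stack_y <- sy
    lab[sx, sy] <- cur
    while (length(stack_x)) {
      cx <- stack_x[length(stack_x)]; cy <- stack_y[length(stack_y)]
      stack_x <- stack_x[-length(stack_x)]
      stack_y <- stack_y[-length(stack_y)]
      for (k in seq_along(dx)) {
        nxp <- cx + dx[k]; nyp <- cy + dy[k]
        if (nxp >= 1L && nxp <= nx && nyp >= 1L && nyp <= ny &&
            mask[nxp, nyp] && lab[nxp, nyp] == 0L) {
          lab[nxp, nyp] <- cur
          stack_x <- c(stack_x, nxp); stack_y <- c(stack_y, nyp)
        }
      }
    }
  }
  lab
}

#' Build per-area streamline-rate templates on a CC grid
#'
#' Each cortical target area gets a smooth unimodal "bump" of expected
#' streamline rate along the anterior-posterior axis of the CC mask: a
#' Gaussian profile in the millimetre AP coordinate, uniform dorso-ventrally,
#' truncated to the mask. Left and right hemisphere templates are identical at
#' construction; any asymmetry is applied later by the simulator. Areas are
#' given in anterior-to-posterior order and this order is preserved.
#'
#' @param grid a `cc_grid`.
#' @param specs data frame with columns `area_id` (unique labels), `ap_mm`
#'   (requested AP centre in mm relative to the anterior commissure, inside
#'   the mask extent), `spread_mm` (Gaussian SD in mm, > 0; large values give
#'   near-uniform coverage) and `peak_rate` (expected streamline count at the
#'   bump peak, > 0). `ap_mm` must be non-decreasing (anterior -> posterior).
#' @return Object of class `cc_templates`: list with `grid`, `table` (the
#'   specs plus realized `ap_center`, the intensity-weighted AP centroid) and
#'   `rates`, a masked-voxel x area matrix of expected rates (shared by both
#'   hemispheres).
#' @export
cc_area_templates <- function(grid, specs) {
  stopifnot(inherits(grid, "cc_grid"), is.data.frame(specs))
  need <- c("area_id", "ap_mm", "spread_mm", "peak_rate")
  miss <- setdiff(need, names(specs))
  if (length(miss)) stop("specs missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(specs$area_id)) stop("duplicated area_id in specs")
  if (any(specs$peak_rate <= 0)) stop("peak_rate must be > 0")
  if (any(specs$spread_mm <= 0)) stop("spread_mm must be > 0")
  if (is.unsorted(specs$ap_mm)) {
    stop("ap_mm must be ordered anterior to posterior (non-decreasing)")
  }
  ap <- grid$voxels$x_mm
  if (any(specs$ap_mm < min(ap) | specs$ap_mm > max(ap))) {
    stop("ap_mm outside the mask extent [",
         min(ap), ", ", max(ap), "] mm")
  }
  rates <- vapply(seq_len(nrow(specs)), function(i) {
    specs$peak_rate[i] * exp(-(ap - specs$ap_mm[i])^2 / (2 * specs$spread_mm[i]^2))
  }, numeric(length(ap)))
  if (!is.matrix(rates)) rates <- matrix(rates, nrow = length(ap))
  colnames(rates) <- specs$area_id

  tab <- specs
  tab$ap_center <- apply(rates, 2L, function(r) sum(r * ap) / sum(r))
  structure(list(grid = grid, table = tab, rates = rates),
            class = "cc_templates")
}

#' @export
print.cc_templates <- function(x, ...) {
  cat(sprintf("<cc_templates> %d areas on %d CC voxels\n",
              ncol(x$rates), nrow(x$rates)))
  invisible(x)
}

#' Default cortical target-area specification
#'
#' A realistic default world for the synthetic generator: 48 cortical target
#' areas per hemisphere, of which 13 have concentrated anterior-posterior
#' ordered passage fields (frontal/limbic areas through somatosensory
#' subregions to visual cortex), 5 contribute weak widespread streamlines, and
#' 30 background areas are essentially unconnected. Rates are scaled so that
#' the mean per-voxel streamline total over the mask equals `budget`
#' (5000 by default, a standard seeds-per-voxel setting for probabilistic
#' tractography).
#'
#' @param grid a `cc_grid`.
#' @param budget mean total expected streamlines per masked voxel.
#' @param n_background number of near-zero background areas (default 30).
#' @return A specs data frame suitable for [cc_area_templates()], with an
#'   extra `class` column (`passage_field`, `widespread_weak`, `background`).
#' @export
cc_default_area_specs <- function(grid, budget = 5000, n_background = 30L) {
  stopifnot(inherits(grid, "cc_grid"))
  ap_lo <- min(grid$voxels$x_mm); ap_hi <- max(grid$voxels$x_mm)
  span <- ap_hi - ap_lo
  passage <- c("ORB", "ILA", "MO", "ACA", "SSp-m", "SSp-n", "SSp-ul",
               "SSp-bfd", "SSp-ll", "SSp-tr", "RSP", "PTLp", "VIS")
  # anterior -> posterior centres, evenly spread over the central 90% of mask
  pos <- ap_lo + span * seq(0.05, 0.95, length.out = length(passage))
  spec_p <- data.frame(
    area_id = passage, ap_mm = pos,
    spread_mm = span * 0.055, peak_rate = 1,
    class = "passage_field"
  )
  weak <- c("AI", "AUD", "GU", "PL", "SSs")
  spec_w <- data.frame(
    area_id = weak,
    ap_mm = ap_lo + span * seq(0.2, 0.8, length.out = length(weak)),
    spread_mm = span * 2,     # near-uniform over the whole mask
    peak_rate = 0.02,
    class = "widespread_weak"
  )
  spec_b <- data.frame(
    area_id = sprintf("BG%02d", seq_len(n_background)),
    ap_mm = ap_lo + span * seq(0.1, 0.9, length.out = n_background),
    spread_mm = span * 2,
    peak_rate = 1e-4,
    class = "background"
  )
  specs <- rbind(spec_p, spec_w, spec_b)
  specs <- specs[order(specs$ap_mm, specs$area_id), ]
  rownames(specs) <- NULL

  # scale all rates so the mean per-voxel total equals the streamline budget
  tmp <- cc_area_templates(grid, specs)
  total <- mean(rowSums(tmp$rates))
  specs$peak_rate <- specs$peak_rate * budget / total
  specs
}
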
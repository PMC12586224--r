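# Left-right symmetry of passage fields: ordinary least squares of the
# right-hemisphere population value on the left, voxelwise, per area. A slope
# of 1 with high adjusted R^2 indicates the CC voxels receive equally strong
# projections from the homotopic cortical areas of the two hemispheres.

#' Paired left/right voxel values for one area
#'
#' @param left,right `cc_popmap` objects sharing grid and area set.
#' @param area_id the area to pair.
#' @param inclusion voxel inclusion rule: `"nonzero_either"` (default) keeps
#'   voxels where either side is positive; `"all"` keeps every masked voxel.
#' @return Data frame with one row per included voxel: `voxel`, `left`,
#'   `right`.
#' @export
cc_paired_values <- function(left, right, area_id,
                             inclusion = c("nonzero_either", "all")) {
  inclusion <- match.arg(inclusion)
  stopifnot(inherits(left, "cc_popmap"), inherits(right, "cc_popmap"))
  for (m in list(left, right)) {
    if (!area_id %in% colnames(m$values)) stop("area '", area_id, "' absent")
  }
  if (nrow(left$values) != nrow(right$values)) {
    stop("maps do not share the grid")
  }
  l <- left$values[, area_id]; r <- right$values[, area_id]
  keep <- if (inclusion == "nonzero_either") pmax(l, r) > 0 else rep(TRUE, length(l))
  data.frame(voxel = which(keep), left = l[keep], right = r[keep])
}

#' Fit the left-right symmetry regression for one area
#'
#' Ordinary least squares of right on left with an intercept. A slope near 1
#' with intercept near 0 and high adjusted R^2 means the voxelwise projection
#' strengths of the two hemispheres agree. Fits with fewer than 3 voxels, or
#' with a degenerate (constant) predictor, are refused and reported as unfit.
#'
#' @param pairs data frame with columns `left` and `right`
#'   (see [cc_paired_values()]).
#' @param area_id optional label carried into the result.
#' @return Object of class `cc_symfit`: list with `area_id`, `n_voxels`,
#'   `slope`, `intercept`, `r2`, `r2_adjusted`, `fit_ok`.
#' @export
cc_fit_symmetry <- function(pairs, area_id = NA_character_) {
  stopifnot(is.data.frame(pairs), all(c("left", "right") %in% names(pairs)))
  n <- nrow(pairs)
  unfit <- function() structure(
    list(area_id = area_id, n_voxels = n, slope = NA_real_,
         intercept = NA_real_, r2 = NA_real_, r2_adjusted = NA_real_,
         fit_ok = FALSE),
    class = "cc_symfit")
  if (n < 3L) return(unfit())
  x <- pairs$left; y <- pairs$right
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(unfit())
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(area_id = area_id, n_voxels = n, slope = slope,
                 intercept = intercept, r2 = r2, r2_adjusted = r2_adj,
                 fit_ok = TRUE),
            class = "cc_symfit")
}

#' @export
print.cc_symfit <- function(x, ...) {
  if (!x$fit_ok) {
    cat(sprintf("<cc_symfit> %s: unfit (n=%d)\n", x$area_id, x$n_voxels))
  } else {
    cat(sprintf("<cc_symfit> %s: slope=%.3f, intercept=%.4f, adj R2=%.3f (n=%d)\n",
                x$area_id, x$slope, x$intercept, x$r2_adjusted, x$n_voxels))
  }
  invisible(x)
}

#' Classify an area as bilaterally symmetric
#'
#' True when the fitted slope lies in the closed band (default `1 +/- 0.5`,
#' endpoints included) and the adjusted R^2 strictly exceeds `r2_min`
#' (default 0.7). Unfit areas are classified `NA`.
#'
#' @param fit a `cc_symfit`.
#' @param band closed slope interval, default `c(0.5, 1.5)`.
#' @param r2_min adjusted-R^2 floor, default 0.7.
#' @return Logical flag (or `NA` if the fit was refused).
#' @export
cc_classify_symmetric <- function(fit, band = c(0.5, 1.5), r2_min = 0.7) {
  stopifnot(inherits(fit, "cc_symfit"), length(band) == 2L, band[1] <= band[2])
  if (!fit$fit_ok) return(NA)
  fit$slope >= band[1] && fit$slope <= band[2] && fit$r2_adjusted > r2_min
}

#' Symmetry table over all areas of a map pair
#'
#' @param left,right `cc_popmap` objects sharing grid and area set.
#' @param areas areas to fit (default all shared areas).
#' @param band,r2_min classification parameters, see
#'   [cc_classify_symmetric()].
#' @param inclusion voxel inclusion rule, see [cc_paired_values()].
#' @return Data frame with `area_id`, `n_voxels`, `slope`, `intercept`,
#'   `r2_adjusted`, `symmetric` (logical, `NA` for unfit areas).
#' @export
cc_symmetry_table <- function(left, right, areas = colnames(left$values),
                              band = c(0.5, 1.5), r2_min = 0.7,
                              inclusion = "nonzero_either") {
  rows <- lapply(areas, function(a) {
    fit <- cc_fit_symmetry(cc_paired_values(left, right, a, inclusion), a)
    data.frame(area_id = a, n_voxels = fit$n_voxels, slope = fit$slope,
               intercept = fit$intercept, r2_adjusted = fit$r2_adjusted,
               symmetric = cc_classify_symmetric(fit, band, r2_min),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
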
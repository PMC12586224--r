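# Population-based probabilistic tractography maps.
#
# Per scan, streamline counts p(v, b) from each CC voxel v to each cortical
# target b are row-normalized to connection probabilities P(v, b); P is
# binarized at a small set of exact decimal thresholds (strict >, equality
# maps to 0); the population map P_hat(v, b) is the average of the binary
# maps over all thresholds and all sample units, i.e. the exceedance fraction
# over (sample, threshold) pairs. Thresholding is performed on the integer
# counts (p * den > thr_num * rowsum) so the strict-inequality convention is
# exact, never subject to floating-point ties.

#' Normalize streamline counts to voxelwise connection probabilities
#'
#' Divides every voxel's streamline counts by that voxel's total across all
#' target areas. Voxels with a zero total are undefined under this
#' normalization; they are set to all-zero and flagged, which keeps the map
#' interpretable and lets downstream stages exclude them.
#'
#' @param counts a `cc_counts` object, or a bare nonnegative integer matrix
#'   (voxels x areas).
#' @return Object of class `cc_normmap`: list with `values` (probabilities,
#'   rows summing to 1 except flagged rows), `zero_flags` (logical per voxel),
#'   and the original integer `counts` and row `totals` (kept so thresholding
#'   can be exact), plus `subject_id`, `scan_age`, `side` when available.
#' @examples
#' m <- cc_normalize(matrix(c(3, 1, 0, 0, 0, 0), 2, 3, byrow = TRUE))
#' m$values
#' m$zero_flags
#' @export
cc_normalize <- function(counts) {
  meta <- list(subject_id = NA_character_, scan_age = NA_real_,
               side = NA_character_)
  if (inherits(counts, "cc_counts")) {
    meta <- counts[c("subject_id", "scan_age", "side")]
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("negative streamline counts are invalid")
  if (any(counts != round(counts))) stop("streamline counts must be integers")
  totals <- rowSums(counts)
  zero <- totals == 0
  values <- counts / ifelse(zero, 1, totals)
  values[zero, ] <- 0
  structure(c(list(values = values, zero_flags = zero, counts = counts,
                   totals = totals), meta),
            class = "cc_normmap")
}

#' Multi-threshold scheme with exact decimal thresholds
#'
#' The default scheme is the five thresholds 0.100 to 0.200 in steps of
#' 0.025, used to average out single-threshold bias. Thresholds are stored as
#' scaled integers (numerator over a power-of-ten denominator) so that the
#' strict-inequality binarization can be computed exactly on integer counts.
#'
#' @param thresholds strictly increasing decimal values in (0, 1), each
#'   representable with at most 6 decimal places.
#' @return Object of class `cc_scheme`: list with `thresholds`, integer
#'   `num` and common `den`, and `M` (number of thresholds).
#' @export
cc_threshold_scheme <- function(thresholds = c(0.100, 0.125, 0.150, 0.175, 0.200)) {
  if (!length(thresholds)) stop("at least one threshold is required")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must be in (0, 1)")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  den <- 10^6
  num <- round(thresholds * den)
  if (any(abs(num - thresholds * den) > 1e-6)) {
    stop("thresholds must be exact decimals with at most 6 places")
  }
  g <- Reduce(gcd_int, c(num, den))
  structure(list(thresholds = thresholds, num = as.numeric(num / g),
                 den = as.numeric(den / g), M = length(thresholds)),
            class = "cc_scheme")
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Binarize a normalized map at one threshold
#'
#' Applies the strict-inequality rule: 1 where `P > thr`, 0 where `P < thr`,
#' and 0 at exact equality (the rule only assigns 1 to strict exceedance).
#' When the map carries its integer counts, the comparison is done as
#' `count * den > num * total`, which is exact; otherwise a plain
#' floating-point comparison is used.
#'
#' @param P a `cc_normmap`, or a numeric matrix of probabilities.
#' @param thr a single threshold in (0, 1); may be given as a number or as
#'   `list(num =, den =)` scaled integers.
#' @return Integer 0/1 matrix of the same shape.
#' @export
cc_binarize <- function(P, thr) {
  if (is.list(thr)) {
    num <- thr$num; den <- thr$den
  } else {
    if (length(thr) != 1L || thr <= 0 || thr >= 1) stop("thr must be in (0, 1)")
    den <- 10^6; num <- round(thr * den)
  }
  if (inherits(P, "cc_normmap")) {
    bin <- (P$counts * den > num * P$totals)
    storage.mode(bin) <- "integer"
    return(bin)
  }
  stopifnot(is.matrix(P))
  bin <- (P * den > num)
  storage.mode(bin) <- "integer"
  bin
}

#' Average binarized maps into a population map
#'
#' The population map is the mean of the thresholded maps over all thresholds
#' of the scheme and all sample units: equivalently, the fraction of
#' (sample, threshold) pairs in which a voxel's probability strictly exceeds
#' the threshold. The result does not depend on sample order and is an
#' integer multiple of `1/(S*M)` at every voxel.
#'
#' @param samples list of `cc_normmap` objects for one hemisphere, sharing
#'   grid shape and area set.
#' @param scheme a `cc_scheme` (default [cc_threshold_scheme()]).
#' @param side label recorded on the output (`"left"`, `"right"` or `NA`).
#' @param sample_unit `"per_scan"` treats each map as one sample unit;
#'   `"per_subject"` first averages the normalized probabilities within each
#'   subject (maps must carry `subject_id`), then binarizes and averages
#'   across subjects, so S becomes the number of subjects.
#' @return Object of class `cc_popmap`: list with `values` (the map),
#'   `exceedance` (integer matrix, `values * S * M`), `n_samples`, `scheme`,
#'   `side`, `sample_unit`.
#' @export
cc_population_average <- function(samples, scheme = cc_threshold_scheme(),
                                  side = NA_character_,
                                  sample_unit = c("per_scan", "per_subject")) {
  sample_unit <- match.arg(sample_unit)
  stopifnot(inherits(scheme, "cc_scheme"))
  if (!length(samples)) stop("at least one sample is required")
  if (!all(vapply(samples, inherits, logical(1), "cc_normmap"))) {
    stop("samples must be cc_normmap objects")
  }
  d1 <- dim(samples[[1]]$values); cn <- colnames(samples[[1]]$values)
  for (s in samples) {
    if (!identical(dim(s$values), d1) || !identical(colnames(s$values), cn)) {
      stop("samples do not share grid shape and area set")
    }
  }

  if (sample_unit == "per_subject") {
    ids <- vapply(samples, function(s) s$subject_id, character(1))
    if (anyNA(ids)) stop("per_subject averaging requires subject ids on every sample")
    samples <- lapply(split(samples, ids), function(grp) {
      cnt <- Reduce(`+`, lapply(grp, function(s) s$counts))
      val <- Reduce(`+`, lapply(grp, function(s) s$values)) / length(grp)
      # within-subject mean probability map; thresholded as plain values
      structure(list(values = val, zero_flags = rowSums(cnt) == 0,
                     counts = NULL, totals = NULL,
                     subject_id = grp[[1]]$subject_id,
                     scan_age = NA_real_, side = grp[[1]]$side),
                class = "cc_normmap")
    })
  }

  S <- length(samples)
  acc <- matrix(0L, d1[1], d1[2], dimnames = list(NULL, cn))
  for (s in samples) {
    for (m in seq_len(scheme$M)) {
      thr <- list(num = scheme$num[m], den = scheme$den)
      if (is.null(s$counts)) {
        acc <- acc + cc_binarize(s$values, thr)
      } else {
        acc <- acc + cc_binarize(s, thr)
      }
    }
  }
  structure(list(values = acc / (S * scheme$M), exceedance = acc,
                 n_samples = S, scheme = scheme, side = side,
                 sample_unit = sample_unit),
            class = "cc_popmap")
}

#' @export
print.cc_popmap <- function(x, ...) {
  cat(sprintf("<cc_popmap> side=%s, S=%d samples (%s), M=%d thresholds, %d voxels x %d areas\n",
              x$side, x$n_samples, x$sample_unit, x$scheme$M,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Per-area mean profile of a population map
#'
#' For each target area, the mean of the population map over all masked CC
#' voxels, and the same mean normalized by the cortical ROI size (number of
#' voxels in the target region), which compensates for larger targets
#' attracting more streamlines.
#'
#' @param pop a `cc_popmap`.
#' @param area_sizes named numeric vector of cortical ROI voxel counts; must
#'   cover every area in the map with positive sizes.
#' @return Data frame with `area_id`, `mean`, `size_normalized_mean`.
#' @export
cc_roi_profile <- function(pop, area_sizes) {
  stopifnot(inherits(pop, "cc_popmap"))
  areas <- colnames(pop$values)
  miss <- setdiff(areas, names(area_sizes))
  if (length(miss)) stop("missing area sizes for: ", paste(miss, collapse = ", "))
  sz <- area_sizes[areas]
  if (any(sz <= 0)) stop("area sizes must be > 0")
  m <- colMeans(pop$values)
  data.frame(area_id = areas, mean = as.numeric(m),
             size_normalized_mean = as.numeric(m / sz),
             row.names = NULL)
}

#' Detectability criteria
#'
#' Cut-offs for classifying each cortical area's callosal projection from its
#' population map: `peak_high` (a passage field has a voxel peak above this),
#' `peak_low` (widespread weak projections stay below this at every voxel)
#' and `mean_min` (minimum CC-wide mean for anything detectable).
#'
#' @param peak_high default 0.15.
#' @param peak_low default 0.08; must be `< peak_high`.
#' @param mean_min default 0.01.
#' @return A classed list of the three cut-offs.
#' @export
cc_detectability_criteria <- function(peak_high = 0.15, peak_low = 0.08,
                                      mean_min = 0.01) {
  if (peak_low >= peak_high) stop("peak_low must be < peak_high")
  structure(list(peak_high = peak_high, peak_low = peak_low,
                 mean_min = mean_min),
            class = "cc_criteria")
}

#' Classify per-area detectability
#'
#' An area is a `passage_field` if its peak voxel value exceeds `peak_high`;
#' `widespread_weak` if its mean exceeds `mean_min` while its peak stays
#' below `peak_low`; otherwise `undetectable`. When both hemispheres are
#' supplied, the peak is the maximum and the mean is the average over the two
#' sides.
#'
#' @param left a `cc_popmap`.
#' @param right optional `cc_popmap` for the other hemisphere.
#' @param criteria a `cc_detectability_criteria()` object.
#' @return Data frame with `area_id`, `peak`, `mean`, `class`, and the
#'   criteria attached as attribute `criteria`.
#' @export
cc_classify_detectability <- function(left, right = NULL,
                                      criteria = cc_detectability_criteria()) {
  stopifnot(inherits(left, "cc_popmap"), inherits(criteria, "cc_criteria"))
  peak <- apply(left$values, 2L, max)
  mn <- colMeans(left$values)
  if (!is.null(right)) {
    stopifnot(inherits(right, "cc_popmap"))
    if (!identical(colnames(right$values), colnames(left$values))) {
      stop("left and right maps must share the area set")
    }
    peak <- pmax(peak, apply(right$values, 2L, max))
    mn <- (mn + colMeans(right$values)) / 2
  }
  cls <- ifelse(peak > criteria$peak_high, "passage_field",
         ifelse(mn > criteria$mean_min & peak < criteria$peak_low,
                "widespread_weak", "undetectable"))
  out <- data.frame(area_id = colnames(left$values), peak = as.numeric(peak),
                    mean = as.numeric(mn), class = as.character(cls),
                    row.names = NULL)
  attr(out, "criteria") <- criteria
  out
}
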
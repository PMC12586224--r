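# Synthetic longitudinal cohort generator. Expected counts follow a
# log-linear model on the template rates:
#   lambda(v, b | subject k, age a) =
#     rate_b(v) * exp(slope_b * (a - ref_age) + sex_b * 1[female] + u_k),
#   u_k ~ Normal(0, subject_sd^2),
# with realized counts drawn from a negative binomial parameterized by mean
# and dispersion (variance = mu + dispersion * mu^2), degenerating to Poisson
# at dispersion 0 and to deterministic rounding under `noise_free`.

#' Describe a longitudinal cohort design
#'
#' Captures the study design emulated by the generator: three cohorts of
#' C57BL/6-type mice entering at 6 or 12 months and scanned at up to four of
#' the ages {6, 12, 18, 24} months, with monotone per-interval dropout, a
#' male-skewed sex split, and per-area age and sex effects on log expected
#' streamline rate with subject-specific random intercepts.
#'
#' Defaults mirror the emulated study: 66 subjects (46 male / 20 female) in
#' cohorts A (22, entry 12 mo), B (12, entry 6 mo) and C (32, entry 6 mo).
#'
#' @param cohorts named list; each element a list with `n` (subjects),
#'   `n_female` and `ages` (scheduled scan ages, strictly increasing, months).
#' @param dropout_prob probability in `[0, 1]` that a subject is lost in each
#'   inter-scan interval (monotone: no re-entry). Default 0.2.
#' @param age_slope named numeric, per-area slope of log expected rate per
#'   month. Unnamed areas get 0.
#' @param sex_effect named numeric, per-area additive log-rate effect for
#'   females (males are the reference). Unnamed areas get 0.
#' @param subject_sd SD of the subject random intercept on the log scale.
#' @param asymmetry nonnegative left-right asymmetry factor; 0 means the two
#'   hemispheres share expected rates exactly. See [cc_mirror_counts()].
#' @param dispersion negative-binomial dispersion (variance inflation); 0
#'   gives Poisson counts.
#' @param noise_free if `TRUE`, counts are the rounded expected rates (no
#'   sampling at all).
#' @param ref_age reference age in months for the age effect (default 6,
#'   study entry, so intercepts are interpretable at baseline).
#' @param seed integer random seed; mandatory, reproducibility is part of the
#'   generator contract.
#' @return Object of class `cc_design` (a validated list).
#' @export
cc_cohort_design <- function(cohorts = list(
                               A = list(n = 22L, n_female = 7L, ages = c(12, 18, 24)),
                               B = list(n = 12L, n_female = 4L, ages = c(6, 12, 18, 24)),
                               C = list(n = 32L, n_female = 9L, ages = c(6, 12, 18, 24))),
                             dropout_prob = 0.2,
                             age_slope = c(ORB = -0.02, ACA = -0.02, MO = -0.02,
                                           RSP = -0.02, "SSp-n" = 0.02,
                                           "SSp-bfd" = 0.02, PTLp = 0.02),
                             sex_effect = c(ORB = 0.3),
                             subject_sd = 0.1,
                             asymmetry = 0,
                             dispersion = 0.05,
                             noise_free = FALSE,
                             ref_age = 6,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory: the generator must be reproducible")
  }
  if (!length(cohorts)) stop("empty design: at least one cohort is required")
  for (nm in names(cohorts)) {
    ch <- cohorts[[nm]]
    if (!all(c("n", "n_female", "ages") %in% names(ch))) {
      stop("cohort '", nm, "' needs fields n, n_female, ages")
    }
    if (ch$n < 1L || ch$n_female < 0L || ch$n_female > ch$n) {
      stop("cohort '", nm, "' has an invalid sex split")
    }
    if (is.unsorted(ch$ages, strictly = TRUE)) {
      stop("cohort '", nm, "' scan ages must be strictly increasing")
    }
  }
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (asymmetry < 0) stop("asymmetry must be >= 0")
  structure(list(cohorts = cohorts, dropout_prob = dropout_prob,
                 age_slope = age_slope, sex_effect = sex_effect,
                 subject_sd = subject_sd, asymmetry = asymmetry,
                 dispersion = dispersion, noise_free = isTRUE(noise_free),
                 ref_age = ref_age, seed = as.integer(seed)),
            class = "cc_design")
}

# smooth unit-magnitude AP perturbation profile used for asymmetry; values
# span [-1, 1] so the right/left rate ratio stays within
# [1/(1+a), 1+a] when the multiplier is (1+a)^s
asym_profile <- function(grid) {
  x <- grid$voxels$x_mm
  rng <- range(x)
  sin(2 * pi * (x - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps))
}

draw_counts <- function(lambda, dispersion, noise_free) {
  if (noise_free) return(round(lambda))
  if (dispersion <= 0) return(rpois(length(lambda), lambda))
  rnbinom(length(lambda), mu = lambda, size = 1 / dispersion)
}

new_cc_counts <- function(counts, subject_id, scan_age, side, grid) {
  structure(list(subject_id = subject_id, scan_age = scan_age, side = side,
                 counts = counts, grid = grid),
            class = "cc_counts")
}

#' @export
print.cc_counts <- function(x, ...) {
  cat(sprintf("<cc_counts> %s @ %g mo, %s: %d voxels x %d areas, %s streamlines\n",
              x$subject_id, x$scan_age, x$side, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Simulate a longitudinal cohort of streamline-count matrices
#'
#' Realizes subjects, dropout and per-scan, per-hemisphere streamline-count
#' matrices from a [cc_cohort_design()] on a [cc_grid()] with
#' [cc_area_templates()]. Identical seeds give bit-identical output.
#'
#' @param design a `cc_design`.
#' @param grid a `cc_grid`.
#' @param templates a `cc_templates` built on `grid`.
#' @return Object of class `cc_dataset`: list with `grid`, `templates`,
#'   `scans` (list of `cc_counts`, two per realized scan: sides left and
#'   right), `subjects` (one row per subject: subject_id, sex, cohort,
#'   random intercept) and `metadata` (one row per realized scan:
#'   subject_id, sex, cohort, scan_age_months).
#' @export
cc_simulate_cohort <- function(design, grid, templates) {
  stopifnot(inherits(design, "cc_design"), inherits(grid, "cc_grid"),
            inherits(templates, "cc_templates"))
  if (!identical(dim(templates$rates)[1], nrow(grid$voxels))) {
    stop("templates are not defined on this grid")
  }
  set.seed(design$seed)

  areas <- colnames(templates$rates)
  slope <- setNames(rep(0, length(areas)), areas)
  slope[intersect(names(design$age_slope), areas)] <-
    design$age_slope[intersect(names(design$age_slope), areas)]
  sexef <- setNames(rep(0, length(areas)), areas)
  sexef[intersect(names(design$sex_effect), areas)] <-
    design$sex_effect[intersect(names(design$sex_effect), areas)]

  # subjects: id, sex, cohort, random intercept
  subjects <- do.call(rbind, lapply(names(design$cohorts), function(nm) {
    ch <- design$cohorts[[nm]]
    data.frame(cohort = nm,
               sex = rep(c("female", "male"), c(ch$n_female, ch$n - ch$n_female)),
               stringsAsFactors = FALSE)
  }))
  subjects$subject_id <- sprintf("S%03d", seq_len(nrow(subjects)))
  subjects$u <- if (design$subject_sd > 0) {
    rnorm(nrow(subjects), 0, design$subject_sd)
  } else rep(0, nrow(subjects))

  # monotone dropout: first scheduled scan always happens, each later
  # interval is survived with probability 1 - dropout_prob
  realized <- lapply(seq_len(nrow(subjects)), function(i) {
    ages <- design$cohorts[[subjects$cohort[i]]]$ages
    keep <- ages[1]
    for (a in ages[-1]) {
      if (stats::runif(1) < design$dropout_prob) break
      keep <- c(keep, a)
    }
    keep
  })

  pert <- asym_profile(grid)
  mult_r <- (1 + design$asymmetry)^pert   # right-side rate multiplier

  scans <- list()
  meta <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    female <- subjects$sex[i] == "female"
    for (a in realized[[i]]) {
      logfx <- slope * (a - design$ref_age) + if (female) sexef else 0
      lam <- sweep(templates$rates, 2L, exp(logfx + subjects$u[i]), `*`)
      for (side in c("left", "right")) {
        lam_s <- if (side == "right") lam * mult_r else lam
        cnt <- matrix(draw_counts(as.numeric(lam_s), design$dispersion,
                                  design$noise_free),
                      nrow = nrow(lam_s), dimnames = dimnames(lam_s))
        scans[[length(scans) + 1L]] <- new_cc_counts(cnt, sid, a, side, grid)
      }
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = sid, sex = subjects$sex[i],
        cohort = subjects$cohort[i], scan_age_months = a,
        stringsAsFactors = FALSE)
    }
  }

  structure(list(grid = grid, templates = templates, scans = scans,
                 subjects = subjects[, c("subject_id", "sex", "cohort", "u")],
                 metadata = do.call(rbind, meta), design = design),
            class = "cc_dataset")
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("<cc_dataset> %d subjects, %d scans (x2 sides), %d areas on %d voxels\n",
              nrow(x$subjects), nrow(x$metadata),
              ncol(x$scans[[1]]$counts), nrow(x$grid$voxels)))
  invisible(x)
}

#' Mirror a left-hemisphere count matrix to the right
#'
#' With `asymmetry = 0` the right-hemisphere matrix is an exact copy of the
#' left. With `asymmetry = a > 0`, expected rates are multiplied voxelwise by
#' a smooth anterior-posterior perturbation `(1 + a)^s(v)` with
#' `s(v) in [-1, 1]` (so the right/left rate ratio lies in
#' `[1/(1+a), 1+a]`) and counts are re-drawn as Poisson around the perturbed
#' rates, using the current RNG state.
#'
#' @param left a `cc_counts` with `side == "left"`.
#' @param asymmetry nonnegative perturbation magnitude.
#' @return A `cc_counts` for the right side, with the perturbation multiplier
#'   attached as attribute `rate_multiplier`.
#' @export
cc_mirror_counts <- function(left, asymmetry = 0) {
  stopifnot(inherits(left, "cc_counts"))
  if (asymmetry < 0) stop("asymmetry must be >= 0")
  if (asymmetry == 0) {
    out <- new_cc_counts(left$counts, left$subject_id, left$scan_age,
                         "right", left$grid)
    attr(out, "rate_multiplier") <- rep(1, nrow(left$counts))
    return(out)
  }
  mult <- (1 + asymmetry)^asym_profile(left$grid)
  lam <- left$counts * mult
  cnt <- matrix(rpois(length(lam), as.numeric(lam)),
                nrow = nrow(lam), dimnames = dimnames(lam))
  out <- new_cc_counts(cnt, left$subject_id, left$scan_age, "right", left$grid)
  attr(out, "rate_multiplier") <- mult
  out
}
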
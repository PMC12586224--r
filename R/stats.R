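# Longitudinal mixed-effects statistics.
#
# Outcomes (passage-field size, voxelwise or field-mean streamline density)
# are modelled as outcome ~ fixed effects + (1 | subject), fitted by maximum
# likelihood. Sex uses male as the reference level; age is in months and
# entered linearly, uncentered. p-values use the residual-df approximation
# (t on n_obs - n_fixed df); the method tag is recorded in every result
# because the choice is a convention, not a given.

lme_formula <- function(fixed) {
  fixed <- unique(fixed)
  allowed <- c("sex", "age", "sex:age")
  if (!length(fixed) || !all(fixed %in% allowed)) {
    stop("fixed terms must be a nonempty subset of {sex, age, sex:age}")
  }
  if ("sex:age" %in% fixed && !all(c("sex", "age") %in% fixed)) {
    stop("the sex:age interaction requires both main effects")
  }
  stats::as.formula(paste("value ~", paste(fixed, collapse = " + "),
                          "+ (1 | subject_id)"))
}

#' Fit a longitudinal linear mixed-effects model
#'
#' Maximum-likelihood fit of `outcome ~ fixed + (1 | subject)` on a
#' longitudinal table, via `lme4::lmer(REML = FALSE)`. Suitable for
#' unbalanced designs with differing entry ages and follow-up depth: the
#' subject random intercept absorbs stable inter-individual differences while
#' the age fixed effect captures the within-lifespan trajectory.
#'
#' @param table data frame with columns `subject_id`, `sex`
#'   (`"male"`/`"female"`, male is the reference level), `age` (months) and
#'   the outcome column.
#' @param fixed character subset of `c("sex", "age", "sex:age")`; the
#'   interaction requires both main effects.
#' @param outcome name of the outcome column (default `"value"`).
#' @return Object of class `cc_lme`: list with `terms` (data frame: `term`,
#'   `estimate`, `se`, `t`, `p`), `converged`, `singular`, `n_obs`,
#'   `n_subjects`, `df`, `method = "ML"`, `df_method = "residual"` and the
#'   fitted `model`.
#' @export
cc_fit_lme <- function(table, fixed = c("sex", "age"), outcome = "value") {
  stopifnot(is.data.frame(table))
  need <- c("subject_id", "age", outcome)
  if ("sex" %in% fixed || "sex:age" %in% fixed) need <- c(need, "sex")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table missing columns: ", paste(miss, collapse = ", "))
  dat <- table
  dat$value <- dat[[outcome]]
  dat <- dat[stats::complete.cases(dat[, need]), , drop = FALSE]
  if (length(unique(dat$subject_id)) < 2L) {
    stop("at least 2 subjects with observations are required")
  }
  if ("sex" %in% need) {
    dat$sex <- factor(dat$sex, levels = c("male", "female"))
    if (any(is.na(dat$sex))) stop("sex must be 'male' or 'female'")
    if (length(unique(dat$sex)) < 2L && any(c("sex", "sex:age") %in% fixed)) {
      stop("a sex term requires both sexes in the table")
    }
  }

  form <- lme_formula(fixed)
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore")
  warns <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = FALSE, control = ctrl),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- !any(grepl("failed to converge", warns, ignore.case = TRUE))
  singular <- lme4::isSingular(fit)

  cf <- summary(fit)$coefficients   # estimate, se, t
  n_obs <- nrow(dat)
  df <- n_obs - nrow(cf)
  p <- 2 * stats::pt(-abs(cf[, "t value"]), df = df)
  terms <- data.frame(term = rownames(cf),
                      estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"],
                      t = cf[, "t value"],
                      p = as.numeric(p),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, converged = converged, singular = singular,
                 n_obs = n_obs, n_subjects = length(unique(dat$subject_id)),
                 df = df, method = "ML", df_method = "residual",
                 model = fit),
            class = "cc_lme")
}

#' @export
print.cc_lme <- function(x, ...) {
  cat(sprintf("<cc_lme> ML fit, %d obs / %d subjects, residual df=%d%s\n",
              x$n_obs, x$n_subjects, x$df,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `alpha`: order the m p-values ascending, find
#' the largest k with `p_(k) <= k/m * alpha`, and reject hypotheses 1..k.
#' q-values are the monotonized `m * p_(i) / i`.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param alpha significance level, default 0.05.
#' @param ids optional unit labels (default index).
#' @param family optional family label recorded on the report.
#' @return Data frame with `id`, `p`, `q`, `significant`; attributes `alpha`
#'   and `family`.
#' @export
cc_bh_fdr <- function(pvals, alpha = 0.05, ids = seq_along(pvals),
                      family = NA_character_) {
  if (!length(pvals)) {
    out <- data.frame(id = character(), p = numeric(), q = numeric(),
                      significant = logical())
    attr(out, "alpha") <- alpha; attr(out, "family") <- family
    return(out)
  }
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1] with no NAs")
  }
  m <- length(pvals)
  o <- order(pvals)
  ps <- pvals[o]
  k <- which(ps <= seq_len(m) / m * alpha)
  cutoff_rank <- if (length(k)) max(k) else 0L
  sig_sorted <- seq_len(m) <= cutoff_rank
  q_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  q <- numeric(m); q[o] <- pmin(q_sorted, 1)
  sig <- logical(m); sig[o] <- sig_sorted
  out <- data.frame(id = ids, p = pvals, q = q, significant = sig)
  attr(out, "alpha") <- alpha; attr(out, "family") <- family
  out
}

#' Voxelwise mixed-effects analysis of streamline density
#'
#' Fits one LME per voxel of a passage field and controls the false discovery
#' rate across the voxels of that field (one family per area and per fixed
#' term). Voxels whose fit fails or does not converge are excluded from the
#' family and counted.
#'
#' @param table long data frame with columns `subject_id`, `sex`, `age`,
#'   `voxel_x`, `voxel_y`, `value` (density at that voxel for that scan).
#' @param fixed fixed-effect terms, see [cc_fit_lme()].
#' @param alpha FDR level, default 0.05.
#' @param family label for the FDR family (typically the area id).
#' @return Object of class `cc_voxelwise`: list with `results` (data frame:
#'   `voxel_x`, `voxel_y`, `term`, `estimate`, `se`, `t`, `p`, `q`,
#'   `significant`, `direction` = sign of t among significant voxels),
#'   `n_voxels`, `n_failed`, `alpha`, `family`.
#' @export
cc_voxelwise_lme <- function(table, fixed = c("sex", "age"), alpha = 0.05,
                             family = NA_character_) {
  stopifnot(is.data.frame(table),
            all(c("voxel_x", "voxel_y", "value") %in% names(table)))
  key <- paste(table$voxel_x, table$voxel_y, sep = ",")
  vox <- unique(key)
  fits <- vector("list", length(vox))
  failed <- 0L
  for (i in seq_along(vox)) {
    sub <- table[key == vox[i], , drop = FALSE]
    f <- tryCatch(cc_fit_lme(sub, fixed = fixed), error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      failed <- failed + 1L
      next
    }
    xy <- as.integer(strsplit(vox[i], ",", fixed = TRUE)[[1]])
    tt <- f$terms[f$terms$term != "(Intercept)", , drop = FALSE]
    tt$voxel_x <- xy[1]; tt$voxel_y <- xy[2]
    fits[[i]] <- tt
  }
  if (failed) message(failed, " voxel fit(s) failed or did not converge; excluded")
  res <- do.call(rbind, fits)
  if (is.null(res) || !nrow(res)) {
    return(structure(list(results = NULL, n_voxels = length(vox),
                          n_failed = failed, alpha = alpha, family = family),
                     class = "cc_voxelwise"))
  }
  out <- lapply(split(res, res$term), function(d) {
    fdr <- cc_bh_fdr(d$p, alpha = alpha,
                     ids = paste(d$voxel_x, d$voxel_y, sep = ","),
                     family = paste0(family, ":", d$term[1]))
    d$q <- fdr$q
    d$significant <- fdr$significant
    d$direction <- ifelse(d$significant, sign(d$t), 0)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res <- res[, c("voxel_x", "voxel_y", "term", "estimate", "se", "t",
                 "p", "q", "significant", "direction")]
  structure(list(results = res, n_voxels = length(vox), n_failed = failed,
                 alpha = alpha, family = family),
            class = "cc_voxelwise")
}

#' @export
print.cc_voxelwise <- function(x, ...) {
  cat(sprintf("<cc_voxelwise> family=%s: %d voxels (%d failed), alpha=%g\n",
              x$family, x$n_voxels, x$n_failed, x$alpha))
  if (!is.null(x$results)) {
    nsig <- tapply(x$results$significant, x$results$term, sum)
    for (tm in names(nsig)) cat(sprintf("  %s: %d significant voxels\n", tm, nsig[[tm]]))
  }
  invisible(x)
}

#' Group-swap confound check
#'
#' Re-runs the voxelwise sex analysis after relabelling a subset of male
#' subjects as female, emulating the housing-confound check of moving a male
#' group into the female group: if the sex effect is biological rather than a
#' group artefact, mislabelling dilutes it.
#'
#' @param table voxelwise density table, see [cc_voxelwise_lme()].
#' @param swap_ids nonempty character vector of subject ids, all male in
#'   `table`, to be relabelled female.
#' @param fixed fixed-effect terms (must include `"sex"`).
#' @param alpha FDR level.
#' @param family family label.
#' @return List with `before` and `after`, each containing `n_significant`
#'   and `mean_t` for the sex term, plus the two full `cc_voxelwise` objects.
#' @export
cc_group_swap <- function(table, swap_ids, fixed = c("sex", "age"),
                          alpha = 0.05, family = NA_character_) {
  if (!length(swap_ids)) stop("swap subset must be nonempty")
  if (!"sex" %in% fixed) stop("the group-swap check needs a sex term")
  sex_of <- unique(table[, c("subject_id", "sex")])
  bad <- swap_ids[!swap_ids %in% sex_of$subject_id]
  if (length(bad)) stop("unknown subjects: ", paste(bad, collapse = ", "))
  not_male <- swap_ids[sex_of$sex[match(swap_ids, sex_of$subject_id)] != "male"]
  if (length(not_male)) {
    stop("swap subset must be all male; not male: ",
         paste(not_male, collapse = ", "))
  }
  before <- cc_voxelwise_lme(table, fixed, alpha, family)
  table2 <- table
  table2$sex[table2$subject_id %in% swap_ids] <- "female"
  after <- cc_voxelwise_lme(table2, fixed, alpha, family)
  sex_stats <- function(vw) {
    if (is.null(vw$results)) return(list(n_significant = 0L, mean_t = NA_real_))
    d <- vw$results[grepl("^sex", vw$results$term), , drop = FALSE]
    sig <- d[d$significant, , drop = FALSE]
    list(n_significant = nrow(sig),
         mean_t = if (nrow(sig)) mean(sig$t) else NA_real_)
  }
  list(before = c(sex_stats(before), list(fit = before)),
       after = c(sex_stats(after), list(fit = after)))
}

#' Simulate a Gaussian longitudinal outcome table
#'
#' Lightweight generator for calibrating the mixed-effects stage directly on
#' its own model: `value = intercept + age_slope * age + sex_effect *
#' 1[female] + u_subject + noise`, with `u ~ N(0, subject_sd^2)` and
#' `noise ~ N(0, resid_sd^2)`. Used for type-I error, parameter-recovery and
#' FDR-control simulations where the full count pipeline would only add cost.
#'
#' @param n_subjects number of subjects (default 40); sexes alternate so both
#'   are represented.
#' @param ages scan ages in months applied to every subject
#'   (default `c(6, 12, 18)`).
#' @param intercept baseline outcome at age 0.
#' @param age_slope fixed age effect per month.
#' @param sex_effect additive female effect (male reference).
#' @param subject_sd SD of subject random intercepts.
#' @param resid_sd residual SD.
#' @param n_voxels if > 1, generates a voxelwise table (`voxel_x`, `voxel_y`
#'   columns) with the sex effect applied only at `effect_voxels`.
#' @param effect_voxels integer indices (into `1:n_voxels`) of the voxels
#'   carrying the sex effect; default all.
#' @param seed optional seed (set it for reproducibility).
#' @return Longitudinal data frame with `subject_id`, `sex`, `age`, `value`
#'   (and voxel coordinates when `n_voxels > 1`).
#' @export
cc_simulate_lme_table <- function(n_subjects = 40L, ages = c(6, 12, 18),
                                  intercept = 100, age_slope = 0,
                                  sex_effect = 0, subject_sd = 5,
                                  resid_sd = 3, n_voxels = 1L,
                                  effect_voxels = seq_len(n_voxels),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- sprintf("S%03d", seq_len(n_subjects))
  sex <- rep(c("male", "female"), length.out = n_subjects)
  u <- rnorm(n_subjects, 0, subject_sd)
  base <- expand.grid(i = seq_len(n_subjects), age = ages)
  rows <- lapply(seq_len(n_voxels), function(v) {
    sx <- if (v %in% effect_voxels) sex_effect else 0
    mu <- intercept + age_slope * base$age +
      sx * (sex[base$i] == "female") + u[base$i]
    df <- data.frame(subject_id = subj[base$i], sex = sex[base$i],
                     age = base$age,
                     value = mu + rnorm(nrow(base), 0, resid_sd),
                     stringsAsFactors = FALSE)
    if (n_voxels > 1L) {
      df$voxel_x <- v; df$voxel_y <- 1L
    }
    df
  })
  do.call(rbind, rows)
}

#' Build a voxelwise density table from a dataset
#'
#' For each realized scan (both hemispheres present) and each voxel of a
#' passage field, computes the scan-level density: the single-scan population
#' value (multi-threshold exceedance fraction with S = 1), averaged over the
#' two hemispheres. With `statistic = "field_mean"` the densities are
#' averaged over the field's voxels into one value per scan.
#'
#' @param dataset a `cc_dataset`.
#' @param area_id cortical area.
#' @param field a `cc_field` delimiting the voxels (e.g. from
#'   [cc_combine_bilateral()] on the whole-dataset population maps).
#' @param scheme threshold scheme.
#' @param statistic `"voxel"` (default) or `"field_mean"`.
#' @return Longitudinal data frame with `subject_id`, `sex`, `cohort`, `age`,
#'   `value` and, for the voxel statistic, `voxel_x`, `voxel_y`.
#' @export
cc_density_table <- function(dataset, area_id, field,
                             scheme = cc_threshold_scheme(),
                             statistic = c("voxel", "field_mean")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(dataset, "cc_dataset"), inherits(field, "cc_field"))
  vox <- dataset$grid$voxels
  in_field <- field$mask[cbind(vox$x, vox$y)]
  if (!any(in_field)) stop("the field is empty")

  keys <- vapply(dataset$scans, function(s)
    paste(s$subject_id, s$scan_age, sep = "@"), character(1))
  sides <- vapply(dataset$scans, function(s) s$side, character(1))
  rows <- list()
  for (k in unique(keys)) {
    il <- which(keys == k & sides == "left")[1]
    ir <- which(keys == k & sides == "right")[1]
    if (is.na(il) || is.na(ir)) next
    sl <- dataset$scans[[il]]; sr <- dataset$scans[[ir]]
    pl <- cc_population_average(list(cc_normalize(sl)), scheme, side = "left")
    pr <- cc_population_average(list(cc_normalize(sr)), scheme, side = "right")
    dens <- (pl$values[in_field, area_id] + pr$values[in_field, area_id]) / 2
    info <- dataset$metadata[dataset$metadata$subject_id == sl$subject_id &
                             dataset$metadata$scan_age_months == sl$scan_age, ][1, ]
    if (statistic == "field_mean") {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sl$subject_id, sex = info$sex, cohort = info$cohort,
        age = sl$scan_age, value = mean(dens), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sl$subject_id, sex = info$sex, cohort = info$cohort,
        age = sl$scan_age, voxel_x = vox$x[in_field],
        voxel_y = vox$y[in_field], value = as.numeric(dens),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
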
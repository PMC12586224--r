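# popmap module: normalization, exact-decimal thresholding, population
# averaging, ROI profiles, detectability

random_counts <- function(nv, na, max = 30L) {
  matrix(sample(0:max, nv * na, replace = TRUE), nv, na,
         dimnames = list(NULL, paste0("b", seq_len(na))))
}

test_that("normalization divides rows by their totals and flags zero rows", {
  m <- cc_normalize(matrix(c(3, 1, 0,
                             0, 0, 0), 2, 3, byrow = TRUE))
  expect_equal(m$values[1, ], c(0.75, 0.25, 0))
  expect_equal(m$values[2, ], c(0, 0, 0))
  expect_identical(m$zero_flags, c(FALSE, TRUE))

  expect_error(cc_normalize(matrix(c(-1, 2), 1)), "negative")

  set.seed(5)
  cnt <- random_counts(50, 10)
  v <- cc_normalize(cnt)$values
  brute <- t(apply(cnt, 1, function(r) if (sum(r) == 0) r * 0 else r / sum(r)))
  expect_equal(v, brute, tolerance = 1e-15)
})

test_that("normalization conserves probability mass (1000 random matrices)", {
  set.seed(6)
  for (i in seq_len(1000)) {
    m <- cc_normalize(random_counts(sample(3:20, 1), sample(2:8, 1), max = 5L))
    sums <- rowSums(m$values)[!m$zero_flags]
    expect_true(all(abs(sums - 1) < 1e-12))
    expect_true(all(rowSums(m$values)[m$zero_flags] == 0))
  }
})

test_that("binarization is strict and exact at decimal thresholds", {
  # P = 0.11 > 0.100 -> 1
  m <- cc_normalize(matrix(c(11, 89), 1))
  expect_equal(cc_binarize(m, 0.100)[1, 1], 1L)
  # exact equality maps to 0: P = 15/100 = 0.150 at thr 0.150
  m2 <- cc_normalize(matrix(c(15, 85), 1))
  expect_equal(cc_binarize(m2, 0.150)[1, 1], 0L)
  # another equality that would be floating-point fragile: 1/8 at 0.125
  m3 <- cc_normalize(matrix(c(1, 7), 1))
  expect_equal(cc_binarize(m3, 0.125)[1, 1], 0L)

  # elementwise oracle on random maps at every scheme threshold
  set.seed(7)
  sch <- cc_threshold_scheme()
  for (i in 1:20) {
    m <- cc_normalize(random_counts(15, 6))
    for (k in seq_len(sch$M)) {
      got <- cc_binarize(m, list(num = sch$num[k], den = sch$den))
      # brute force on exact rationals: count/total > num/den
      brute <- sweep(m$counts * sch$den, 1, sch$num[k] * m$totals, `>`)
      storage.mode(brute) <- "integer"
      expect_identical(got, brute)
    }
  }
  expect_error(cc_binarize(m, 1.5), "thr")
})

test_that("population averaging matches printed single-sample examples", {
  sch <- cc_threshold_scheme()
  # P = 0.12 exceeds only thr 0.100: P_hat = 1/5
  m <- cc_normalize(matrix(c(12, 88), 1))
  expect_equal(cc_population_average(list(m), sch)$values[1, 1], 0.2)
  # all-zero probabilities -> 0
  m0 <- cc_normalize(matrix(c(0, 0), 1))
  expect_equal(cc_population_average(list(m0), sch)$values[1, 1], 0)
  # P = 0.5 exceeds every threshold for every sample -> 1
  mh <- cc_normalize(matrix(c(5, 5), 1))
  expect_equal(cc_population_average(list(mh, mh, mh), sch)$values[1, 1], 1)
})

test_that("population map equals the exhaustive exceedance oracle", {
  set.seed(8)
  sch <- cc_threshold_scheme()
  for (trial in seq_len(500)) {
    samples <- lapply(seq_len(10), function(i) cc_normalize(random_counts(20, 5)))
    pop <- cc_population_average(samples, sch)
    brute <- oracle_exceedance(lapply(samples, `[[`, "values"), sch$thresholds)
    expect_equal(unname(pop$values), unname(brute), tolerance = 1e-12)
    # rational support: S * M * P_hat integral
    expect_true(all(abs(pop$values * 10 * sch$M -
                          round(pop$values * 10 * sch$M)) < 1e-9))
  }
})

test_that("population averaging is permutation invariant and threshold monotone", {
  set.seed(9)
  sch <- cc_threshold_scheme()
  samples <- lapply(seq_len(8), function(i) cc_normalize(random_counts(25, 4)))
  p1 <- cc_population_average(samples, sch)
  p2 <- cc_population_average(rev(samples), sch)
  expect_identical(p1$values, p2$values)

  # binarized maps are voxelwise non-increasing in the threshold, so the map
  # from a scheme prefix dominates the full-scheme map
  for (s in samples) {
    prev <- NULL
    for (k in seq_len(sch$M)) {
      b <- cc_binarize(s, list(num = sch$num[k], den = sch$den))
      if (!is.null(prev)) expect_true(all(prev >= b))
      prev <- b
    }
  }
  prefix <- cc_threshold_scheme(sch$thresholds[1:2])
  expect_true(all(cc_population_average(samples, prefix)$values >=
                    p1$values - 1e-12))
})

test_that("ROI mean profiles match brute-force averages", {
  set.seed(10)
  sch <- cc_threshold_scheme()
  samples <- lapply(1:5, function(i) cc_normalize(random_counts(30, 3)))
  pop <- cc_population_average(samples, sch)
  sizes <- c(b1 = 10, b2 = 4, b3 = 25)
  prof <- cc_roi_profile(pop, sizes)
  for (j in 1:3) {
    expect_equal(prof$mean[j], mean(pop$values[, j]), tolerance = 1e-12)
    expect_equal(prof$size_normalized_mean[j],
                 mean(pop$values[, j]) / sizes[[j]], tolerance = 1e-12)
  }
  # constant map: (c, c / size)
  popc <- pop; popc$values[, 1] <- 0.4
  profc <- cc_roi_profile(popc, sizes)
  expect_equal(profc$mean[1], 0.4)
  expect_equal(profc$size_normalized_mean[1], 0.04)
  # all-zero area
  pop0 <- pop; pop0$values[, 2] <- 0
  expect_equal(cc_roi_profile(pop0, sizes)$mean[2], 0)

  expect_error(cc_roi_profile(pop, sizes[1:2]), "missing area sizes")
})

test_that("detectability classes follow the three printed cut-offs", {
  fake_pop <- function(vals) {
    structure(list(values = vals, n_samples = 1L,
                   scheme = cc_threshold_scheme(), side = "left",
                   sample_unit = "per_scan"),
              class = "cc_popmap")
  }
  v <- cbind(strong = c(0.30, rep(0, 9)),          # peak clears 0.15
             weak = rep(0.02, 10),                 # mean 0.02, peak 0.02 < 0.08
             nothing = rep(0, 10),
             borderline = c(0.05, rep(0.018, 9)))  # mean 0.021, peak 0.05
  cls <- cc_classify_detectability(fake_pop(v))
  expect_equal(cls$class[cls$area_id == "strong"], "passage_field")
  expect_equal(cls$class[cls$area_id == "weak"], "widespread_weak")
  expect_equal(cls$class[cls$area_id == "nothing"], "undetectable")
  expect_equal(cls$class[cls$area_id == "borderline"], "widespread_weak")

  expect_error(cc_detectability_criteria(peak_high = 0.1, peak_low = 0.2),
               "peak_low")
})

test_that("per-subject sample units average within subject first", {
  sch <- cc_threshold_scheme()
  m1 <- cc_normalize(matrix(c(30, 70), 1))   # P = 0.30
  m2 <- cc_normalize(matrix(c(2, 98), 1))    # P = 0.02
  m1$subject_id <- "s1"; m2$subject_id <- "s1"
  m3 <- cc_normalize(matrix(c(50, 50), 1))   # P = 0.50
  m3$subject_id <- "s2"
  pop <- cc_population_average(list(m1, m2, m3), sch,
                               sample_unit = "per_subject")
  # s1 mean P = 0.16 -> exceeds thr 0.100/0.125/0.150 -> 3/5; s2 -> 5/5
  expect_equal(pop$n_samples, 2L)
  expect_equal(pop$values[1, 1], (3 / 5 + 1) / 2)
})
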
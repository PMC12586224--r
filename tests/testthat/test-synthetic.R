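# synthetic_data module: grid construction, area templates, cohort
# simulation, hemisphere mirroring

test_that("cc_grid builds a connected elongated mask with a valid origin", {
  g <- cc_grid(60, 12, 0.18)
  expect_gt(sum(g$mask), 300)
  expect_true(g$origin[["x"]] >= 1 && g$origin[["x"]] <= g$n_x)
  expect_true(g$origin[["y"]] >= 1 && g$origin[["y"]] <= g$n_y)
  # anterior commissure maps to [0, 0] mm
  ac <- g$voxels[g$voxels$x == g$origin[["x"]] & g$voxels$y == g$origin[["y"]], ]
  if (nrow(ac)) expect_equal(unlist(ac[, c("x_mm", "y_mm")]), c(x_mm = 0, y_mm = 0))

  gmin <- cc_grid(8, 2, 0.18)   # boundary of the precondition
  expect_true(any(gmin$mask))

  expect_error(cc_grid(0, 2), "positive")
  expect_error(cc_grid(10, -1), "positive")
  expect_error(cc_grid(10, 12), "elongated")
  expect_error(cc_grid(60, 12, voxel_size = 0), "voxel_size")
})

test_that("grid masks are single components under a flood-fill oracle", {
  for (dims in list(c(8, 2), c(20, 5), c(40, 10), c(60, 12), c(120, 20))) {
    g <- cc_grid(dims[1], dims[2])
    expect_equal(max(oracle_label(g$mask, eight = TRUE)), 1L,
                 info = paste(dims, collapse = "x"))
  }
})

test_that("area templates are ordered, centred and mask-confined", {
  g <- cc_grid(60, 12)
  specs <- data.frame(area_id = c("a", "b", "c"),
                      ap_mm = c(-2, 0, 2), spread_mm = 0.5, peak_rate = 10)
  tm <- cc_area_templates(g, specs)

  # centroids ordered anterior -> posterior, within 1 voxel of requested
  expect_true(all(diff(tm$table$ap_center) > 0))
  expect_true(all(abs(tm$table$ap_center - specs$ap_mm) <= g$voxel_size))

  # brute-force intensity-weighted centroid agrees to 1e-9
  for (a in specs$area_id) {
    r <- tm$rates[, a]
    expect_equal(tm$table$ap_center[tm$table$area_id == a],
                 sum(r * g$voxels$x_mm) / sum(r), tolerance = 1e-9)
  }

  # spread -> infinity gives near-uniform intensity over the mask
  tm_flat <- cc_area_templates(g, data.frame(
    area_id = "u", ap_mm = 0, spread_mm = 1e6, peak_rate = 10))
  expect_lt(diff(range(tm_flat$rates[, "u"])) / mean(tm_flat$rates[, "u"]), 1e-6)

  expect_error(cc_area_templates(g, rbind(specs, specs[1, ])), "ap_mm|duplicated")
  specs2 <- specs; specs2$area_id[2] <- "a"
  expect_error(cc_area_templates(g, specs2), "duplicated")
  specs3 <- specs; specs3$ap_mm[3] <- 99
  expect_error(cc_area_templates(g, specs3), "extent")
})

test_that("noise-free null cohort reproduces rounded template rates", {
  w <- tiny_world()
  d <- cc_cohort_design(
    cohorts = list(A = list(n = 3L, n_female = 1L, ages = c(6, 12))),
    dropout_prob = 0, age_slope = c(A1 = 0), sex_effect = c(A1 = 0),
    subject_sd = 0, dispersion = 0, noise_free = TRUE, seed = 1)
  ds <- cc_simulate_cohort(d, w$grid, w$templates)
  expected <- round(w$templates$rates)
  for (s in ds$scans) expect_identical(unname(s$counts), unname(expected))
})

test_that("simulation is seed-deterministic and respects the design", {
  w <- tiny_world()
  d <- cc_cohort_design(
    cohorts = list(A = list(n = 4L, n_female = 2L, ages = c(6, 12, 18))),
    dropout_prob = 0.3, subject_sd = 0.1, dispersion = 0.1, seed = 7)
  ds1 <- cc_simulate_cohort(d, w$grid, w$templates)
  ds2 <- cc_simulate_cohort(d, w$grid, w$templates)
  expect_identical(lapply(ds1$scans, `[[`, "counts"),
                   lapply(ds2$scans, `[[`, "counts"))
  expect_identical(ds1$metadata, ds2$metadata)

  # counts are nonnegative integers; realized ages subset of scheduled,
  # strictly increasing per subject (monotone dropout)
  for (s in ds1$scans) {
    expect_true(all(s$counts >= 0))
    expect_true(all(s$counts == round(s$counts)))
  }
  for (sid in unique(ds1$metadata$subject_id)) {
    ages <- ds1$metadata$scan_age_months[ds1$metadata$subject_id == sid]
    ages <- ages[!duplicated(ages)]
    expect_true(all(ages %in% c(6, 12, 18)))
    expect_true(!is.unsorted(ages, strictly = TRUE))
  }

  expect_error(cc_cohort_design(cohorts = list(), seed = 1), "empty")
  expect_error(cc_cohort_design(), "seed")
})

test_that("planted age slope matches its analytic log-rate change", {
  # slope 0.02 / month on log rate: expected log-count difference between
  # 24 and 6 months is 0.02 * 18 = 0.36; check by simulation
  g <- cc_grid(16, 4, 0.18)
  span <- range(g$voxels$x_mm)
  tm <- cc_area_templates(g, data.frame(
    area_id = "A1", ap_mm = mean(span), spread_mm = 10, peak_rate = 200))
  diffs <- vapply(seq_len(200), function(r) {
    d <- cc_cohort_design(
      cohorts = list(A = list(n = 1L, n_female = 0L, ages = c(6, 24))),
      dropout_prob = 0, age_slope = c(A1 = 0.02), sex_effect = c(A1 = 0),
      subject_sd = 0, dispersion = 0, seed = 1000 + r)
    ds <- cc_simulate_cohort(d, g, tm)
    sides <- vapply(ds$scans, `[[`, character(1), "side")
    ages <- vapply(ds$scans, `[[`, numeric(1), "scan_age")
    tot <- function(a) sum(ds$scans[[which(sides == "left" & ages == a)]]$counts)
    log(tot(24)) - log(tot(6))
  }, numeric(1))
  expect_equal(mean(diffs), 0.36, tolerance = 0.02)
})

test_that("cc_mirror_counts honours the asymmetry contract", {
  w <- tiny_world()
  d <- cc_cohort_design(
    cohorts = list(A = list(n = 1L, n_female = 0L, ages = 6)),
    dropout_prob = 0, subject_sd = 0, dispersion = 0, seed = 3)
  ds <- cc_simulate_cohort(d, w$grid, w$templates)
  left <- ds$scans[[which(vapply(ds$scans, `[[`, character(1), "side") == "left")]]

  r0 <- cc_mirror_counts(left, 0)
  expect_identical(r0$counts, left$counts)      # byte-identical at 0
  expect_equal(r0$side, "right")

  # downstream symmetry of an exact mirror: slope 1, R^2 1
  sch <- cc_threshold_scheme()
  pl <- cc_population_average(list(cc_normalize(left)), sch, side = "left")
  pr <- cc_population_average(list(cc_normalize(r0)), sch, side = "right")
  fit <- cc_fit_symmetry(cc_paired_values(pl, pr, "A2"), "A2")
  expect_equal(fit$slope, 1)
  expect_equal(fit$r2_adjusted, 1)

  # rate perturbation bound at asymmetry 0.5
  set.seed(11)
  r5 <- cc_mirror_counts(left, 0.5)
  mult <- attr(r5, "rate_multiplier")
  expect_true(all(mult >= 1 / 1.5 - 1e-12 & mult <= 1.5 + 1e-12))
  expect_error(cc_mirror_counts(left, -0.1), "asymmetry")
})
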
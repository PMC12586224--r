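# parcellation module: bilateral product thresholding, boundary tracing,
# field sizes, per-scan field tables

fake_pop <- function(vals) {
  structure(list(values = vals, n_samples = 1L,
                 scheme = cc_threshold_scheme(), side = NA_character_,
                 sample_unit = "per_scan"),
            class = "cc_popmap")
}

test_that("bilateral combination is a strict product threshold", {
  g <- cc_grid(8, 2)
  nv <- nrow(g$voxels)
  l <- matrix(0, nv, 1, dimnames = list(NULL, "A"))
  r <- l
  l[1, 1] <- 0.06; r[1, 1] <- 0.05          # product 0.003 > 0.0025
  l[2, 1] <- 0.05; r[2, 1] <- 0.05          # product 0.0025, equality -> out
  l[3, 1] <- 0.00; r[3, 1] <- 0.99          # annihilation
  fld <- cc_combine_bilateral(fake_pop(l), fake_pop(r), "A", g)
  inside <- fld$mask[cbind(g$voxels$x, g$voxels$y)]
  expect_true(inside[1])
  expect_false(inside[2])
  expect_false(inside[3])
  expect_equal(fld$size, 1L)
  expect_equal(cc_field_size(fld), 1L)

  expect_error(cc_combine_bilateral(fake_pop(l), fake_pop(r), "missing", g),
               "absent")
})

test_that("bilateral masks equal brute-force product thresholding", {
  set.seed(21)
  g <- cc_grid(20, 5)
  nv <- nrow(g$voxels)
  for (trial in 1:50) {
    l <- matrix(round(runif(nv * 2), 3), nv, 2, dimnames = list(NULL, c("A", "B")))
    r <- matrix(round(runif(nv * 2), 3), nv, 2, dimnames = list(NULL, c("A", "B")))
    fld <- cc_combine_bilateral(fake_pop(l), fake_pop(r), "A", g)
    brute <- l[, "A"] * r[, "A"] > 0.0025
    expect_identical(unname(fld$mask[cbind(g$voxels$x, g$voxels$y)]),
                     unname(brute))
    # product bound: bilateral mask subset of each single-side threshold
    expect_true(all(!brute | l[, "A"] > 0.0025))
    expect_true(all(!brute | r[, "A"] > 0.0025))
    # monotonicity in thr_sq
    tighter <- cc_combine_bilateral(fake_pop(l), fake_pop(r), "A", g,
                                    thr_sq = 0.01)
    expect_true(all(fld$mask | !tighter$mask))
  }
})

test_that("boundary tracing handles canonical shapes", {
  # single pixel
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  b <- cc_trace_boundaries(m)
  expect_length(b, 1)
  expect_equal(unname(b[[1]]), matrix(c(2, 2), 1))

  # solid 3x3 block: the 8 perimeter pixels, once each
  m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
  b <- cc_trace_boundaries(m)
  expect_length(b, 1)
  expect_equal(nrow(b[[1]]), 8)
  perim <- expand.grid(x = 2:4, y = 2:4)
  perim <- perim[!(perim$x == 3 & perim$y == 3), ]
  expect_setequal(paste(b[[1]][, 1], b[[1]][, 2]), paste(perim$x, perim$y))

  # 5x5 ring with hollow centre: exactly one outer path, no hole contour
  m <- matrix(FALSE, 7, 7); m[2:6, 2:6] <- TRUE; m[4, 4] <- FALSE
  b <- cc_trace_boundaries(m)
  expect_length(b, 1)
  expect_equal(nrow(b[[1]]), 16)  # outer 5x5 perimeter only

  expect_identical(cc_trace_boundaries(matrix(FALSE, 3, 3)), list())
})

test_that("traced boundaries equal the hole-suppressing oracle on random masks", {
  set.seed(22)
  for (trial in 1:150) {
    nx <- sample(3:30, 1); ny <- sample(3:30, 1)
    mask <- matrix(runif(nx * ny) < runif(1, 0.25, 0.75), nx, ny)
    paths <- cc_trace_boundaries(mask)
    got <- matrix(FALSE, nx, ny)
    for (p in paths) {
      # every boundary pixel is in the mask
      expect_true(all(mask[p]))
      got[p] <- TRUE
    }
    expect_identical(got, oracle_boundary(mask))
    # one path per 8-connected component
    expect_length(paths, max(oracle_label(mask, eight = TRUE)))
  }
})

test_that("field size adds up over components (labelling oracle)", {
  set.seed(23)
  g <- cc_grid(20, 5)
  nv <- nrow(g$voxels)
  for (trial in 1:20) {
    l <- matrix(runif(nv), nv, 1, dimnames = list(NULL, "A"))
    r <- matrix(runif(nv), nv, 1, dimnames = list(NULL, "A"))
    fld <- cc_combine_bilateral(fake_pop(l), fake_pop(r), "A", g, thr_sq = 0.3)
    lab <- oracle_label(fld$mask, eight = TRUE)
    comp_sizes <- if (max(lab)) tabulate(lab[lab > 0]) else integer(0)
    expect_equal(cc_field_size(fld), sum(comp_sizes))
    expect_equal(cc_field_size(fld), sum(fld$mask))
  }
})

test_that("per-scan field sizes follow the S = 1 pipeline", {
  # construct a noise-free symmetric dataset where area A's normalized share
  # is 1 on exactly 40 voxels (P_hat = 1 there) and 0.05 elsewhere (below
  # every threshold, P_hat = 0): the bilateral field has exactly 40 voxels
  g <- cc_grid(24, 6)
  nv <- nrow(g$voxels)
  stopifnot(nv > 40)
  a_cnt <- rep(5L, nv); b_cnt <- rep(95L, nv)
  a_cnt[1:40] <- 30L; b_cnt[1:40] <- 0L
  cnt <- cbind(A = a_cnt, B = b_cnt)
  mk <- function(sid, age, side) cctopo:::new_cc_counts(cnt, sid, age, side, g)
  ds <- structure(list(
    grid = g, templates = NULL,
    scans = list(mk("s1", 6, "left"), mk("s1", 6, "right")),
    subjects = data.frame(subject_id = "s1", sex = "male", cohort = "A"),
    metadata = data.frame(subject_id = "s1", sex = "male", cohort = "A",
                          scan_age_months = 6)),
    class = "cc_dataset")
  tab <- cc_per_scan_fields(ds, "A")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size_voxels, 40L)

  # all-zero counts for the area -> size 0
  cnt0 <- cbind(A = rep(0L, nv), B = rep(1L, nv))
  ds0 <- ds
  ds0$scans <- list(cctopo:::new_cc_counts(cnt0, "s1", 6, "left", g),
                    cctopo:::new_cc_counts(cnt0, "s1", 6, "right", g))
  expect_equal(cc_per_scan_fields(ds0, "A")$size_voxels, 0L)

  # duplicating a scan gives two identical rows (per-scan independence)
  ds2 <- ds
  ds2$scans <- c(ds$scans, ds$scans)
  ds2$metadata <- rbind(ds$metadata, ds$metadata)
  tab2 <- cc_per_scan_fields(ds2, "A")
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$size_voxels, c(40L, 40L))

  # a scan missing one hemisphere is skipped with a warning
  ds3 <- ds
  ds3$scans <- ds$scans[1]
  expect_warning(tab3 <- cc_per_scan_fields(ds3, "A"), "missing one hemisphere")
  expect_equal(nrow(tab3), 0)
})

test_that("per-age-group pooling produces one row per age", {
  w <- tiny_world()
  d <- cc_cohort_design(
    cohorts = list(A = list(n = 4L, n_female = 2L, ages = c(6, 12))),
    dropout_prob = 0, subject_sd = 0.05, dispersion = 0.05, seed = 12)
  ds <- cc_simulate_cohort(d, w$grid, w$templates)
  tab <- cc_per_scan_fields(ds, "A2", mode = "per_age_group")
  expect_equal(tab$scan_age_months, c(6, 12))
  expect_equal(tab$n_scans, c(4L, 4L))
  expect_true(all(tab$size_voxels >= 0))
})
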
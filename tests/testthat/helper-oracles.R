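# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / first principles and must stay independent of the
# implementation paths they check.

# boundary-pixel oracle with hole suppression: for each 8-connected
# component C, flood the complement of C (4-connected) from the padded
# border; C's boundary pixels are those 4-adjacent to that outer region.
# Interior holes of C are unreachable from the border and contribute nothing.
oracle_boundary <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- oracle_label(mask, eight = TRUE)
  res <- matrix(FALSE, nx, ny)
  for (comp in seq_len(max(lab))) {
    C <- lab == comp
    pad <- matrix(TRUE, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- !C
    reach <- oracle_label(pad, eight = FALSE)
    outer <- reach[1, 1]
    for (i in 1:nx) for (j in 1:ny) if (C[i, j]) {
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        if (reach[i + d[1] + 1, j + d[2] + 1] == outer) {
          res[i, j] <- TRUE
          break
        }
      }
    }
  }
  res
}

# queue-based connected-component labelling, written independently of
# cc_label_components (grows a frontier vector instead of a stack)
oracle_label <- function(mask, eight = TRUE) {
  nx <- nrow(mask); ny <- ncol(mask)
  offs <- if (eight) {
    expand.grid(dx = -1:1, dy = -1:1)[-5, ]
  } else {
    data.frame(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))
  }
  lab <- matrix(0L, nx, ny)
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    frontier <- s
    lab[s] <- nxt
    while (length(frontier)) {
      newf <- integer(0)
      for (f in frontier) {
        fi <- (f - 1L) %% nx + 1L; fj <- (f - 1L) %/% nx + 1L
        for (k in seq_len(nrow(offs))) {
          ii <- fi + offs$dx[k]; jj <- fj + offs$dy[k]
          if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
              mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- nxt
            newf <- c(newf, (jj - 1L) * nx + ii)
          }
        }
      }
      frontier <- newf
    }
  }
  lab
}

# exhaustive (sample x threshold) exceedance fraction, double loop
oracle_exceedance <- function(value_mats, thresholds) {
  acc <- matrix(0, nrow(value_mats[[1]]), ncol(value_mats[[1]]))
  for (v in value_mats) {
    for (thr in thresholds) acc <- acc + (v > thr)
  }
  acc / (length(value_mats) * length(thresholds))
}

# literal Benjamini-Hochberg step-up decision: reject H_(1..k) for the
# largest k with p_(k) <= k * alpha / m
oracle_bh_flags <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in m:1) {
    if (ps[i] <= i * alpha / m) { k <- i; break }
  }
  flags <- logical(m)
  if (k > 0) flags[o[seq_len(k)]] <- TRUE
  flags
}

# closed-form OLS (normal equations) for y ~ 1 + x
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)
}

# small default world shared by several tests
tiny_world <- function(n_x = 24L, n_y = 6L, n_areas = 4L) {
  grid <- cc_grid(n_x, n_y, 0.18)
  span <- range(grid$voxels$x_mm)
  specs <- data.frame(
    area_id = paste0("A", seq_len(n_areas)),
    ap_mm = seq(span[1] + 0.3, span[2] - 0.3, length.out = n_areas),
    spread_mm = diff(span) * 0.08,
    peak_rate = 50)
  list(grid = grid, templates = cc_area_templates(grid, specs))
}
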
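# Shared fixtures and independent oracles used across the test files.

cccp_concentrations <- c(0.5, 5, 25, 50, 250, 500, 2500)
dnp_concentrations <- c(0.94, 1.88, 3.75, 7.5, 15, 20, 30, 40)

# A small layout: one experiment, a concentration series, one of each
# control group, n individuals per group.
tiny_layout <- function(concentrations = c(1, 10, 100), n = 1,
                        n_experiments = 1, compound = "X", unit = "ug/L") {
  design_layout(compound, concentrations, unit = unit, n_per_group = n,
                n_experiments = n_experiments, timepoint_h = 24,
                n_control = n, n_solvent = n, n_dead = n)
}

# Hand-rolled z-level measurement row for QC truth-table tests.
z_row <- function(well_id = "W1", z = 1L, segment_count = 1L,
                  ratio = 2, mean_cy3 = 200, mean_fitc = 100,
                  area_px = 100L) {
  z_correct <- segment_count == 1L && !is.na(ratio)
  tibble::tibble(
    well_id = well_id, z = as.integer(z), area_px = area_px,
    mean_cy3 = mean_cy3, mean_fitc = mean_fitc, n_saturated_px = 0L,
    segment_count = as.integer(segment_count), z_correct = z_correct,
    ratio = if (z_correct) ratio else NA_real_
  )
}

# Stack of z rows with the given number of correct / incorrect layers.
z_stack_rows <- function(n_correct, n_incorrect, ratio = 2,
                         bad_segment_count = 0L) {
  rows <- list()
  for (i in seq_len(n_correct)) {
    rows[[length(rows) + 1]] <- z_row(z = length(rows) + 1, ratio = ratio)
  }
  for (i in seq_len(n_incorrect)) {
    rows[[length(rows) + 1]] <- z_row(z = length(rows) + 1,
                                      segment_count = bad_segment_count)
  }
  dplyr::bind_rows(rows)
}

# Independent 8-connected labelling oracle: breadth-first flood fill in
# plain R, written without reference to the package implementation.
oracle_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue) > 0) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- cur[1] + di; nj <- cur[2] + dj
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- nxt
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  lab
}

# Brute-force LL2 binomial maximum-likelihood oracle: dense grid search
# over (b, log e).
oracle_ll2_grid <- function(x, n, k, b_range = c(-12, -0.25),
                            e_range = NULL, nb = 120, ne = 240) {
  if (is.null(e_range)) e_range <- range(x[x > 0])
  bs <- seq(b_range[1], b_range[2], length.out = nb)
  es <- exp(seq(log(e_range[1]), log(e_range[2]), length.out = ne))
  best <- c(NA_real_, NA_real_, Inf)
  for (b in bs) for (e in es) {
    eta <- b * (log(pmax(x, .Machine$double.xmin)) - log(e))
    eta[x == 0] <- if (b < 0) Inf else -Inf
    p <- pmin(pmax(1 / (1 + exp(eta)), 1e-12), 1 - 1e-12)
    v <- -sum(dbinom(k, n, p, log = TRUE))
    if (v < best[3]) best <- c(b, e, v)
  }
  list(b = best[1], e = best[2], nll = best[3])
}

# Brute-force LL4 least-squares oracle with c fixed: dense grid search
# over (b, d, e).
oracle_ll4_grid <- function(x, y, c_fixed, b_range = c(0.25, 8),
                            d_range = NULL, e_range = NULL,
                            nb = 40, nd = 40, ne = 120) {
  if (is.null(d_range)) d_range <- c(0.8, 1.2) * max(y)
  if (is.null(e_range)) e_range <- range(x[x > 0])
  bs <- seq(b_range[1], b_range[2], length.out = nb)
  ds <- seq(d_range[1], d_range[2], length.out = nd)
  es <- exp(seq(log(e_range[1]), log(e_range[2]), length.out = ne))
  best <- c(NA_real_, NA_real_, NA_real_, Inf)
  for (b in bs) for (d in ds) for (e in es) {
    eta <- b * (log(pmax(x, .Machine$double.xmin)) - log(e))
    eta[x == 0] <- if (b < 0) Inf else -Inf
    mu <- c_fixed + (d - c_fixed) / (1 + exp(eta))
    v <- sum((y - mu)^2)
    if (v < best[4]) best <- c(b, d, e, v)
  }
  list(b = best[1], d = best[2], e = best[3], rss = best[4])
}

# Fast phantom settings for image-based tests.
fast_phantom <- function(...) {
  phantom_params(z_levels = 4, ...)
}
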
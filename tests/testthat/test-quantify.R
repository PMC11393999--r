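mask3 <- function(sel) {
  m <- matrix(FALSE, 3, 3)
  m[sel] <- TRUE
  organism_mask(m, 1L, 1L)
}

test_that("saturated Cy3 pixels are excluded from both channel means", {
  # 2-pixel mask, one pixel at the saturation threshold
  cy3 <- matrix(0, 3, 3); fitc <- matrix(0, 3, 3)
  cy3[1, 1] <- 100; cy3[1, 2] <- 65000
  fitc[1, 1] <- 50; fitc[1, 2] <- 60
  m <- masked_channel_means(mask3(cbind(c(1, 1), c(1, 2))), cy3, fitc,
                            well_id = "W")
  expect_equal(m$mean_cy3, 100)
  expect_equal(m$mean_fitc, 50)
  expect_equal(m$n_saturated_px, 1L)
  expect_equal(m$ratio, 2)

  # no saturation: plain masked means
  cy3[] <- 200; fitc[] <- 100
  m2 <- masked_channel_means(mask3(cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))),
                             cy3, fitc, well_id = "W")
  expect_equal(m2$mean_cy3, 200)
  expect_equal(m2$mean_fitc, 100)
  expect_equal(m2$n_saturated_px, 0L)

  # hand-computed 3x3 fixture with mixed values
  cy3 <- matrix(c(100, 200, 65500, 300, 400, 500, 600, 700, 800), 3, 3)
  fitc <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), 3, 3)
  full <- organism_mask(matrix(TRUE, 3, 3), 1L, 1L)
  m3 <- masked_channel_means(full, cy3, fitc, well_id = "W")
  expect_equal(m3$mean_cy3, mean(c(100, 200, 300, 400, 500, 600, 700, 800)))
  expect_equal(m3$mean_fitc, mean(c(10, 20, 40, 50, 60, 70, 80, 90)))
  expect_equal(m3$n_saturated_px, 1L)

  # all mask pixels saturated: undefined means, layer forced incorrect
  cy3[] <- 65535
  m4 <- masked_channel_means(full, cy3, fitc, well_id = "W")
  expect_true(is.na(m4$mean_cy3))
  expect_false(m4$z_correct)
  expect_true(is.na(m4$ratio))
})

test_that("ratio is scale invariant and undefined at zero FITC", {
  r <- z_row(mean_cy3 = 200, mean_fitc = 100)
  expect_equal(red_green_ratio(r), 2)
  r2 <- z_row(mean_cy3 = 600, mean_fitc = 300)
  expect_equal(red_green_ratio(r2), red_green_ratio(r))
  r3 <- z_row(mean_cy3 = 150, mean_fitc = 150)
  expect_equal(red_green_ratio(r3), 1)
  r4 <- z_row(mean_cy3 = 200, mean_fitc = 0)
  expect_warning(expect_true(is.na(red_green_ratio(r4))), "FITC")
})

test_that("the more-than-50% incorrect rule excludes individuals exactly", {
  # 10 z-levels, 6 incorrect: excluded
  expect_false(aggregate_individual(z_stack_rows(4, 6))$qc_pass)
  # 10 z-levels, 5 incorrect: 50% is not "more than 50%", kept
  ind5 <- aggregate_individual(z_stack_rows(5, 5, ratio = 2))
  expect_true(ind5$qc_pass)
  expect_equal(ind5$ratio, 2)
  expect_equal(ind5$n_z_correct, 5L)
  # all layers correct with constant ratio
  ind0 <- aggregate_individual(z_stack_rows(10, 0, ratio = 2))
  expect_equal(ind0$ratio, 2)
  # excluded individuals carry a reason
  ind_multi <- aggregate_individual(z_stack_rows(3, 7,
                                                 bad_segment_count = 2L))
  expect_match(ind_multi$qc_reason, "> 1")
  expect_true(is.na(ind_multi$ratio))
})

test_that("aggregation is invariant to z-level order", {
  set.seed(31)
  z <- z_stack_rows(6, 4)
  z$ratio[z$z_correct] <- runif(6, 1, 3)
  a <- aggregate_individual(z)
  b <- aggregate_individual(z[sample(nrow(z)), ])
  expect_equal(a$ratio, b$ratio)
  expect_equal(a$qc_pass, b$qc_pass)
})

test_that("an injected saturated patch barely moves the measured means", {
  truth <- simulation_truth(seed = 33)
  ph_clean <- fast_phantom()
  ph_patch <- fast_phantom(artifact_rates = list(saturated_patch = 1))
  set.seed(33)
  clean <- generate_well_stack(250, truth, ph_clean, "W")
  set.seed(33)
  patched <- generate_well_stack(250, truth, ph_patch, "W")
  mc <- measure_well_stack(clean$stack)
  mp <- measure_well_stack(patched$stack)
  expect_true(all(mp$n_saturated_px > 0))
  expect_true(all(abs(mp$mean_cy3 - mc$mean_cy3) / mc$mean_cy3 < 0.02))
  expect_true(all(abs(mp$mean_fitc - mc$mean_fitc) / mc$mean_fitc < 0.02))
})

test_that("recovered per-well ratios track the generating truth within 5%", {
  truth <- simulation_truth(seed = 34)
  ph <- fast_phantom()
  set.seed(34)
  for (dose in c(0, 25, 250, 2500)) {
    g <- generate_well_stack(dose, truth, ph, "W")
    ind <- aggregate_individual(measure_well_stack(g$stack))
    expect_true(ind$qc_pass)
    expect_lt(abs(ind$ratio - g$truth$intended_ratio_raw) /
                g$truth$intended_ratio_raw, 0.05)
  }
})
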
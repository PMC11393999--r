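test_that("tabular simulation is deterministic and exact without noise", {
  truth0 <- simulation_truth(noise_sd = 0, seed = 61)
  tabs <- simulate_response_tables(truth0)
  mu <- ll4_response(tabs$jc1$concentration, 2, 0.2, 1, 100)
  expect_equal(tabs$jc1$response, mu)
  expect_equal(nrow(tabs$jc1), 3 * 7)
  expect_true(all(tabs$immobilization$n_immobile <=
                    tabs$immobilization$n_exposed))

  # same seed twice: identical tables
  truth <- simulation_truth(seed = 62)
  t1 <- simulate_response_tables(truth)
  t2 <- simulate_response_tables(truth)
  expect_identical(t1, t2)
})

test_that("simulated immobilization counts recover the generating EC50", {
  est <- vapply(seq_len(200), function(i) {
    tabs <- simulate_response_tables(
      simulation_truth(ll2 = c(b = -4, e = 500), n_exposed_per_conc = 20,
                       n_experiments = 1, seed = 6300 + i))
    fit_ll2(tabs$immobilization)$coef[["e"]]
  }, 1)
  expect_lt(abs(median(est) / 500 - 1), 0.05)
})

test_that("forced artifacts produce the expected segment counts and QC calls", {
  truth <- simulation_truth(seed = 64)
  set.seed(64)
  g_empty <- generate_well_stack(0, truth,
                                 fast_phantom(artifact_rates =
                                                list(empty_well = 1)), "W")
  m_empty <- measure_well_stack(g_empty$stack)
  expect_true(all(m_empty$segment_count == 0))
  expect_false(aggregate_individual(m_empty)$qc_pass)

  g_double <- generate_well_stack(0, truth,
                                  fast_phantom(artifact_rates =
                                                 list(double_occupancy = 1)),
                                  "W")
  m_double <- measure_well_stack(g_double$stack)
  expect_true(all(m_double$segment_count == 2))
  ind <- aggregate_individual(m_double)
  expect_false(ind$qc_pass)
  expect_match(ind$qc_reason, "> 1")
})

test_that("the artifact-free pipeline recovers each well's intended ratio", {
  truth <- simulation_truth(seed = 65)
  ph <- fast_phantom()
  set.seed(65)
  for (dose in c(5, 100, 1000)) {
    g <- generate_well_stack(dose, truth, ph, "W")
    ind <- aggregate_individual(measure_well_stack(g$stack))
    expect_lt(abs(ind$ratio - g$truth$intended_ratio_raw) /
                g$truth$intended_ratio_raw, 0.05)
  }
})

test_that("plate generation writes the full file set deterministically", {
  truth <- simulation_truth(seed = 66)
  lay <- tiny_layout(c(10, 100), n = 1)
  ph <- phantom_params(z_levels = 2)
  dir1 <- withr::local_tempdir()
  generate_plate(lay, truth, ph, dir = dir1, seed = 66)
  # 5 wells x 2 z x 3 channels + layout + immobilization + truth manifest
  expect_length(list.files(dir1, pattern = "\\.tif$"), 5 * 2 * 3)
  expect_true(file.exists(file.path(dir1, "layout.csv")))
  expect_true(file.exists(file.path(dir1, "immobilization.csv")))
  expect_true(file.exists(file.path(dir1, "truth.json")))

  # refusal to overwrite without force
  expect_error(generate_plate(lay, truth, ph, dir = dir1, seed = 66),
               class = "jc1_io_error")

  # byte-identical regeneration under the same seed
  dir2 <- withr::local_tempdir()
  generate_plate(lay, truth, ph, dir = dir2, seed = 66)
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
  expect_identical(
    jsonlite::read_json(file.path(dir1, "truth.json")),
    jsonlite::read_json(file.path(dir2, "truth.json")))
})

test_that("raising the saturated-patch rate never increases QC passes", {
  truth <- simulation_truth(seed = 67)
  lay <- tiny_layout(c(10, 100), n = 2)
  passes <- vapply(c(0, 0.5, 1), function(rate) {
    ph <- fast_phantom(artifact_rates = list(saturated_patch = rate),
                       saturated_patch_frac = 0.98)
    zl <- list()
    generate_plate(lay, truth, ph, write = FALSE, seed = 67,
                   on_stack = function(stack, tr) {
                     zl[[length(zl) + 1]] <<- measure_well_stack(stack)
                   })
    z <- dplyr::bind_rows(zl)
    ind <- dplyr::bind_rows(lapply(split(z, z$well_id),
                                   aggregate_individual))
    sum(ind$qc_pass)
  }, 1)
  expect_true(all(diff(passes) <= 0))
})

test_that("dead-control wells encode the floor ratio", {
  truth <- simulation_truth(seed = 68)
  lay <- plate_layout(tibble::tibble(
    well_id = "DEAD1", compound = "X", concentration = 0, unit = "ug/L",
    role = "dead_control", experiment_id = "E1", timepoint_h = 24,
    n_individuals = 1L))
  captured <- NULL
  generate_plate(lay, truth, fast_phantom(), write = FALSE, seed = 68,
                 on_stack = function(stack, tr) captured <<- list(stack, tr))
  expect_equal(captured[[2]]$intended_ratio_normalized, 0.2)
  ind <- aggregate_individual(measure_well_stack(captured[[1]]))
  # raw ratio = control_ratio * floor
  expect_lt(abs(ind$ratio - 2 * 0.2) / 0.4, 0.05)
})
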
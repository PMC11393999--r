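make_individuals <- function(layout, ratios) {
  tibble::tibble(
    well_id = layout$well_id,
    ratio = ratios,
    n_z_total = 10L, n_z_correct = 10L,
    n_z_segment0 = 0L, n_z_multi = 0L,
    qc_pass = TRUE, qc_reason = NA_character_,
    normalized_ratio = NA_real_
  )
}

test_that("normalization divides by the experiment's control mean", {
  lay <- tiny_layout(c(10), n = 2)
  # controls at 2.0, everything else at 1.0
  ratios <- ifelse(lay$role == "control", 2, 1)
  ind <- make_individuals(lay, ratios)
  norm <- normalize_to_control(ind, lay)
  expect_equal(mean(norm$normalized_ratio[norm$role == "control"]), 1)
  expect_equal(unique(norm$normalized_ratio[norm$role == "treatment"]), 0.5)

  # two experiments with different control means: same raw ratio, different
  # normalized values
  lay2 <- tiny_layout(c(10), n = 1, n_experiments = 2)
  ratios2 <- ifelse(lay2$role == "control",
                    ifelse(lay2$experiment_id == "E1", 2, 4), 1)
  norm2 <- normalize_to_control(make_individuals(lay2, ratios2), lay2)
  trt <- norm2[norm2$role == "treatment", ]
  expect_equal(trt$normalized_ratio[trt$experiment_id == "E1"], 0.5)
  expect_equal(trt$normalized_ratio[trt$experiment_id == "E2"], 0.25)

  # missing controls in an experiment is an error naming it
  lay3 <- plate_layout(as.data.frame(lay)[lay$role != "control", ])
  expect_error(normalize_to_control(make_individuals(lay3, rep(1, nrow(lay3))),
                                    lay3),
               "E1", class = "jc1_normalization_error")
})

test_that("normalization is idempotent on already-normalized data", {
  lay <- tiny_layout(c(1, 10, 100), n = 3)
  set.seed(51)
  ratios <- runif(nrow(lay), 0.5, 2.5)
  norm1 <- normalize_to_control(make_individuals(lay, ratios), lay)
  renorm_input <- norm1[names(make_individuals(lay, ratios))]
  renorm_input$ratio <- norm1$normalized_ratio
  norm2 <- normalize_to_control(renorm_input, lay)
  expect_equal(norm2$normalized_ratio, norm1$normalized_ratio)
  expect_equal(mean(norm2$normalized_ratio[norm2$role == "control"]), 1)
})

test_that("the dead-control floor is their mean normalized ratio", {
  lay <- tiny_layout(c(10), n = 2)
  ind <- make_individuals(lay, rep(1, nrow(lay)))
  ind$normalized_ratio <- ind$ratio
  dead <- lay$role == "dead_control"
  ind$normalized_ratio[dead] <- c(0.18, 0.22)
  expect_equal(dead_control_floor(ind, lay), 0.2)
  expect_equal(dead_control_floor(ind[dead, ][1, ]),
               0.18)

  # no dead controls is a configuration error pointing at the explicit floor
  lay_nd <- plate_layout(as.data.frame(lay)[!dead, ])
  expect_error(dead_control_floor(ind[!dead, ], lay_nd),
               "floor", class = "jc1_configuration_error")

  # estimator accuracy: 10 dead controls with noise sd 0.05 around a true
  # floor of 0.2 estimate it within +-0.03
  set.seed(52)
  di <- tibble::tibble(
    well_id = sprintf("D%d", 1:10), ratio = 1, n_z_total = 10L,
    n_z_correct = 10L, n_z_segment0 = 0L, n_z_multi = 0L, qc_pass = TRUE,
    qc_reason = NA_character_,
    normalized_ratio = rnorm(10, 0.2, 0.05)
  )
  expect_lt(abs(dead_control_floor(di) - 0.2), 0.03)
})

test_that("replicate means are aggregated per experiment and concentration", {
  lay <- tiny_layout(dnp_concentrations, n = 5, n_experiments = 3)
  set.seed(53)
  ind <- make_individuals(lay, runif(nrow(lay), 0.5, 2.5))
  norm <- normalize_to_control(ind, lay)
  pts <- aggregate_replicate_means(norm, lay)
  # 3 experiments x (8 concentrations + 1 control cell)
  expect_equal(nrow(pts), 27)
  expect_true(all(pts$n_individuals == 5))

  # the mean of five known ratios
  one <- norm[norm$role == "treatment" & norm$experiment_id == "E1" &
                norm$concentration == 7.5, ]
  expect_equal(pts$response[pts$experiment_id == "E1" &
                              pts$concentration == 7.5],
               mean(one$normalized_ratio))

  # a fully QC-failed cell is dropped with a warning
  norm2 <- norm
  kill <- norm2$role == "treatment" & norm2$experiment_id == "E2" &
    norm2$concentration == 15
  norm2$qc_pass[kill] <- FALSE
  expect_warning(pts2 <- aggregate_replicate_means(norm2, lay), "dropped")
  expect_equal(nrow(pts2), 26)
})

test_that("control comparison picks the right test and holds its size", {
  # identical groups are never significant
  same <- c(1, 1.1, 0.9, 1.05, 0.95)
  rep1 <- compare_controls(same, same)
  expect_false(rep1$significant)
  expect_gt(rep1$p_value, 0.9)

  # constant groups fall back to the rank-sum test without error
  rep_const <- compare_controls(rep(1, 5), rep(1, 5))
  expect_equal(rep_const$test, "wilcoxon_rank_sum")
  expect_false(rep_const$significant)

  expect_error(compare_controls(c(1, 2), same),
               class = "jc1_insufficient_data_error")

  # type-I error near the nominal 5% for same-distribution groups
  set.seed(54)
  rejections <- replicate(1000, {
    compare_controls(rnorm(10, 1, 0.2), rnorm(10, 1, 0.2))$significant
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.02)

  # a 3-sd shift at n = 15 is detected essentially always
  set.seed(55)
  power <- replicate(200, {
    compare_controls(rnorm(15, 1, 0.1), rnorm(15, 1.3, 0.1))$significant
  })
  expect_gte(mean(power), 0.99)
})
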
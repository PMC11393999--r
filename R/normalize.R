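join_layout <- function(individuals, layout) {
  ind <- as_tibble(individuals)
  lay <- as_tibble(layout)
  meta <- lay[c("well_id", "compound", "concentration", "unit", "role",
                "experiment_id", "timepoint_h")]
  out <- dplyr::left_join(ind, meta, by = "well_id")
  if (anyNA(out$role)) {
    missing <- unique(out$well_id[is.na(out$role)])
    abort(paste0("Well(s) not present in the layout: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "jc1_validation_error")
  }
  out
}

#' Normalize per-individual ratios to the medium control
#'
#' Each individual's red/green ratio is divided by the mean ratio of the
#' QC-passing M7 medium-control individuals of the same experiment and
#' timepoint, so the control group's mean normalized ratio is exactly 1.
#'
#' @param individuals Tibble of individual results (see
#'   [aggregate_individual]).
#' @param layout A [plate_layout] mapping well ids to roles and experiments.
#' @return The individuals tibble with `normalized_ratio` filled in and the
#'   layout metadata columns attached.
#' @export
normalize_to_control <- function(individuals, layout) {
  out <- join_layout(individuals, layout)
  out <- dplyr::group_by(out, .data$experiment_id, .data$timepoint_h)
  out <- dplyr::mutate(out, .ctrl_mean = {
    sel <- .data$role == "control" & .data$qc_pass
    if (!any(sel)) NA_real_ else mean(.data$ratio[sel])
  })
  out <- dplyr::ungroup(out)
  if (anyNA(out$.ctrl_mean)) {
    bad <- unique(out$experiment_id[is.na(out$.ctrl_mean)])
    abort(paste0("No QC-passing medium control in experiment(s): ",
                 paste(bad, collapse = ", ")),
          class = "jc1_normalization_error")
  }
  out$normalized_ratio <- out$ratio / out$.ctrl_mean
  out$.ctrl_mean <- NULL
  out
}

#' Dead-control floor for the JC-1 model's lower limit
#'
#' The lower asymptote of the four-parameter log-logistic JC-1 model is
#' fixed to the mean normalized ratio of non-viable reference organisms
#' (dead controls). The floor is estimated on the normalized scale because
#' the model is fitted to normalized ratios.
#'
#' @param individuals Tibble of individual results with `normalized_ratio`
#'   filled in (see [normalize_to_control]). Rows are restricted to role
#'   `dead_control` using the layout (or an attached `role` column); when
#'   neither is available all rows are assumed to be dead controls.
#' @param layout Optional [plate_layout].
#' @return The arithmetic mean of the QC-passing dead controls' normalized
#'   ratios.
#' @export
dead_control_floor <- function(individuals, layout = NULL) {
  ind <- as_tibble(individuals)
  if (!is.null(layout)) {
    ind <- join_layout(ind, layout)
  }
  if ("role" %in% names(ind)) {
    ind <- ind[ind$role == "dead_control", , drop = FALSE]
  }
  ind <- ind[ind$qc_pass & !is.na(ind$normalized_ratio), , drop = FALSE]
  if (nrow(ind) == 0) {
    abort(paste0("No QC-passing dead controls available; supply the floor ",
                 "value explicitly (e.g. pipeline_config(jc1_floor = ...))."),
          class = "jc1_configuration_error")
  }
  mean(ind$normalized_ratio)
}

#' Replicate means per experiment and concentration
#'
#' One response point per (experiment, concentration) cell: the mean of
#' the QC-passing individuals' normalized ratios, with the number of
#' contributing individuals recorded. Cells with no QC-passing individual
#' are dropped with a warning.
#'
#' @param individuals Tibble of individual results with `normalized_ratio`.
#' @param layout A [plate_layout].
#' @param roles Which layout roles contribute points; defaults to the
#'   medium control (plotted at concentration 0) and the treatments.
#' @return Tibble of response points: `compound`, `concentration`, `unit`,
#'   `experiment_id`, `timepoint_h`, `response`, `n_individuals`,
#'   `endpoint = "jc1"`.
#' @export
aggregate_replicate_means <- function(individuals, layout,
                                      roles = c("control", "treatment")) {
  ind <- as_tibble(individuals)
  if (!all(c("role", "concentration") %in% names(ind))) {
    ind <- join_layout(ind, layout)
  }
  ind <- ind[ind$role %in% roles, , drop = FALSE]
  cells <- dplyr::distinct(ind, .data$compound, .data$concentration,
                           .data$unit, .data$experiment_id,
                           .data$timepoint_h, .data$role)
  ok <- ind[ind$qc_pass & !is.na(ind$normalized_ratio), , drop = FALSE]
  pts <- dplyr::summarise(
    dplyr::group_by(ok, .data$compound, .data$concentration, .data$unit,
                    .data$experiment_id, .data$timepoint_h, .data$role),
    response = mean(.data$normalized_ratio),
    n_individuals = dplyr::n(),
    .groups = "drop"
  )
  n_dropped <- nrow(cells) - nrow(pts)
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " (experiment, concentration) cell(s) had no ",
                "QC-passing individuals and were dropped."))
  }
  pts$endpoint <- "jc1"
  pts
}

#' Compare the medium control with the solvent control
#'
#' Each group is checked for normality (Shapiro-Wilk); if both pass at the
#' given alpha, a two-sided Welch two-sample t-test compares the groups,
#' otherwise a Wilcoxon rank-sum test is used. Constant groups are treated
#' as failing the normality check.
#'
#' @param m7 Numeric vector of medium-control values (>= 3).
#' @param solvent Numeric vector of solvent-control (DMSO) values (>= 3).
#' @param alpha Significance level, default 0.05.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `significant`,
#'   `shapiro_p_m7`, `shapiro_p_solvent`, `alpha`.
#' @export
compare_controls <- function(m7, solvent, alpha = 0.05) {
  m7 <- m7[is.finite(m7)]
  solvent <- solvent[is.finite(solvent)]
  if (length(m7) < 3 || length(solvent) < 3) {
    abort("Both control groups need >= 3 QC-passing values.",
          class = "jc1_insufficient_data_error")
  }
  shapiro_p <- function(v) {
    if (length(unique(v)) < 3 || sd(v) == 0) return(0)
    shapiro.test(v)$p.value
  }
  p1 <- shapiro_p(m7)
  p2 <- shapiro_p(solvent)
  if (p1 > alpha && p2 > alpha) {
    tt <- t.test(m7, solvent, var.equal = FALSE)
    test <- "welch_t"
    statistic <- unname(tt$statistic)
    p_value <- tt$p.value
  } else {
    tt <- suppressWarnings(wilcox.test(m7, solvent, exact = FALSE))
    test <- "wilcoxon_rank_sum"
    statistic <- unname(tt$statistic)
    # fully tied samples give an undefined normal approximation: no evidence
    # of a difference
    p_value <- if (is.na(tt$p.value)) 1 else tt$p.value
  }
  tibble(
    test = test, statistic = statistic, p_value = p_value,
    significant = p_value < alpha,
    shapiro_p_m7 = p1, shapiro_p_solvent = p2, alpha = alpha
  )
}
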
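#' Tidy a log-logistic fit
#'
#' @param x An `ll_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (`NA` for fixed parameters) and `fixed`.
#' @exportS3Method generics::tidy
tidy.ll_fit <- function(x, ...) {
  terms <- names(x$coef)
  se <- setNames(rep(NA_real_, length(terms)), terms)
  free <- intersect(terms, rownames(x$vcov))
  se[free] <- sqrt(pmax(diag(x$vcov)[free], 0))
  tibble(
    term = terms,
    estimate = unname(x$coef),
    std.error = unname(se),
    fixed = terms %in% x$fixed
  )
}

#' One-row summary of a log-logistic fit
#'
#' @param x An `ll_fit`.
#' @param ... Unused.
#' @return A tibble: `family`, `endpoint`, `n_points`, `converged`, `ec50`.
#' @exportS3Method generics::glance
glance.ll_fit <- function(x, ...) {
  tibble(
    family = x$family,
    endpoint = x$endpoint,
    n_points = x$n_points,
    converged = x$converged,
    ec50 = x$coef[["e"]]
  )
}

#' Plot a log-logistic fit with its data
#'
#' Observed points (replicate means or immobile fractions) over the fitted
#' curve on a log-scaled concentration axis; zero-dose points are drawn at
#' a pseudo-concentration one decade below the smallest positive dose.
#'
#' @param object An `ll_fit`.
#' @param n_curve Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ll_fit <- function(object, n_curve = 200, ...) {
  dat <- object$data
  if (object$family == "LL2") {
    pts <- tibble(concentration = dat$concentration,
                  response = dat$n_immobile / dat$n_exposed)
    ylab <- "Immobile fraction"
  } else {
    pts <- tibble(concentration = dat$concentration,
                  response = dat$response)
    ylab <- "Normalized red/green ratio"
  }
  pos <- pts$concentration[pts$concentration > 0]
  x0 <- min(pos) / 10
  pts$concentration[pts$concentration == 0] <- x0
  xs <- exp(seq(log(x0), log(max(pos)), length.out = n_curve))
  curve <- tibble(
    concentration = xs,
    response = ll4_response(xs, object$coef[["b"]], object$coef[["c"]],
                            object$coef[["d"]], object$coef[["e"]])
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$concentration,
                                    y = .data$response)) +
    ggplot2::geom_line(data = curve, colour = "#2166ac") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Concentration", y = ylab,
                  title = paste0(object$family, " fit",
                                 if (!is.na(object$endpoint))
                                   paste0(" (", object$endpoint, ")")
                                 else "")) +
    ggplot2::theme_minimal()
}

#' Plot per-well QC status across a plate
#'
#' @param individuals Per-individual results from [analyze_plate].
#' @return A ggplot bar chart of QC outcomes by reason.
#' @export
plot_qc_summary <- function(individuals) {
  ind <- as_tibble(individuals)
  ind$status <- ifelse(ind$qc_pass, "pass", ind$qc_reason)
  ggplot2::ggplot(ind, ggplot2::aes(x = .data$status)) +
    ggplot2::geom_bar(fill = "#4393c3") +
    ggplot2::labs(x = "QC outcome", y = "Individuals") +
    ggplot2::theme_minimal()
}
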
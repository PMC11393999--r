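ll_linpred <- function(x, b, e) {
  # b * (ln x - ln e), with the x = 0 limit resolved by the sign of b so
  # that the response approaches the correct asymptote at zero dose
  eta <- b * (log(x) - log(e))
  zero <- !is.na(x) & x == 0
  if (any(zero)) {
    eta[zero] <- if (b < 0) Inf else if (b > 0) -Inf else NaN
  }
  eta
}

#' Two-parameter log-logistic response
#'
#' The quantal concentration-response family used for immobilization, with
#' lower and upper limits fixed to 0 and 1:
#' `f(x) = 1 / (1 + exp(b (ln x - ln e)))`. With negative slope `b` the
#' response increases from 0 at zero dose to 1 at high dose; `e` is the
#' inflection concentration (EC50).
#'
#' @param x Concentration(s), non-negative.
#' @param b Slope (dimensionless).
#' @param e Inflection concentration, positive.
#' @return Response in `[0, 1]`, vectorized over `x`.
#' @export
ll2_response <- function(x, b, e) {
  if (!is.numeric(e) || length(e) != 1 || !is.finite(e) || e <= 0) {
    abort("Inflection parameter e must be a positive number.",
          class = "jc1_domain_error")
  }
  if (any(x < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative.", class = "jc1_domain_error")
  }
  stats::plogis(-ll_linpred(x, b, e))
}

#' Four-parameter log-logistic response
#'
#' `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))`, the drc-style
#' `(b, c, d, e)` parameterization. With `(c, d) = (0, 1)` it reduces
#' exactly to [ll2_response]. For the JC-1 endpoint the lower limit `c` is
#' fixed to the dead-control floor, the upper limit `d` is close to 1 on
#' the normalized scale, and positive `b` gives a response decreasing from
#' `d` toward `c` with dose.
#'
#' @inheritParams ll2_response
#' @param c Lower limit.
#' @param d Upper limit, `d >= c`.
#' @return Response, vectorized over `x`.
#' @export
ll4_response <- function(x, b, c, d, e) {
  if (d < c) {
    abort("Upper limit d must be >= lower limit c.",
          class = "jc1_domain_error")
  }
  c + (d - c) * ll2_response(x, b, e)
}

new_ll_fit <- function(family, coef, fixed, vcov, n_points, converged,
                       data, endpoint = NA_character_, diagnostics = NULL) {
  structure(
    list(family = family, coef = coef, fixed = fixed, vcov = vcov,
         n_points = n_points, converged = converged, data = data,
         endpoint = endpoint, diagnostics = diagnostics),
    class = "ll_fit"
  )
}

#' @export
print.ll_fit <- function(x, ...) {
  cat("<ll_fit> ", x$family, " (", if (x$converged) "converged" else
    "NOT converged", ")\n", sep = "")
  est <- x$coef
  tags <- ifelse(names(est) %in% x$fixed, " (fixed)", "")
  for (nm in names(est)) {
    cat(sprintf("  %s = %.6g%s\n", nm, est[[nm]],
                tags[match(nm, names(est))]))
  }
  invisible(x)
}

ll2_nll <- function(theta, x, n, k) {
  b <- theta[1]; e <- exp(theta[2])
  p <- stats::plogis(-ll_linpred(x, b, e))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(stats::dbinom(k, n, p, log = TRUE))
}

#' Fit the two-parameter log-logistic model to immobilization counts
#'
#' Maximizes the binomial likelihood of immobilized counts with
#' `p(x) = ll2_response(x, b, e)`. Counts (not fractions) drive the fit, so
#' 0/1 plateaus are handled gracefully; a least-squares mode on the
#' observed fractions is provided for sensitivity checks. The covariance of
#' `(b, e)` comes from the inverse observed information at the optimum
#' (computed on `(b, ln e)` and mapped back by the delta method).
#'
#' @param records Tibble of immobilization records with columns
#'   `concentration`, `n_exposed`, `n_immobile` (records at the same
#'   concentration are pooled by the likelihood).
#' @param method `"binomial_ml"` (default) or `"least_squares"`.
#' @return An `ll_fit` with family `"LL2"`, `c = 0` and `d = 1` fixed.
#' @export
fit_ll2 <- function(records, method = c("binomial_ml", "least_squares")) {
  method <- match.arg(method)
  rec <- as_tibble(records)
  stopifnot(all(c("concentration", "n_exposed", "n_immobile") %in% names(rec)))
  x <- rec$concentration; n <- rec$n_exposed; k <- rec$n_immobile
  pos <- unique(x[x > 0])
  frac <- k / n
  if (length(pos) < 2) {
    abort("Need >= 2 distinct positive concentrations.",
          class = "jc1_fit_error")
  }
  if (all(k == 0) || all(k == n)) {
    abort("All-zero or all-one responses: LL2 parameters are not identifiable.",
          class = "jc1_fit_error")
  }
  # direction of effect sets the slope sign: immobilization rising with
  # dose corresponds to negative b in this parameterization
  posmask <- x > 0
  slope_dir <- stats::cor(log(x[posmask]), frac[posmask])
  b0 <- if (is.na(slope_dir) || slope_dir >= 0) -1 else 1
  e0 <- x[posmask][which.min(abs(frac[posmask] - 0.5))]
  if (!is.finite(e0) || e0 <= 0) e0 <- exp(mean(log(pos)))

  if (method == "least_squares") {
    obj <- function(theta) {
      p <- stats::plogis(-ll_linpred(x, theta[1], exp(theta[2])))
      sum((frac - p)^2)
    }
  } else {
    obj <- function(theta) ll2_nll(theta, x, n, k)
  }

  starts <- list(c(b0, log(e0)),
                 c(2 * b0, log(e0) + 1),
                 c(0.5 * b0, log(e0) - 1))
  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0 && !is.null(best) &&
        opt$value <= best$value + 1e-9) break
  }
  if (is.null(best)) {
    abort("LL2 optimization failed from all starts.", class = "jc1_fit_error")
  }
  theta <- best$par
  hess <- tryCatch(
    stats::optimHess(theta, obj),
    error = function(e) NULL
  )
  b_hat <- theta[1]; e_hat <- exp(theta[2])
  vc <- matrix(NA_real_, 2, 2, dimnames = list(c("b", "e"), c("b", "e")))
  converged <- best$convergence == 0
  if (!is.null(hess)) {
    vc_theta <- tryCatch(solve(hess), error = function(e) NULL)
    if (method == "least_squares" && !is.null(vc_theta)) {
      # Gauss-Newton style scaling by the residual variance
      dfree <- max(length(x) - 2, 1)
      vc_theta <- vc_theta * 2 * best$value / dfree
    }
    if (!is.null(vc_theta) && all(is.finite(vc_theta)) &&
        all(diag(vc_theta) >= 0)) {
      jac <- diag(c(1, e_hat))
      vc <- jac %*% vc_theta %*% t(jac)
      dimnames(vc) <- list(c("b", "e"), c("b", "e"))
    } else {
      converged <- FALSE
    }
  } else {
    converged <- FALSE
  }
  new_ll_fit(
    family = "LL2",
    coef = c(b = b_hat, c = 0, d = 1, e = e_hat),
    fixed = c("c", "d"),
    vcov = vc,
    n_points = length(x),
    converged = converged,
    data = rec,
    endpoint = "immobilization",
    diagnostics = list(value = best$value, method = method,
                       optim_convergence = best$convergence)
  )
}

ll4_unsafe <- function(x, b, c, d, e) {
  c + (d - c) * stats::plogis(-ll_linpred(x, b, abs(e) + 1e-300))
}

#' Fit the four-parameter log-logistic model with a fixed lower limit
#'
#' Least-squares fit of [ll4_response] to replicate-mean normalized JC-1
#' ratios with the lower limit `c` frozen at the dead-control floor; free
#' parameters are `(b, d, e)`. The covariance is the residual variance
#' times the inverse Gauss-Newton curvature at the solution. Fitting is
#' multi-start: the initial inflection is the concentration whose response
#' is nearest the midpoint, the slope sign follows the response direction,
#' and up to three perturbed restarts are tried on non-convergence.
#'
#' @param points Tibble of response points with columns `concentration` and
#'   `response` (normalized ratio).
#' @param c_fixed Lower-limit value, typically from [dead_control_floor];
#'   must be below the maximum response.
#' @return An `ll_fit` with family `"LL4"` and `c` fixed.
#' @export
fit_ll4 <- function(points, c_fixed) {
  pts <- as_tibble(points)
  stopifnot(all(c("concentration", "response") %in% names(pts)))
  x <- pts$concentration; y <- pts$response
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x[x > 0])) < 3) {
    abort("Need >= 3 distinct positive concentrations.",
          class = "jc1_fit_error")
  }
  if (!is.finite(c_fixed) || c_fixed >= max(y)) {
    abort("c_fixed must be finite and below the maximum response.",
          class = "jc1_fit_error")
  }
  d0 <- max(y)
  mid <- (d0 + c_fixed) / 2
  posmask <- x > 0
  e0 <- x[posmask][which.min(abs(y[posmask] - mid))]
  if (!is.finite(e0) || e0 <= 0) e0 <- exp(mean(log(unique(x[posmask]))))
  slope_dir <- stats::cor(log(x[posmask]), y[posmask])
  b0 <- if (is.na(slope_dir) || slope_dir <= 0) 1 else -1

  dat <- data.frame(x = x, y = y)
  starts <- list(c(b = b0, d = d0, e = e0),
                 c(b = 2 * b0, d = d0, e = 2 * e0),
                 c(b = 0.5 * b0, d = d0 * 1.1, e = 0.5 * e0))
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ ll4_unsafe(x, b, c_fixed, d, e),
        data = dat, start = as.list(s),
        lower = c(b = -Inf, d = -Inf, e = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && isTRUE(fit$convInfo$isConv)) break
  }
  if (!is.null(fit)) {
    est <- coef(fit)
    rss <- sum(stats::resid(fit)^2)
    vc_free <- tryCatch(vcov(fit), error = function(e)
      matrix(NA_real_, 3, 3, dimnames = list(names(est), names(est))))
    converged <- isTRUE(fit$convInfo$isConv) && all(is.finite(vc_free))
    diag_info <- list(rss = rss, optimizer = "nlsLM",
                      isConv = fit$convInfo$isConv)
  } else {
    # Levenberg-Marquardt failed from every start (typically a response
    # gradient too weak to pin the inflection down); fall back to a direct
    # simplex search so the caller still gets estimates, flagged
    # non-converged unless the Gauss-Newton curvature is usable
    obj <- function(th) {
      sum((y - ll4_unsafe(x, th[1], c_fixed, th[2], exp(th[3])))^2)
    }
    o <- stats::optim(c(b0, d0, log(e0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    est <- c(b = o$par[1], d = o$par[2], e = exp(o$par[3]))
    rss <- o$value
    vc_free <- ll4_gn_vcov(x, y, est, c_fixed)
    converged <- o$convergence == 0 && all(is.finite(vc_free))
    diag_info <- list(rss = rss, optimizer = "optim",
                      optim_convergence = o$convergence)
  }
  vc <- vc_free[c("b", "d", "e"), c("b", "d", "e"), drop = FALSE]
  new_ll_fit(
    family = "LL4",
    coef = c(b = unname(est["b"]), c = c_fixed, d = unname(est["d"]),
             e = unname(est["e"])),
    fixed = "c",
    vcov = vc,
    n_points = length(x),
    converged = converged,
    data = pts[keep, ],
    endpoint = "jc1",
    diagnostics = diag_info
  )
}

# residual variance times the inverse Gauss-Newton curvature, with a
# central-difference Jacobian of the model surface
ll4_gn_vcov <- function(x, y, est, c_fixed) {
  nm <- c("b", "d", "e")
  J <- matrix(NA_real_, length(x), 3)
  h <- pmax(abs(est[nm]), 1e-4) * 1e-5
  for (j in 1:3) {
    up <- est; up[nm[j]] <- up[nm[j]] + h[j]
    dn <- est; dn[nm[j]] <- dn[nm[j]] - h[j]
    J[, j] <- (ll4_unsafe(x, up[["b"]], c_fixed, up[["d"]], up[["e"]]) -
                 ll4_unsafe(x, dn[["b"]], c_fixed, dn[["d"]], dn[["e"]])) /
      (2 * h[j])
  }
  sigma2 <- sum((y - ll4_unsafe(x, est[["b"]], c_fixed, est[["d"]],
                                est[["e"]]))^2) / max(length(x) - 3, 1)
  vc <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e)
    matrix(NA_real_, 3, 3))
  dimnames(vc) <- list(nm, nm)
  vc
}

ec_point <- function(b, e, p) {
  e * (p / (100 - p))^(1 / abs(b))
}

#' Effect concentrations with 95% confidence intervals
#'
#' Uses the relative-effect definition: `EC_p` is the concentration at
#' which the response has moved `p`% of the `d - c` span from the zero-dose
#' asymptote toward the asymptote the curve approaches at high
#' concentration, giving `EC_p = e * (p / (100 - p))^(1 / |b|)` and
#' `EC_50 = e` exactly. The default confidence interval is a delta-method
#' interval on the original concentration scale, which can legitimately
#' produce negative lower bounds for poorly determined fits; a log-scale
#' delta interval and a parametric bootstrap are available.
#'
#' @param fit A converged `ll_fit`.
#' @param p Percent effect level(s) in `(0, 100)`; default `c(10, 50)`.
#' @param ci_method One of `"delta_original"` (default), `"delta_log"`,
#'   `"bootstrap"`.
#' @param level Confidence level, default 0.95.
#' @param n_boot Bootstrap draws when `ci_method = "bootstrap"`.
#' @return Tibble with columns `p`, `value`, `ci_low`, `ci_high`, `method`.
#' @export
ec_x <- function(fit, p = c(10, 50),
                 ci_method = c("delta_original", "delta_log", "bootstrap"),
                 level = 0.95, n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(fit, "ll_fit"))
  if (any(p <= 0 | p >= 100)) {
    abort("Effect level p must lie in (0, 100).", class = "jc1_domain_error")
  }
  b <- fit$coef[["b"]]; e <- fit$coef[["e"]]
  if (b == 0) {
    abort("EC is undefined for zero slope.", class = "jc1_domain_error")
  }
  zq <- qnorm(1 - (1 - level) / 2)
  vc <- fit$vcov[c("b", "e"), c("b", "e")]
  purrr::map_dfr(p, function(pp) {
    rho <- pp / (100 - pp)
    val <- ec_point(b, e, pp)
    # gradient of e * rho^(1/|b|) wrt (b, e)
    g_e <- rho^(1 / abs(b))
    g_b <- -val * log(rho) * sign(b) / b^2
    if (ci_method == "bootstrap") {
      draws <- mvrnorm_draws(n_boot, c(b = b, e = e), vc)
      ecs <- ec_point(draws[, "b"], draws[, "e"], pp)
      ecs <- ecs[is.finite(ecs)]
      qs <- quantile(ecs, c((1 - level) / 2, 1 - (1 - level) / 2),
                     names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    } else {
      g <- c(g_b, g_e)
      v <- drop(t(g) %*% vc %*% g)
      v <- max(v, 0)
      if (ci_method == "delta_original") {
        lo <- val - zq * sqrt(v)
        hi <- val + zq * sqrt(v)
      } else {
        sd_log <- sqrt(v) / val
        lo <- val * exp(-zq * sd_log)
        hi <- val * exp(zq * sd_log)
      }
    }
    tibble(p = pp, value = val, ci_low = lo, ci_high = hi,
           method = ci_method)
  })
}

mvrnorm_draws <- function(n, mu, sigma) {
  # multivariate normal draws via the (regularized) Cholesky factor
  k <- length(mu)
  sigma <- (sigma + t(sigma)) / 2
  ch <- tryCatch(chol(sigma), error = function(e)
    chol(sigma + diag(1e-12 * max(diag(sigma), 1e-300), k)))
  z <- matrix(rnorm(n * k), n, k)
  out <- sweep(z %*% ch, 2, mu, `+`)
  colnames(out) <- names(mu)
  out
}

#' Immobile fraction of an exposure group
#'
#' @param records Tibble with columns `n_exposed` (positive) and
#'   `n_immobile`.
#' @return Numeric vector `n_immobile / n_exposed`.
#' @export
immobile_fraction <- function(records) {
  rec <- as_tibble(records)
  if (any(rec$n_exposed <= 0)) {
    abort("n_exposed must be positive.", class = "jc1_domain_error")
  }
  rec$n_immobile / rec$n_exposed
}
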
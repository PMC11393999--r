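test_that("log-logistic closed forms behave at landmarks", {
  # midpoint at x = e for any slope
  for (b in c(-4, -1, 0.5, 2)) {
    expect_equal(ll2_response(100, b, 100), 0.5)
    expect_equal(ll4_response(100, b, 0.2, 0.9, 100), (0.2 + 0.9) / 2)
  }
  # asymptotes
  expect_equal(ll2_response(1e12, -2, 100), 1, tolerance = 1e-8)
  expect_equal(ll2_response(0, -2, 100), 0)
  expect_equal(ll2_response(0, 2, 100), 1)
  expect_equal(ll4_response(0, 2, 0.2, 1, 100), 1)
  expect_equal(ll4_response(1e12, 2, 0.2, 1, 100), 0.2, tolerance = 1e-6)
  # direct arithmetic oracle
  expect_equal(ll2_response(50, -2, 100), 1 / (1 + exp(-2 * (log(50) - log(100)))))
  # nesting identity on a grid
  xs <- c(0, 10^seq(-2, 4, length.out = 40))
  expect_equal(ll4_response(xs, -3, 0, 1, 42), ll2_response(xs, -3, 42))
  # domain errors
  expect_error(ll2_response(10, -2, -1), class = "jc1_domain_error")
  expect_error(ll4_response(10, 2, 1, 0.5, 100), class = "jc1_domain_error")
})

test_that("LL2 binomial ML recovers exact and simulated truths", {
  x <- cccp_concentrations
  # noise-free limit: curve fractions with huge n recover truth to 4 decimals
  n <- 1e6
  k <- round(n * ll2_response(x, -4, 500))
  f <- fit_ll2(tibble::tibble(concentration = x, n_exposed = n,
                              n_immobile = k))
  expect_true(f$converged)
  expect_equal(f$coef[["b"]], -4, tolerance = 1e-4)
  expect_equal(f$coef[["e"]], 500, tolerance = 1e-4)
  expect_equal(f$coef[["c"]], 0)
  expect_equal(f$coef[["d"]], 1)
  expect_setequal(f$fixed, c("c", "d"))

  # recovery simulation at the design of the study: median within 5% of 500
  set.seed(41)
  est <- replicate(200, {
    kk <- rbinom(length(x), 20, ll2_response(x, -4, 500))
    fit_ll2(tibble::tibble(concentration = x, n_exposed = 20,
                           n_immobile = kk))$coef[["e"]]
  })
  expect_lt(abs(median(est) / 500 - 1), 0.05)

  # degenerate data are rejected
  expect_error(
    fit_ll2(tibble::tibble(concentration = x, n_exposed = 20,
                           n_immobile = 0L)),
    class = "jc1_fit_error")
  expect_error(
    fit_ll2(tibble::tibble(concentration = c(0, 10), n_exposed = 20,
                           n_immobile = c(0L, 10L))),
    class = "jc1_fit_error")
})

test_that("LL2 fit matches a dense grid-search oracle on a 5-point dataset", {
  x <- c(2, 10, 50, 250, 1250)
  set.seed(42)
  k <- rbinom(5, 20, ll2_response(x, -2, 60))
  f <- fit_ll2(tibble::tibble(concentration = x, n_exposed = 20,
                              n_immobile = k))
  g <- oracle_ll2_grid(x, 20, k, e_range = c(2, 1250))
  # same optimum within the grid resolution
  expect_lt(abs(f$coef[["e"]] / g$e - 1), 0.05)
  expect_lt(abs(f$coef[["b"]] / g$b - 1), 0.12)
  expect_lte(jc1screen:::ll2_nll(c(f$coef[["b"]], log(f$coef[["e"]])),
                                 x, rep(20, 5), k),
             g$nll + 1e-6)
})

test_that("constrained LL4 least squares recovers exact and simulated truths", {
  x <- dnp_concentrations
  y <- ll4_response(x, 2, 0.2, 1, 7.5)
  pts <- tibble::tibble(concentration = rep(x, 3), response = rep(y, 3))
  f <- fit_ll4(pts, c_fixed = 0.2)
  expect_true(f$converged)
  expect_equal(f$coef[["b"]], 2, tolerance = 1e-4)
  expect_equal(f$coef[["d"]], 1, tolerance = 1e-4)
  expect_equal(f$coef[["e"]], 7.5, tolerance = 1e-4)
  expect_equal(f$fixed, "c")

  # recovery simulation: 3 replicates x 8 concentrations, noise sd 0.05
  set.seed(43)
  est <- replicate(200, {
    yy <- rep(ll4_response(x, 2, 0.2, 1, 7.5), 3) + rnorm(24, 0, 0.05)
    fit_ll4(tibble::tibble(concentration = rep(x, 3), response = yy),
            0.2)$coef[["e"]]
  })
  expect_lt(abs(median(est) / 7.5 - 1), 0.1)

  expect_error(fit_ll4(pts, c_fixed = 2), class = "jc1_fit_error")
  expect_error(fit_ll4(pts[pts$concentration < 2, ], 0.2),
               class = "jc1_fit_error")
})

test_that("LL4 fit matches a dense grid-search oracle", {
  x <- c(1, 5, 25, 125, 625)
  set.seed(44)
  y <- ll4_response(x, 1.5, 0.2, 1, 30) + rnorm(5, 0, 0.03)
  f <- fit_ll4(tibble::tibble(concentration = x, response = y), 0.2)
  g <- oracle_ll4_grid(x, y, 0.2, e_range = c(1, 625))
  expect_lt(abs(f$coef[["e"]] / g$e - 1), 0.05)
  expect_lte(f$diagnostics$rss, g$rss + 1e-9)
})

test_that("ECx follows the relative definition and self-consistency", {
  # EC50 equals the inflection exactly
  x <- dnp_concentrations
  y <- ll4_response(x, 2, 0.2, 1, 7.5)
  f <- fit_ll4(tibble::tibble(concentration = rep(x, 2),
                              response = rep(y, 2)), 0.2)
  ec <- ec_x(f, c(10, 50))
  expect_equal(ec$value[ec$p == 50], f$coef[["e"]])

  # closed form vs numeric root-solve of the response equation
  b <- f$coef[["b"]]; cc <- f$coef[["c"]]; d <- f$coef[["d"]]
  e <- f$coef[["e"]]
  for (p in c(10, 25, 50, 80)) {
    target <- d - (d - cc) * p / 100  # p% of the span toward the floor
    root <- uniroot(function(z) ll4_response(z, b, cc, d, e) - target,
                    c(1e-6, 1e6), tol = 1e-12)$root
    expect_equal(ec_x(f, p)$value, root, tolerance = 1e-6)
  }

  # b = 1, e = 100, p = 10 gives 100 * (10/90)
  f2 <- f; f2$coef[["b"]] <- 1; f2$coef[["e"]] <- 100
  expect_equal(ec_x(f2, 10)$value, 100 * (10 / 90), tolerance = 1e-9)

  # ECp is monotone in p
  ecs <- ec_x(f, c(5, 10, 25, 50, 75, 90))$value
  expect_true(all(diff(ecs) > 0))

  expect_error(ec_x(f, 0), class = "jc1_domain_error")
  f0 <- f; f0$coef[["b"]] <- 0
  expect_error(ec_x(f0, 50), class = "jc1_domain_error")
})

test_that("delta-method CIs agree with a parametric bootstrap", {
  x <- dnp_concentrations
  set.seed(45)
  y <- rep(ll4_response(x, 2, 0.2, 1, 7.5), 3) + rnorm(24, 0, 0.05)
  f <- fit_ll4(tibble::tibble(concentration = rep(x, 3), response = y), 0.2)
  delta <- ec_x(f, 50, ci_method = "delta_original")
  set.seed(46)
  boot <- ec_x(f, 50, ci_method = "bootstrap", n_boot = 2000)
  # overlapping intervals with midpoints within 15%
  expect_lt(max(delta$ci_low, boot$ci_low), min(delta$ci_high, boot$ci_high))
  mid_d <- (delta$ci_low + delta$ci_high) / 2
  mid_b <- (boot$ci_low + boot$ci_high) / 2
  expect_lt(abs(mid_d - mid_b) / mid_d, 0.15)
})

test_that("fitted curves are monotone in concentration", {
  x <- cccp_concentrations
  set.seed(47)
  k <- rbinom(7, 20, ll2_response(x, -4, 300))
  f2 <- fit_ll2(tibble::tibble(concentration = x, n_exposed = 20,
                               n_immobile = k))
  xs <- 10^seq(-1, 4, length.out = 100)
  resp <- ll2_response(xs, f2$coef[["b"]], f2$coef[["e"]])
  expect_true(all(diff(resp) >= 0))

  y <- rep(ll4_response(x, 2, 0.2, 1, 100), 3) + rnorm(21, 0, 0.03)
  f4 <- fit_ll4(tibble::tibble(concentration = rep(x, 3), response = y), 0.2)
  resp4 <- ll4_response(xs, f4$coef[["b"]], f4$coef[["c"]], f4$coef[["d"]],
                        f4$coef[["e"]])
  expect_true(all(diff(resp4) <= 0))
})

test_that("tidy and glance summarise fits in broom style", {
  x <- dnp_concentrations
  y <- rep(ll4_response(x, 2, 0.2, 1, 7.5), 2)
  f <- fit_ll4(tibble::tibble(concentration = rep(x, 2), response = y), 0.2)
  td <- tidy(f)
  expect_equal(td$term, c("b", "c", "d", "e"))
  expect_true(td$fixed[td$term == "c"])
  expect_true(is.na(td$std.error[td$term == "c"]))
  gl <- glance(f)
  expect_equal(gl$family, "LL4")
  expect_true(gl$converged)
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})
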
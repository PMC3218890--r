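test_that("perfect and null fits behave exactly", {
  g <- genotype_matrix(cbind(v1 = c(0, 1, 2, 1, 0, 2),
                             v2 = c(2, 0, 1, 1, 2, 0)))
  y <- stats::setNames(as.numeric(g$dosages[, "v1"]), sample_ids(g))
  fit <- fit_ols(y, g, "v1")
  expect_equal(fit$r2, 1)
  expect_equal(fit$adj_r2, 1)
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-12)

  # response orthogonal to the predictor by construction
  x <- c(0, 1, 2, 1, 0, 2)
  y0 <- stats::setNames(residuals(lm(rnorm(6) ~ x)), sample_ids(g))
  fit0 <- fit_ols(y0, g, "v1")
  expect_equal(unname(fit0$coefficients["v1"]), 0, tolerance = 1e-12)
  expect_equal(unname(fit0$p["v1"]), 1, tolerance = 1e-10)
})

test_that("a 6-point fit matches hand normal equations to 1e-10", {
  d <- cbind(v1 = c(0, 1, 2, 0, 1, 2), v2 = c(1, 1, 0, 2, 0, 2))
  g <- genotype_matrix(d)
  y <- stats::setNames(c(0.3, 1.1, 2.2, -0.4, 0.9, 2.5), sample_ids(g))
  fit <- fit_ols(y, g, c("v1", "v2"))
  o <- ne_oracle(y, d)
  expect_equal(unname(fit$coefficients), unname(o$coef),
               tolerance = 1e-10)
  expect_equal(fit$rss, o$rss, tolerance = 1e-10)
  expect_equal(fit$adj_r2, o$adj_r2, tolerance = 1e-10)
})

test_that("fit matches the normal-equation oracle on random instances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(15:50, 1)
    p <- sample(1:5, 1)
    g <- rand_genotypes(n, p)
    ok <- apply(g$dosages, 2, var) > 0
    g <- g[, ok]
    if (ncol(g$dosages) == 0) next
    y <- stats::setNames(rnorm(n) + g$dosages %*% rnorm(ncol(g$dosages)),
                         sample_ids(g))
    fit <- fit_ols(y, g, variant_ids(g))
    o <- ne_oracle(y, g$dosages)
    expect_equal(unname(fit$coefficients), unname(o$coef),
                 tolerance = 1e-8)
    expect_equal(fit$rss, o$rss, tolerance = 1e-8)
    expect_equal(fit$adj_r2, o$adj_r2, tolerance = 1e-8)
    # residual orthogonality and likelihood identity
    expect_lt(max(abs(crossprod(cbind(1, g$dosages), fit$residuals))),
              1e-8)
    expect_equal(fit$loglik,
                 -n / 2 * (log(2 * pi) + log(fit$rss / n) + 1))
    if (fit$r2 < 1) expect_lt(fit$adj_r2, fit$r2)
  }
})

test_that("degenerate designs are rejected with names", {
  g <- genotype_matrix(cbind(v1 = c(0, 1, 2, 1, 0),
                             v2 = c(0, 1, 2, 1, 0)))
  y <- stats::setNames(rnorm(5), sample_ids(g))
  expect_error(fit_ols(y, g, c("v1", "v2")), "v2")
  g3 <- genotype_matrix(cbind(v1 = c(0, 2)))
  expect_error(fit_ols(stats::setNames(rnorm(2), sample_ids(g3)), g3, "v1"),
               "too few samples")
})

test_that("verdict stars follow the published thresholds exactly", {
  expect_identical(stars(c(0.2, 0.05, 0.049, 0.01, 0.004, 0.001, 5e-4,
                           1e-4, 5e-5, 0)),
                   c("n.s.", "n.s.", "*", "*", "**", "**", "***", "***",
                     "****", "****"))
  expect_error(stars(1.2), "outside")
  expect_error(stars(-0.1), "outside")
})

test_that("LRT identities: self-comparison, t-squared link, F agreement", {
  set.seed(32)
  n <- 300
  g <- rand_genotypes(n, 2)
  y <- stats::setNames(0.3 * g$dosages[, 1] + rnorm(n), sample_ids(g))
  f1 <- fit_ols(y, g, "v01")
  f12 <- fit_ols(y, g, c("v01", "v02"))

  self <- lrt_nested(f1, f1)
  expect_equal(self$statistic, 0)
  expect_equal(self$p, 1)
  expect_identical(self$stars, "n.s.")

  # one added column: LRT statistic approximates the squared t statistic
  cmp <- lrt_nested(f1, f12)
  expect_equal(cmp$statistic, unname(f12$t["v02"])^2, tolerance = 0.05)
  # chi-square and F calibrations agree at this n
  cmpF <- lrt_nested(f1, f12, calibration = "F")
  expect_equal(cmp$p, cmpF$p, tolerance = 0.02)

  expect_error(lrt_nested(f12, f1), "not nested")
})

test_that("LRT statistic grows as true signal is added", {
  set.seed(33)
  n <- 400
  g <- rand_genotypes(n, 3)
  y <- stats::setNames(
    g$dosages %*% c(0.8, 0.5, 0.3) + rnorm(n), sample_ids(g))
  f0 <- fit_ols(y, g, character(0))
  f1 <- fit_ols(y, g, "v01")
  f2 <- fit_ols(y, g, c("v01", "v02"))
  f3 <- fit_ols(y, g, c("v01", "v02", "v03"))
  s <- c(lrt_nested(f0, f1)$statistic, lrt_nested(f0, f2)$statistic,
         lrt_nested(f0, f3)$statistic)
  expect_true(all(diff(s) > 0))
})

test_that("J-test enforces non-nesting and flags degenerate proxies", {
  set.seed(34)
  n <- 100
  g <- rand_genotypes(n, 3)
  y <- stats::setNames(rnorm(n), sample_ids(g))
  expect_error(jtest(y, g, "v01", c("v01", "v02")), "lrt_nested")

  # rival model spanning the base design: proxy is collinear
  d <- g$dosages
  gd <- genotype_matrix(cbind(d[, 1:2], v_dup = d[, 1]))
  expect_error(jtest(stats::setNames(y, rownames(d)), gd,
                     c("v01", "v02"), c("v_dup", "v02")),
               "degenerate")
})

test_that("J-test directions are asymmetric and detect the true model", {
  set.seed(35)
  n <- 500
  g <- rand_genotypes(n, 2, maf = c(0.3, 0.4))
  beta <- effect_for_h2(var(g$dosages[, 1]), 0.3)
  y <- stats::setNames(beta * g$dosages[, 1] + rnorm(n), sample_ids(g))
  jt <- jtest(y, g, "v01", "v02")
  # model B (wrong) is rejected decisively; model A (true) is not
  expect_lt(jt$b$p, 0.001)
  expect_gt(jt$a$p, 0.001)
  expect_identical(jt$a$direction, "a_with_b_proxy")
  expect_identical(jt$b$direction, "b_with_a_proxy")
})
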
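test_that("noise-free single cause is found regardless of panel order", {
  set.seed(41)
  g <- rand_genotypes(80, 6)
  y <- stats::setNames(as.numeric(g$dosages[, "v03"]), sample_ids(g))
  for (perm in 1:3) {
    ord <- sample(variant_ids(g))
    gp <- g[, ord]
    tr <- forward_select(y, gp)
    expect_identical(tr$steps$variant_id, "v03")
    expect_identical(tr$stop_reason, "no_significant_improvement")
  }
})

test_that("a response orthogonal to every dosage selects nothing", {
  set.seed(42)
  g <- rand_genotypes(50, 4)
  raw <- rnorm(50)
  y0 <- stats::setNames(residuals(lm(raw ~ g$dosages)), sample_ids(g))
  tr <- forward_select(y0, g)
  expect_equal(nrow(tr$steps), 0)
  expect_equal(tr$fit$r2, 0, tolerance = 1e-12)
})

test_that("selection trace is internally consistent with its alpha rules", {
  set.seed(43)
  n <- 200
  g <- rand_genotypes(n, 10)
  y <- stats::setNames(
    g$dosages[, 1:3] %*% c(1, 0.7, 0.4) + rnorm(n), sample_ids(g))
  tr <- forward_select(y, g)
  expect_true(all(tr$steps$entry_p < tr$alpha_entry))
  expect_true(all(tr$fit$p[-1] < tr$alpha_stay))
  expect_identical(tr$steps$variant_id, tr$fit$variant_ids)
})

test_that("forward entry agrees with the exhaustive best-subset oracle", {
  set.seed(44)
  agree <- logical(10)
  for (r in seq_along(agree)) {
    n <- 200
    g <- rand_genotypes(n, 15)
    k <- sample(1:3, 1)
    beta <- c(1, 0.7, 0.4)[seq_len(k)]
    y <- stats::setNames(
      g$dosages[, seq_len(k), drop = FALSE] %*% beta + rnorm(n),
      sample_ids(g))
    fwd <- forward_select(y, g)$steps$variant_id
    orc <- best_subset_oracle(y, g$dosages)
    agree[r] <- setequal(fwd, orc)
  }
  expect_gte(mean(agree), 0.8)
})

test_that("evaluate_composition refits exactly and respects monotonicity", {
  set.seed(45)
  n <- 120
  g <- rand_genotypes(n, 5)
  y <- stats::setNames(g$dosages[, 1] + rnorm(n), sample_ids(g))
  tr <- forward_select(y, g)
  refit <- evaluate_composition(tr$steps$variant_id, y, g)
  expect_equal(refit$coefficients, tr$fit$coefficients)
  expect_equal(refit$rss, tr$fit$rss)

  empty <- evaluate_composition(character(0), y, g)
  expect_equal(empty$r2, 0, tolerance = 1e-12)

  sub <- evaluate_composition("v01", y, g)
  sup <- evaluate_composition(c("v01", "v02"), y, g)
  expect_lte(sup$rss, sub$rss)
})

test_that("cross-check grid has an n.s. diagonal and correct nesting logic", {
  set.seed(46)
  n <- 150
  g <- rand_genotypes(n, 6)
  mk <- function(b) stats::setNames(
    g$dosages[, names(b), drop = FALSE] %*% b + rnorm(n), sample_ids(g))
  responses <- list(d1 = mk(c(v01 = 1)), d2 = mk(c(v02 = 1)))
  best <- lapply(responses, function(y) forward_select(y, g)$steps$variant_id)
  grid <- cross_check(best, responses, g)
  diagonal <- grid$table[grid$table$model == grid$table$dataset, ]
  expect_true(all(diagonal$verdict == "n.s."))

  # a superset of the proper best is never significantly inferior
  sup <- unique(c(best$d1, best$d2, "v03"))
  grid2 <- cross_check(list(d1 = best$d1, d2 = sup),
                       list(d1 = responses$d1, d2 = responses$d2), g)
  cell <- grid2$table[grid2$table$model == "d2" &
                      grid2$table$dataset == "d2", ]
  expect_identical(cell$verdict, "n.s.")
  cmp <- grid2$comparisons$d2$d1
  if (all(best$d1 %in% sup))
    expect_identical(cmp$direction, "contains_best")
})

test_that("a composition missing the strong variant is decisively inferior", {
  set.seed(47)
  n <- 500
  g <- rand_genotypes(n, 4, maf = rep(0.3, 4))
  beta <- effect_for_h2(var(g$dosages[, 1]), 0.5)
  y <- stats::setNames(beta * g$dosages[, 1] + rnorm(n), sample_ids(g))
  responses <- list(dA = y, dB = y)
  best <- list(dA = c("v01"), dB = c("v02", "v03"))
  grid <- cross_check(best, responses, g)
  cell <- grid$table[grid$table$model == "dB" &
                     grid$table$dataset == "dA", ]
  expect_lt(cell$comparison_p, 0.001)
  expect_true(cell$verdict %in% c("***", "****"))
})

test_that("functional-panel models rank and compare sensibly", {
  set.seed(48)
  n <- 400
  g <- rand_genotypes(n, 6, maf = rep(0.3, 6))
  y <- stats::setNames(
    g$dosages[, c("v01", "v02")] %*% c(0.8, 0.5) + rnorm(n),
    sample_ids(g))
  best <- c("v01", "v02")                    # the proper best composition

  # panel equal to the causal set: its pair model is not inferior
  fp <- functional_panel_models(y, g, c("v01", "v02"), best)
  top <- fp[fp$model == "v01+v02", ]
  expect_true(is.na(top$comparison_p) || top$comparison_p >= 0.05)
  expect_identical(top$kind, "self")
  expect_identical(fp$model[1], "v01+v02")   # ranked by model P

  # irrelevant panel: every model significantly inferior
  fp2 <- functional_panel_models(y, g, c("v05", "v06"), best)
  expect_true(all(fp2$comparison_p < 0.05))

  # max_size = 1 with one member: a single row
  fp3 <- functional_panel_models(y, g, "v01", best, max_size = 1L)
  expect_equal(nrow(fp3), 1)
})
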
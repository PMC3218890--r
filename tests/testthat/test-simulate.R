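test_that("pool validation enforces its invariants", {
  expect_error(haplotype_pool(c("a", "b"),
                              rbind(h1 = c(0, 0), h2 = c(1, 1)),
                              c(0.6, 0.5)), "sum to 1")
  expect_error(haplotype_pool(c("a", "b"),
                              rbind(h1 = c(0, 2), h2 = c(1, 1)),
                              c(0.5, 0.5)), "0/1")
  expect_error(haplotype_pool("a", rbind(h1 = c(0, 1), h2 = c(1, 0)),
                              c(0.5, 0.5)), "one entry per variant")
})

test_that("a degenerate single-haplotype pool yields constant homozygotes", {
  pool <- haplotype_pool(c("a", "b"), rbind(h1 = c(1, 0)), 1)
  sim <- simulate_genotypes(pool, 5, seed = 1)
  expect_true(all(sim$genotypes$dosages[, "a"] == 2))
  expect_true(all(sim$genotypes$dosages[, "b"] == 0))
  expect_true(all(sim$diplotypes$hap1 == "h1" & sim$diplotypes$hap2 == "h1"))
})

test_that("dosage means and haplotype frequencies converge to expectation", {
  pool <- haplotype_pool("a", rbind(A = 0, B = 1), c(0.5, 0.5))
  sim <- simulate_genotypes(pool, 10000, seed = 2)
  se <- sqrt(2 * 0.25 / 10000)
  expect_lt(abs(mean(sim$genotypes$dosages[, "a"]) - 1), 3 * se)

  pool6 <- fixture_pool_for_tests()
  sim6 <- simulate_genotypes(pool6, 10000, seed = 3)
  emp <- colSums(sim6$hap_dosage) / (2 * 10000)
  for (h in names(pool6$frequencies)) {
    f <- pool6$frequencies[h]
    expect_lt(abs(emp[h] - f), 3 * sqrt(f * (1 - f) / (2 * 10000)))
  }
})

test_that("expression simulation realizes the requested heritability", {
  pool <- haplotype_pool("a", rbind(A = 0, B = 1), c(0.6, 0.4))
  sim <- simulate_genotypes(pool, 10000, seed = 4)
  dvar <- 2 * 0.4 * 0.6
  beta <- effect_for_h2(dvar, 0.8)
  ex <- simulate_expression(sim$genotypes, c(a = beta), noise_sd = 1,
                            seed = 5)
  r2 <- summary(lm(ex$latent ~ sim$genotypes$dosages[, "a"]))$r.squared
  expect_equal(r2, 0.8, tolerance = 0.02)

  expect_error(simulate_expression(sim$genotypes, c(nope = 1), 1),
               "nope")
})

test_that("zero effects with tiny probe noise duplicate the latent signal", {
  pool <- haplotype_pool("a", rbind(A = 0, B = 1), c(0.5, 0.5))
  sim <- simulate_genotypes(pool, 500, seed = 6)
  ex <- simulate_expression(sim$genotypes, numeric(0), noise_sd = 1,
                            n_probes = 2, probe_noise_sd = 1e-8, seed = 7)
  v <- ex$dataset$values
  expect_equal(cor(v[, 1], v[, 2])^2, 1, tolerance = 1e-10)
  expect_equal(unname(v[, 1]), unname(ex$latent), tolerance = 1e-6)
})

test_that("probe-pair attenuation hits its target r2", {
  pool <- haplotype_pool("a", rbind(A = 0, B = 1), c(0.5, 0.5))
  sim <- simulate_genotypes(pool, 10000, seed = 8)
  ex <- simulate_expression(sim$genotypes, c(a = 0.5), noise_sd = 1,
                            n_probes = 2,
                            probe_noise_sd = probe_sd_for_pair_r2(
                              0.5^2 * var(sim$genotypes$dosages[, "a"]) + 1,
                              0.79),
                            seed = 9)
  v <- ex$dataset$values
  expect_equal(cor(v[, 1], v[, 2])^2, 0.79, tolerance = 0.02)
})

test_that("the four-study fixture is deterministic with the published shapes", {
  f1 <- make_four_study_fixture(seed = 123)
  f2 <- make_four_study_fixture(seed = 123)
  expect_identical(f1, f2)
  f3 <- make_four_study_fixture(seed = 124)
  expect_false(identical(f1$expression$K$values, f3$expression$K$values))

  fix <- get_fixture(1)
  expect_equal(vapply(fix$expression, function(e) nrow(e$values),
                      integer(1)),
               c(K = 57L, S = 60L, C = 58L, D = 181L))
  expect_equal(vapply(fix$expression, function(e) ncol(e$values),
                      integer(1)),
               c(K = 17L, S = 2L, C = 1L, D = 3L))
  expect_equal(sum(fix$expression$K$probe_meta$targets_intron), 4)
})

test_that("forward selection on the low-noise study recovers the causal set", {
  fix <- get_fixture(1)
  pr <- prune_by_ld(fix$genotypes$CEU, keep_ids = fix$truth$functional_ids)
  e <- standardize(fix$expression$S)
  y <- e$values[, fix$truth$signal_probes$S]
  tr <- forward_select(stats::setNames(y, rownames(e$values)), pr$g)
  expect_setequal(tr$steps$variant_id, names(fix$truth$effects))
  # effect signs are recovered too
  expect_equal(sign(tr$fit$coefficients[names(fix$truth$effects)]),
               sign(fix$truth$effects), ignore_attr = TRUE)
})

test_that("fixture serialization round-trips through plain text", {
  fix <- get_fixture(1)
  dir <- withr::local_tempdir()
  write_fixture(fix, dir)
  ek <- read_expression(file.path(dir, "expression_K.tsv"),
                        file.path(dir, "probes_K.tsv"))
  expect_equal(ek$values, fix$expression$K$values, tolerance = 1e-12)
  expect_equal(ek$probe_meta$targets_intron,
               fix$expression$K$probe_meta$targets_intron)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$effects$v04, unname(fix$truth$effects["v04"]))
  expect_identical(truth$risk_haplotype, "H6")
})
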
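test_that("standardization produces exact z-scores and is idempotent", {
  e <- expression_dataset(cbind(p1 = c(1, 2, 3), p2 = c(10, 30, 20)))
  z <- standardize(e)
  expect_equal(unname(z$values[, "p1"]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-9))
  z2 <- standardize(z)
  expect_equal(z2$values, z$values)
  expect_equal(z2$raw, e$values)                  # provenance retained

  e0 <- expression_dataset(cbind(flat = rep(5, 4), ok = 1:4))
  expect_error(standardize(e0), "flat")
})

test_that("intron probes are filtered by annotation with counts reported", {
  pm <- data.frame(probe_id = paste0("p", 1:5),
                   target = c("exon1", "intron1", "exon2", "intron2",
                              "utr3"),
                   targets_intron = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  e <- expression_dataset(matrix(rnorm(20), 4, 5,
                                 dimnames = list(NULL, pm$probe_id)), pm)
  expect_message(ef <- filter_intron_probes(e), "2 intron.*3 retained")
  expect_identical(colnames(ef$values), c("p1", "p3", "p5"))

  # no intron probes: identity
  pm2 <- pm; pm2$targets_intron <- FALSE
  e2 <- expression_dataset(e$values, pm2)
  expect_message(ef2 <- filter_intron_probes(e2))
  expect_equal(ef2$values, e2$values)

  # all intronic: empty with a warning
  pm3 <- pm; pm3$targets_intron <- TRUE
  e3 <- expression_dataset(e$values, pm3)
  suppressMessages(expect_warning(ef3 <- filter_intron_probes(e3),
                                  "all probes"))
  expect_equal(ncol(ef3$values), 0)
})

test_that("probe r2 matrix is sign-blind with unit diagonal", {
  set.seed(21)
  x <- rnorm(40)
  e <- standardize(expression_dataset(cbind(a = x, b = x, c = -x,
                                            d = rnorm(40))))
  r2 <- probe_r2_matrix(e)
  expect_equal(unname(diag(r2)), rep(1, 4))
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], 1)                   # negation
  expect_true(isSymmetric(r2))
})

test_that("probe r2 matches the attenuation identity for noisy copies", {
  set.seed(22)
  n <- 10000
  latent <- rnorm(n)
  sd_p <- probe_sd_for_pair_r2(1, 0.79)
  e <- standardize(expression_dataset(
    cbind(p1 = latent + rnorm(n, 0, sd_p),
          p2 = latent + rnorm(n, 0, sd_p))))
  r2 <- probe_r2_matrix(e)["p1", "p2"]
  expect_equal(r2, 0.79, tolerance = 0.02)
})

test_that("r2 matrix is invariant to affine transforms of raw probes", {
  set.seed(23)
  raw <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("p", 1:3)))
  e1 <- standardize(expression_dataset(raw))
  e2 <- standardize(expression_dataset(sweep(raw * 3.7, 2, c(1, -5, 100),
                                             "+")))
  expect_equal(probe_r2_matrix(e1), probe_r2_matrix(e2))
})

test_that("representative group recovers the coherent block", {
  set.seed(24)
  n <- 200
  sig1 <- rnorm(n); sig2 <- rnorm(n)
  mk <- function(s, k, noise) vapply(1:k, function(i)
    s + rnorm(n, 0, noise), numeric(n))
  # two orthogonal blocks: the larger wins
  v <- cbind(mk(sig1, 4, 0.3), mk(sig2, 2, 0.3))
  colnames(v) <- paste0("p", 1:6)
  e <- standardize(expression_dataset(v))
  grp <- select_representative_group(probe_r2_matrix(e))
  expect_setequal(grp$members, paste0("p", 1:4))
  expect_setequal(grp$excluded, paste0("p", 5:6))

  # all probes identical: everything, mean r2 = 1
  ei <- standardize(expression_dataset(
    matrix(rep(sig1, 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))))
  gi <- select_representative_group(probe_r2_matrix(ei))
  expect_setequal(gi$members, c("a", "b", "c"))
  expect_equal(gi$mean_r2, 1)

  # nothing correlated: empty result with diagnostic
  en <- standardize(expression_dataset(
    matrix(rnorm(4 * n), ncol = 4, dimnames = list(NULL, paste0("q", 1:4)))))
  gn <- select_representative_group(probe_r2_matrix(en), 0.5)
  expect_length(gn$members, 0)
})

test_that("the 8 coherent probes of the fixture's 13 are recovered, in any order", {
  fix <- get_fixture(1)
  e <- suppressMessages(filter_intron_probes(standardize(fix$expression$K)))
  expect_equal(ncol(e$values), 13)
  r2 <- probe_r2_matrix(e)
  grp <- select_representative_group(r2)
  expect_setequal(grp$members, fix$truth$signal_probes$K)
  expect_gt(grp$mean_r2, 0.7)

  # permutation invariance of the selection
  perm <- sample(colnames(r2))
  grp2 <- select_representative_group(r2[perm, perm])
  expect_setequal(grp2$members, grp$members)
})

test_that("composites are exact means with sample alignment rules", {
  x <- stats::setNames(c(1, -1, 0.5), paste0("s", 1:3))
  expect_equal(composite_signal(list(a = x), "one")$value, x)
  expect_equal(unname(composite_signal(list(a = x, b = -x), "zero")$value),
               rep(0, 3))

  y <- stats::setNames(c(2, 0, 1), paste0("s", 2:4))   # mismatched ids
  expect_error(composite_signal(list(a = x, b = y), "bad"),
               "allow_partial")
  cs <- composite_signal(list(a = x, b = y), "ok", allow_partial = TRUE)
  expect_setequal(names(cs$value), c("s2", "s3"))
  expect_setequal(cs$dropped_samples, c("s1", "s4"))

  # K8-style composite equals the row-mean oracle
  fix <- get_fixture(1)
  e <- standardize(fix$expression$K)
  comp <- make_composite(e, fix$truth$signal_probes$K, "K8")
  oracle <- rowMeans(e$values[, fix$truth$signal_probes$K])
  expect_equal(comp$value, oracle)
  # composite of z-scores: mean 0, sd at most 1
  expect_lt(abs(mean(comp$value)), 1e-9)
  expect_lte(sd(comp$value), 1)
})

test_that("classical MDS reproduces simple geometries", {
  # three equidistant probes form an equilateral triangle
  r2 <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(r2) <- 1
  xy <- mds_coordinates(r2)
  dd <- as.matrix(dist(xy))
  expect_equal(dd[upper.tri(dd)], rep(sqrt(0.5), 3), tolerance = 1e-8)

  # Euclidean-realizable distances are reproduced exactly
  set.seed(25)
  pts <- cbind(rnorm(5), rnorm(5))
  d0 <- as.matrix(dist(pts))
  d0 <- d0 / (max(d0) * 1.01)
  r2e <- 1 - d0^2
  dimnames(r2e) <- list(paste0("p", 1:5), paste0("p", 1:5))
  xy2 <- mds_coordinates(r2e)
  expect_equal(as.matrix(dist(xy2)), d0, tolerance = 1e-8,
               ignore_attr = TRUE)

  # collinear configuration: second coordinate vanishes
  pts1 <- cbind(seq(0, 0.8, length.out = 4), 0)
  d1 <- as.matrix(dist(pts1))
  r21 <- 1 - d1^2
  dimnames(r21) <- list(paste0("q", 1:4), paste0("q", 1:4))
  xy3 <- mds_coordinates(r21)
  expect_lt(max(abs(xy3[, 2])), 1e-8)

  expect_error(mds_coordinates(matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               "symmetric")
})
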
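test_that("Pearson ratio reproduces closed-form cases and the Poisson GLM", {
  cond <- c("A", "A", "B", "B")
  expect_equal(pearson_ratio(c(5, 5, 5, 5), cond), 0)
  # group means 5, chi2 = 4 * 25 / 5 = 20, df = 2
  expect_equal(pearson_ratio(c(0, 10, 0, 10), cond), 10)
  # exactly at the threshold: (1,3) in each group -> chi2 2, df 2, ratio 1
  cd <- classify_dispersion(
    count_matrix(matrix(c(1, 3, 1, 3), 1, 4,
                        dimnames = list("g", paste0("s", 1:4)))),
    tiny_design())
  expect_identical(cd$table$label, "equidispersed")
  expect_equal(cd$table$pearson_ratio, 1)
  expect_error(pearson_ratio(c(1, 2), c("A", "B")), "insufficient replicates")

  # oracle: Pearson chi2 / df from a fitted Poisson GLM
  set.seed(11)
  cond6 <- rep(c("A", "B"), each = 3)
  for (i in 1:10) {
    y <- rnbinom(6, mu = 30, size = 2)
    if (any(tapply(y, cond6, mean) == 0)) next
    fit <- stats::glm(y ~ factor(cond6), family = stats::poisson())
    ref <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
    expect_equal(pearson_ratio(y, cond6), ref, tolerance = 1e-10)
  }
})

test_that("dispersion classification labels every gene by the <= 1 rule", {
  m <- matrix(7, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  cd <- classify_dispersion(count_matrix(m), tiny_design())
  expect_equal(cd$n_equidispersed, 5)
  expect_equal(cd$n_overdispersed, 0)
  sim <- simulate_fixed(sim_config(n_genes = 200, replicates = 5, phi = 1,
                                   deg_proportion = 0, f_all_zero = 0,
                                   f_partial = 0, f_constant = 0, f_low = 0,
                                   seed = 4))
  cd2 <- classify_dispersion(sim$matrix, sim$design)
  expect_equal(cd2$n_equidispersed + cd2$n_overdispersed, 200)
  expect_gt(cd2$n_overdispersed, 100)  # phi = 1 data is mostly overdispersed
})

test_that("common-dispersion BCV recovers simulated dispersion", {
  des <- two_group_design(6)
  set.seed(21)
  mu <- rlnorm(2000, 5, 1.5)
  pois <- matrix(rpois(2000 * 12, rep(mu, 12)), 2000, 12,
                 dimnames = list(sprintf("g%04d", 1:2000), des$sample_id))
  expect_lt(estimate_bcv(count_matrix(pois), des)$bcv, 0.05)

  nb <- matrix(rnbinom(2000 * 12, mu = rep(mu, 12), size = 1 / 0.09), 2000, 12,
               dimnames = dimnames(pois))
  b <- estimate_bcv(count_matrix(nb), des)
  expect_gt(b$bcv, 0.27)
  expect_lt(b$bcv, 0.33)
  expect_equal(b$bcv, sqrt(b$common_dispersion))

  # duplicating every gene row leaves the estimate unchanged
  dup <- rbind(nb, nb)
  rownames(dup) <- sprintf("g%04d", 1:4000)  # fresh unique ids
  expect_equal(estimate_bcv(count_matrix(dup), des)$common_dispersion,
               b$common_dispersion, tolerance = 1e-6)

  expect_error(
    estimate_bcv(matrix(0, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4))),
                 tiny_design()),
    "all-zero")
})

test_that("BCV estimate agrees with edgeR's common dispersion to the first decimal", {
  des <- two_group_design(6)
  set.seed(33)
  mu <- rlnorm(1500, 5, 1.5)
  nb <- matrix(rnbinom(1500 * 12, mu = rep(mu, 12), size = 1 / 0.16), 1500, 12,
               dimnames = list(sprintf("g%04d", 1:1500), des$sample_id))
  ours <- estimate_bcv(count_matrix(nb), des)$bcv
  ref <- sqrt(edgeR::estimateCommonDisp(
    edgeR::DGEList(counts = nb, group = des$condition))$common.dispersion)
  expect_lt(abs(ours - ref), 0.05)
})

test_that("adding Poisson genes does not inflate the common dispersion", {
  des <- two_group_design(3)
  worse <- 0
  for (seed in 1:3) {
    set.seed(seed)
    mu <- rlnorm(800, 5, 1)
    nb <- matrix(rnbinom(800 * 6, mu = rep(mu, 6), size = 1 / 0.2), 800, 6,
                 dimnames = list(sprintf("n%03d", 1:800), des$sample_id))
    pois <- matrix(rpois(800 * 6, rep(mu, 6)), 800, 6,
                   dimnames = list(sprintf("p%03d", 1:800), des$sample_id))
    d1 <- estimate_bcv(count_matrix(nb), des)$common_dispersion
    d2 <- estimate_bcv(count_matrix(rbind(nb, pois)), des)$common_dispersion
    if (d2 > d1) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
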
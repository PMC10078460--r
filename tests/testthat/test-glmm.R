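test_that("NB GLM matches glm.nb on random fixtures", {
  set.seed(5)
  cond <- rep(c("A", "B"), each = 10)
  for (i in 1:8) {
    y <- rnbinom(20, mu = rep(exp(runif(2, 2, 6)), each = 10),
                 size = exp(runif(1, 0, 3)))
    if (any(tapply(y, cond, sum) == 0)) next
    f <- fit_nb_glm(y, cond, dispersion = "ml")
    ref <- suppressWarnings(MASS::glm.nb(y ~ factor(cond)))
    expect_equal(unname(f$beta), unname(stats::coef(ref)), tolerance = 1e-5)
    expect_equal(f$theta, ref$theta, tolerance = 1e-3)
    expect_equal(unname(f$se), unname(sqrt(diag(stats::vcov(ref)))),
                 tolerance = 1e-4)
  }
})

test_that("GLMM with zero random-effect variance reduces to the NB GLM", {
  set.seed(6)
  cond <- rep(c("A", "B"), each = 6)
  for (i in 1:10) {
    y <- rnbinom(12, mu = rep(exp(runif(2, 3, 6)), each = 6), size = 5)
    if (any(tapply(y, cond, sum) == 0)) next
    glm_fit <- fit_nb_glm(y, cond, dispersion = "ml")
    red <- fit_nb_glmm(y, cond, group = seq_along(y), fix_sigma_zero = TRUE)
    expect_equal(unname(red$beta), unname(glm_fit$beta), tolerance = 1e-3)
    expect_equal(red$theta, glm_fit$theta, tolerance = 5e-3)
    expect_equal(red$loglik, glm_fit$loglik, tolerance = 1e-6)
  }
})

test_that("GLMM fits agree with glmmTMB on random-intercept data", {
  skip_if_not_installed("glmmTMB")
  set.seed(8)
  K <- 8; per <- 4
  grp <- rep(seq_len(K), each = per)
  cond <- rep(rep(c("A", "B"), each = per / 2), K)
  for (i in 1:3) {
    b <- rnorm(K, 0, 0.6)
    y <- rnbinom(K * per, mu = exp(4 + 0.8 * (cond == "B") + b[grp]), size = 8)
    f <- fit_nb_glmm(y, cond, group = grp)
    ref <- suppressWarnings(glmmTMB::glmmTMB(
      y ~ cnd + (1 | g),
      data = data.frame(y = y, cnd = factor(cond), g = factor(grp)),
      family = glmmTMB::nbinom2))
    refco <- summary(ref)$coefficients$cond
    expect_equal(unname(f$beta), unname(refco[, "Estimate"]), tolerance = 1e-3)
    expect_equal(unname(f$se), unname(refco[, "Std. Error"]), tolerance = 1e-2)
    refs2 <- glmmTMB::VarCorr(ref)$cond$g[1]
    expect_equal(f$sigma2, unname(refs2), tolerance = 0.02)
  }
})

test_that("Wald test follows the standard-normal reference", {
  fake <- structure(list(beta = c(intercept = 0, condition = 0),
                         se = c(intercept = 1, condition = 1),
                         converged = TRUE), class = "GLMMFit")
  expect_equal(wald_test(fake), list(stat = 0, p = 1))
  fake$beta["condition"] <- 1.959964
  expect_equal(wald_test(fake)$p, 0.05, tolerance = 1e-5)
  fake$beta["condition"] <- -1.959964
  expect_equal(wald_test(fake)$p, 0.05, tolerance = 1e-5)  # symmetry
  fake$converged <- FALSE
  expect_true(is.na(wald_test(fake)$p))
})

test_that("p-value adjustment matches hand and brute-force step-up results", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.5, 0.2, 0.9), "bonferroni"),
               pmin(1, 4 * c(0.01, 0.5, 0.2, 0.9)))
  expect_equal(adjust_pvalues(rep(0.2, 5), "BH"), rep(0.2, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
  # NAs excluded from the effective number of tests
  expect_equal(adjust_pvalues(c(0.01, NA, 0.02), "bonferroni"),
               c(0.02, NA, 0.04))
  set.seed(9)
  for (i in 1:20) {
    p <- round(runif(8), 3)
    expect_equal(adjust_pvalues(p, "BH"), brute_force_bh(p),
                 tolerance = 1e-12, info = paste(p, collapse = ","))
  }
})

test_that("gene summaries convert coefficients and gate directions correctly", {
  fake <- structure(list(beta = c(intercept = 1, condition = log(2)),
                         se = c(intercept = 0.1, condition = 0.1),
                         converged = TRUE), class = "GLMMFit")
  s <- summarize_gene(fake, y = c(10, 20, 30, 40),
                      raw_libsizes = rep(1e6, 4), q_value = 0.01)
  expect_equal(s$log2fc, 1)
  expect_identical(s$direction, "up")
  s2 <- summarize_gene(fake, y = c(10, 20, 30, 40),
                       raw_libsizes = rep(1e6, 4), q_value = 0.2)
  expect_identical(s2$direction, "ns")
  fake$beta["condition"] <- -0.8
  s3 <- summarize_gene(fake, y = c(10, 20, 30, 40),
                       raw_libsizes = rep(1e6, 4), q_value = 0.01)
  expect_identical(s3$direction, "down")
  expect_equal(s3$log2fc, -0.8 / log(2), tolerance = 1e-6)
})

test_that("inference runs are deterministic and handle empty input", {
  sim <- simulate_fixed(sim_config(n_genes = 120, replicates = 4,
                                   deg_proportion = 0.1, seed = 2))
  pp <- preprocess(sim$matrix, sim$design)
  r1 <- run_inference(pp, random = "sample_id")
  r2 <- run_inference(pp, random = "sample_id")
  expect_identical(r1, r2)
  expect_true(all(r1$q_value >= r1$p_value - 1e-12, na.rm = TRUE))
  empty <- run_inference(
    structure(list(values = matrix(numeric(), 0, 4,
                                   dimnames = list(NULL, tiny_design()$sample_id)),
                   is_raw = TRUE), class = "CountMatrix"),
    design = tiny_design())
  expect_equal(nrow(empty), 0)
})

test_that("Wald p-values are near-uniform under a simulated null", {
  des <- two_group_design(6)
  set.seed(31)
  mu <- rlnorm(1000, 5, 1.5)
  y <- matrix(rnbinom(1000 * 12, mu = rep(mu, 12), size = 10), 1000, 12,
              dimnames = list(sprintf("g%04d", 1:1000), des$sample_id))
  res <- run_inference(count_matrix(y), des)
  p <- res$p_value[!is.na(res$p_value)]
  expect_gt(length(p), 950)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
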
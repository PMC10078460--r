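test_that("scale correction matches the closed form and equalizes column sums", {
  m <- matrix(c(10, 10, 30, 10), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sc <- scale_correct(count_matrix(m))
  expect_equal(sc$nu, c(s1 = 20, s2 = 40))
  expect_equal(sc$lambda, 20)
  expect_equal(unname(sc$matrix$values),
               matrix(c(10, 10, 15, 5), 2, 2))
  expect_false(sc$matrix$is_raw)

  # equal column sums: output identical to input
  m2 <- matrix(c(5, 15, 12, 8), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(scale_correct(count_matrix(m2))$matrix$values, m2)

  # property: all output column sums equal the minimum input column sum
  for (seed in 1:5) {
    x <- rand_counts(m = 30, n = 5, seed = seed)
    sc <- scale_correct(x)
    cs <- colSums(sc$matrix$values)
    expect_lt(max(abs(cs - sc$lambda)) / sc$lambda, 1e-9)
  }

  # doubling a non-minimum library leaves its corrected column unchanged
  x <- rand_counts(m = 30, n = 4, seed = 7)
  j <- which.max(colSums(x$values))
  doubled <- x$values
  doubled[, j] <- 2 * doubled[, j]
  expect_equal(scale_correct(count_matrix(doubled))$matrix$values[, j],
               scale_correct(x)$matrix$values[, j])

  m0 <- matrix(c(1, 2, 0, 0), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "sZ")))
  expect_error(scale_correct(count_matrix(m0)), "sZ")
})

test_that("RLE size factors follow the median-of-ratios definition", {
  m <- matrix(c(4, 1, 16, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(rle_size_factors(m), c(s1 = 0.5, s2 = 2))

  # identical columns: all factors 1
  m2 <- matrix(rep(c(3, 9, 27), 4), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(rle_size_factors(m2)), rep(1, 4))

  # scaling one column by c multiplies its factor by c^(1 - 1/n) relative
  # shift absorbed in the geometric means; check the defining ratio instead
  x <- rand_counts(m = 50, n = 4, seed = 3, mu = 100)$values + 1
  sf <- rle_size_factors(x)
  x2 <- x
  x2[, 2] <- x[, 2] * 4
  sf2 <- rle_size_factors(x2)
  # ratios between samples scale: factor of sample 2 quadruples relative to others
  expect_equal(unname((sf2[2] / sf2[1]) / (sf[2] / sf[1])), 4, tolerance = 1e-12)

  zeroy <- matrix(c(0, 1, 1, 0), 2, 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(rle_size_factors(zeroy), "RLE undefined")
})

test_that("all-zero and constant filters remove exactly the right genes", {
  m <- rbind(z = c(0, 0, 0, 0), p = c(0, 0, 0, 1), ok = c(5, 6, 7, 8))
  colnames(m) <- paste0("s", 1:4)
  fz <- filter_all_zero(m)
  expect_identical(fz$removed, "z")
  expect_identical(rownames(fz$matrix$values), c("p", "ok"))

  m2 <- rbind(const = c(7, 7, 7, 7), near = c(7, 7, 7, 8))
  colnames(m2) <- paste0("s", 1:4)
  fc <- filter_constant(m2)
  expect_identical(fc$removed, "const")
  expect_identical(rownames(fc$matrix$values), "near")
})

test_that("zero-comparison Wilcoxon matches exact enumeration and keeps/removes per the rule", {
  y_keep <- c(0, 8, 9, 10, 7, 0, 6, 5, 9, 8)   # n = 10, normal branch
  expect_lt(zero_wilcoxon_pvalue(y_keep), 0.05)
  y_drop <- c(0, 0, 0, 5)                      # n = 4, exact branch
  expect_gt(zero_wilcoxon_pvalue(y_drop), 0.05)
  expect_equal(zero_wilcoxon_pvalue(y_drop), brute_force_zero_test(y_drop))

  # exact branch agrees with brute-force pair-counting on random small genes
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    y <- rnbinom(n, mu = 4, size = 1)
    if (all(y == 0)) y[1] <- 3
    expect_equal(zero_wilcoxon_pvalue(y), brute_force_zero_test(y),
                 info = paste(y, collapse = ","))
  }

  # normal branch agrees with the tie-corrected normal approximation in stats
  set.seed(7)
  for (i in 1:10) {
    y <- rnbinom(12, mu = 6, size = 1)
    if (all(y == 0)) y[1] <- 3
    if (all(y > 0)) y[1] <- 0
    ref <- suppressWarnings(
      stats::wilcox.test(y, rep(0, 12), exact = FALSE, correct = TRUE))$p.value
    expect_equal(zero_wilcoxon_pvalue(y), ref, tolerance = 1e-10)
  }
})

test_that("partial-expression filter keeps tested genes only below alpha", {
  m <- rbind(keep = c(0, 8, 9, 10, 7, 0, 6, 5, 9, 8),
             drop = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 5),
             full = c(3, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  colnames(m) <- paste0("s", 1:10)
  fw <- filter_partial_wilcoxon(m, alpha = 0.05)
  expect_identical(fw$removed, "drop")
  expect_identical(fw$kept_partial, "keep")
  expect_identical(rownames(fw$matrix$values), c("keep", "full"))
})

test_that("low-CPM filter uses raw library sizes and the <= threshold rule", {
  m <- rbind(lo = c(1, 1), hi = c(3, 3))
  colnames(m) <- c("s1", "s2")
  f <- filter_low_cpm(m, raw_libsizes = c(2e6, 2e6), threshold = 1)
  expect_identical(f$removed, "lo")  # mean CPM 0.5 <= 1
  f2 <- filter_low_cpm(m, raw_libsizes = c(1e6, 1e6), threshold = 1)
  expect_identical(f2$removed, "lo") # hi: mean CPM 3 > 1 kept
  f3 <- filter_low_cpm(m, raw_libsizes = c(1e6, 1e6), threshold = 0)
  expect_identical(f3$removed, character(0))
})

test_that("preprocess tallies partition the input and stages never alter retained values", {
  # fixture: one all-zero, one constant, one low-CPM, three clean genes,
  # plus a bulk gene fixing every library size at 2e6 so mean CPM of 'lo'
  # is (1+2+1+1)/4 / 2 = 0.625 <= 1
  m <- rbind(zz = c(0, 0, 0, 0),
             cc = c(9, 9, 9, 9),
             lo = c(1, 2, 1, 1),
             a = c(900, 1100, 2000, 2500),
             b = c(1500, 1400, 700, 600),
             c = c(800, 900, 1000, 1100))
  colnames(m) <- paste0("s", 1:4)
  m <- rbind(m, bulk = 2e6 - colSums(m))
  d <- tiny_design()
  pp <- preprocess(count_matrix(m), d, truth = data.frame(
    gene_id = rownames(m), label = "non-DEG", stringsAsFactors = FALSE))
  r <- pp$report
  expect_equal(r$n_unexpressed, 1)
  expect_equal(r$n_constant_removed, 1)
  expect_equal(r$n_lowcpm_removed, 1)
  expect_identical(sort(r$removed_ids$low_cpm), "lo")
  expect_equal(r$n_retained, 4)  # a, b, c, bulk
  expect_equal(r$n_retained + r$n_unexpressed + r$n_partial_removed +
                 r$n_constant_removed + r$n_lowcpm_removed, r$n_input_genes)
  expect_equal(r$deg_loss_percent, 0)  # all non-DEG truth
  # retained raw values are untouched rows of the input
  expect_identical(pp$counts$values, m[rownames(pp$counts$values), ])

  # property: tallies partition on random generator fixtures
  for (seed in 1:3) {
    sim <- simulate_fixed(sim_config(n_genes = 300, replicates = 3,
                                     deg_proportion = 0.1, seed = seed))
    rep_ <- preprocess(sim$matrix, sim$design)$report
    expect_equal(rep_$n_retained + rep_$n_unexpressed + rep_$n_partial_removed +
                   rep_$n_constant_removed + rep_$n_lowcpm_removed,
                 rep_$n_input_genes)
    ids <- rep_$removed_ids
    expect_equal(anyDuplicated(unlist(ids)), 0L)
  }
})
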
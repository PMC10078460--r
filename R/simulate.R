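#' Simulation configuration for fixed-effect count matrices
#'
#' Describes a two-condition RNA-seq count matrix with known differentially
#' expressed genes. Expressed ("core") genes draw a log-normal baseline mean
#' and NB2 counts with common dispersion `phi`; DEGs (an equal up/down split)
#' multiply the second condition's mean by `2^(+/- log2fc)` with magnitude
#' uniform on `fc_range`. Structural gene classes exercising each
#' preprocessing filter are appended: all-zero genes, partially expressed
#' genes (zeros in a random subset of samples), constant genes, and
#' low-count genes whose average CPM falls below one at realistic matrix
#' sizes. The default structural fractions reproduce the observed composition
#' of whole-transcriptome matrices (roughly a third unexpressed, a tenth
#' partially expressed, a fifth weakly expressed, a trace of constant genes).
#'
#' @param n_genes total genes (default 38293, a whole-transcriptome scale).
#' @param replicates biological replicates per condition, 2-15 (default 6).
#' @param deg_proportion fraction of `n_genes` that are DEGs (paper grid:
#'   0.10/0.20/0.30); up:down ratio is fixed at 1:1.
#' @param phi NB dispersion of core genes (default 0.09, i.e. BCV 0.3).
#' @param meanlog,sdlog log-normal parameters of core baseline means.
#' @param fc_range range of |log2 fold change| for DEGs (default c(1, 2)).
#' @param f_all_zero,f_partial,f_constant,f_low structural class fractions.
#' @param seed integer RNG seed; the whole matrix is reproducible from it.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_genes = 38293L, replicates = 6L,
                       deg_proportion = 0.10, phi = 0.09,
                       meanlog = 5, sdlog = 2, fc_range = c(1, 2),
                       f_all_zero = 0.33, f_partial = 0.10,
                       f_constant = 0.001, f_low = 0.22, seed = 1L) {
  if (n_genes < 10L) stop("n_genes must be at least 10")
  if (!(replicates >= 2L && replicates <= 15L)) {
    stop("replicates per condition must be in 2..15")
  }
  if (deg_proportion < 0 || deg_proportion > 1) {
    stop("deg_proportion must be in [0, 1]")
  }
  fr <- c(f_all_zero, f_partial, f_constant, f_low)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1) {
    stop("structural fractions must be in [0, 1] and sum to < 1")
  }
  cfg <- list(n_genes = as.integer(n_genes), replicates = as.integer(replicates),
              deg_proportion = deg_proportion, phi = phi, meanlog = meanlog,
              sdlog = sdlog, fc_range = fc_range, f_all_zero = f_all_zero,
              f_partial = f_partial, f_constant = f_constant, f_low = f_low,
              seed = as.integer(seed))
  n_deg <- 2L * round(n_genes * deg_proportion / 2)
  n_core <- n_genes - sum(round(n_genes * fr))
  if (n_deg > n_core) {
    stop("deg_proportion too large for the structural fractions: ",
         n_deg, " DEGs but only ", n_core, " expressed genes")
  }
  structure(cfg, class = "SimConfig")
}

#' Simulate a fixed-effect count matrix with known DEGs
#'
#' Draws the matrix described by a [sim_config()]. Truth labels are exact:
#' `round(n_genes * deg_proportion / 2)` genes up and the same number down,
#' all among the expressed core. Gene order is shuffled so structural classes
#' are interleaved. Samples are named `A_1..A_r, B_1..B_r` with condition
#' levels `A` (reference) and `B`.
#'
#' @param config a [sim_config()].
#' @return A `SimResult` list: `matrix` (raw [count_matrix()]), `truth`
#'   (data frame gene_id, label in `up`/`down`/`non-DEG`), `design`
#'   ([design_table()]), and `config`.
#' @export
simulate_fixed <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  r <- config$replicates
  n <- 2L * r
  ng <- config$n_genes
  n_zero <- round(ng * config$f_all_zero)
  n_partial <- round(ng * config$f_partial)
  n_const <- round(ng * config$f_constant)
  n_low <- round(ng * config$f_low)
  n_core <- ng - n_zero - n_partial - n_const - n_low
  n_each <- round(ng * config$deg_proportion / 2)

  # expressed core: log-normal baselines, NB counts, fold change on condition B
  lam <- rlnorm(n_core, meanlog = config$meanlog, sdlog = config$sdlog)
  lfc <- numeric(n_core)
  deg_idx <- if (n_each > 0) sample.int(n_core, 2L * n_each) else integer()
  up_idx <- deg_idx[seq_len(n_each)]
  down_idx <- deg_idx[-seq_len(n_each)]
  mag <- runif(2L * n_each, config$fc_range[1], config$fc_range[2])
  lfc[up_idx] <- mag[seq_len(n_each)]
  lfc[down_idx] <- -mag[-seq_len(n_each)]
  size <- 1 / config$phi
  mu <- cbind(matrix(rep(lam, r), n_core, r),
              matrix(rep(lam * 2^lfc, r), n_core, r))
  core <- matrix(rnbinom(n_core * n, mu = as.vector(mu), size = size),
                 n_core, n)

  # structural classes
  zero <- matrix(0, n_zero, n)
  partial <- matrix(0, n_partial, n)
  if (n_partial > 0) {
    # dropout regime: partial expression arises from low abundance, so the
    # few that pass the Wilcoxon filter still sit below the CPM cutoff at
    # transcriptome scale
    lam_p <- rlnorm(n_partial, meanlog = 0.7, sdlog = 0.7)
    npos <- sample(seq_len(n - 1L), n_partial, replace = TRUE)
    for (i in seq_len(n_partial)) {
      pos <- sample.int(n, npos[i])
      partial[i, pos] <- pmax(1, rnbinom(npos[i], mu = lam_p[i], size = size))
    }
  }
  const <- matrix(rep(1 + rpois(n_const, 10), each = 1), n_const, n)
  low <- matrix(1 + rpois(n_low * n, 0.5), n_low, n)

  values <- rbind(core, zero, partial, const, low)
  label <- c(
    {lab <- rep("non-DEG", n_core); lab[up_idx] <- "up"; lab[down_idx] <- "down"; lab},
    rep("non-DEG", n_zero + n_partial + n_const + n_low)
  )
  ord <- sample.int(ng)
  values <- values[ord, , drop = FALSE]
  label <- label[ord]
  gene_id <- sprintf("gene_%05d", seq_len(ng))
  rownames(values) <- gene_id
  sample_id <- c(paste0("A_", seq_len(r)), paste0("B_", seq_len(r)))
  colnames(values) <- sample_id
  design <- design_table(sample_id, condition = rep(c("A", "B"), each = r))

  structure(list(
    matrix = count_matrix(values, is_raw = TRUE),
    truth = data.frame(gene_id = gene_id, label = label,
                       stringsAsFactors = FALSE),
    design = design,
    config = config
  ), class = "SimResult")
}

#' Random-effect injection configuration
#'
#' Parameters of the truncated-normal perturbation added to a fixed-effect
#' matrix: one independent `N(mean, sdnd^2)` draw per matrix entry, negatives
#' clamped to zero, values rounded half-away-from-zero to the nearest
#' integer. The study's SDND grid is 100, 300, 600, 900, 1200, 2000, 3000.
#'
#' @param mean mean of the normal perturbation; see [default_re_mean()] for
#'   the replicate-dependent defaults estimated from public transcriptome
#'   data, or [estimate_random_effect_mean()] to recompute one.
#' @param sdnd standard deviation of the normal distribution (>= 0).
#' @param seed integer RNG seed.
#' @return A `RandomEffectConfig` list.
#' @export
re_config <- function(mean = 0, sdnd = 300, seed = 1L) {
  if (sdnd < 0) stop("sdnd must be >= 0")
  structure(list(mean = mean, sdnd = sdnd, seed = as.integer(seed)),
            class = "RandomEffectConfig")
}

#' Default injection mean by replicate number
#'
#' Mean parameters of the random-effect normal distribution estimated from
#' public GEO transcriptome series matched by replicate count: 2.028 for two
#' replicates, 9.937 for three, 7.158 for four, -3.429 for five to nine, and
#' -1.615 for ten or more.
#'
#' @param replicates biological replicates per condition (>= 2).
#' @return The mean parameter.
#' @export
default_re_mean <- function(replicates) {
  replicates <- as.integer(replicates)
  if (replicates < 2L) stop("replicates must be >= 2")
  if (replicates == 2L) return(2.028)
  if (replicates == 3L) return(9.937)
  if (replicates == 4L) return(7.158)
  if (replicates <= 9L) return(-3.429)
  -1.615
}

#' Estimate the random-effect mean parameter from data
#'
#' For each gene, the difference between the second and first condition's
#' replicate averages is computed; the returned mean parameter is the average
#' of these per-gene differences. Intended to be run on a preprocessed
#' matrix. Swapping condition labels negates the result.
#'
#' @param x a [count_matrix()] or matrix (typically the retained counts from
#'   [preprocess()]).
#' @param design matching [design_table()].
#' @return The mean parameter (a single number).
#' @export
estimate_random_effect_mean <- function(x, design) {
  al <- align_counts(as_filter_input(x), design)
  m <- al$matrix$values
  cond <- design_condition(al$design)
  lev <- levels(cond)
  if (length(lev) != 2L) stop("two experimental conditions are required")
  d <- rowMeans(m[, cond == lev[2], drop = FALSE]) -
       rowMeans(m[, cond == lev[1], drop = FALSE])
  mean(d)
}

#' Inject random effects into a fixed-effect count matrix
#'
#' Adds one independent normal draw to every matrix entry, replaces negative
#' results with zero, and rounds half-away-from-zero to the nearest integer,
#' returning a valid raw count matrix.
#'
#' @param x raw [count_matrix()] or integer matrix.
#' @param config a [re_config()].
#' @return A raw [count_matrix()] with non-negative integer entries.
#' @export
inject_random_effects <- function(x, config = re_config()) {
  stopifnot(inherits(config, "RandomEffectConfig"))
  m <- count_values(x)
  set.seed(config$seed)
  noise <- matrix(rnorm(length(m), mean = config$mean, sd = config$sdnd),
                  nrow(m), ncol(m))
  out <- floor(pmax(m + noise, 0) + 0.5)  # half-away-from-zero on x >= 0
  dimnames(out) <- dimnames(m)
  count_matrix(out, is_raw = TRUE)
}
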
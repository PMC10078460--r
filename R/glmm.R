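#' Fit a negative binomial GLM to one gene
#'
#' NB2 regression (variance \eqn{\mu + \mu^2/\theta}) with log link on an
#' intercept-plus-condition design: iteratively reweighted least squares for
#' the coefficients inside a one-dimensional profile search over
#' \eqn{\log\theta}. Standard errors come from the expected information at
#' fixed \eqn{\theta}. Serves as the zero-random-effect baseline and as the
#' fallback when the mixed model's variance component hits its boundary.
#'
#' @param y non-negative integer counts.
#' @param condition two-level factor (or vector); the coefficient is level 2
#'   minus level 1 on the natural-log scale.
#' @param offset per-sample offset on the log scale (default 0).
#' @param dispersion `"adjusted"` (default) estimates \eqn{\theta} by
#'   maximizing the Cox-Reid adjusted profile likelihood, which removes the
#'   upward small-sample bias of the ML dispersion and keeps the downstream
#'   Wald test calibrated; `"ml"` is the plain maximum-likelihood profile
#'   (the `MASS::glm.nb` estimate).
#' @return A `GLMMFit` with `beta` (intercept, condition), `se`, `theta`,
#'   `sigma2 = 0`, `loglik`, `converged`, `n_iter`, `df` (residual degrees of
#'   freedom for the Wald reference), `boundary = FALSE`, and
#'   `method = "glm"`.
#' @export
fit_nb_glm <- function(y, condition, offset = NULL,
                       dispersion = c("adjusted", "ml")) {
  dispersion <- match.arg(dispersion)
  d <- check_gene_inputs(y, condition, offset)
  f <- cpp_fit_nb_glm(d$y, d$x, d$offset, cox_reid = dispersion == "adjusted")
  new_glmm_fit(f, sigma2 = 0, boundary = FALSE, method = "glm",
               df = length(d$y) - 2)
}

#' Fit a negative binomial GLMM to one gene
#'
#' NB2 mixed model with a fixed condition effect and a random intercept per
#' level of `group`, estimated by maximizing the Laplace-approximate marginal
#' likelihood over \eqn{(\beta, \log\theta, \log\sigma^2)}. Inner Newton
#' iterations solve for the conditional mode of each group's random
#' intercept; the outer problem is optimized by Nelder-Mead followed by
#' Newton polish on finite-difference derivatives, with standard errors from
#' the inverse observed information at the optimum. Initialization is
#' deterministic (Poisson GLM for \eqn{\beta}, method-of-moments
#' \eqn{\theta}, \eqn{\sigma^2 = 0.1}), so identical inputs give identical
#' fits. When the variance component collapses to its lower bound
#' (\eqn{10^{-8}}) the gene is automatically refitted as an NB GLM and
#' flagged with `boundary = TRUE`.
#'
#' @inheritParams fit_nb_glm
#' @param group random-intercept grouping labels, one per sample; `NULL`
#'   drops the random term (plain NB fit through the same objective).
#' @param fix_sigma_zero force \eqn{\sigma^2 = 0}; the objective reduces to
#'   the plain NB log-likelihood (used to check the GLM reduction).
#' @param sigma2_init starting variance for the random intercept.
#' @param max_outer maximum outer Newton-polish iterations before the fit is
#'   flagged non-converged.
#' @return A `GLMMFit`; see [fit_nb_glm()] for the fields.
#' @export
fit_nb_glmm <- function(y, condition, group = NULL, offset = NULL,
                        fix_sigma_zero = FALSE, sigma2_init = 0.1,
                        max_outer = 200L) {
  d <- check_gene_inputs(y, condition, offset)
  no_random <- is.null(group) || fix_sigma_zero
  if (no_random) {
    grp <- integer(length(d$y))
  } else {
    group <- factor(group)
    if (length(group) != length(d$y)) stop("group length must match y")
    grp <- as.integer(group) - 1L
  }
  f <- cpp_fit_nb_glmm(d$y, d$x, d$offset, grp, fix_sigma0 = no_random,
                       sigma2_init = sigma2_init, max_outer = max_outer)
  if (isTRUE(f$boundary)) {
    g <- fit_nb_glm(y, condition, offset)
    g$boundary <- TRUE
    return(g)
  }
  # residual df convention: n - rank(X); variance parameters (theta, sigma2)
  # are not counted, matching the GLM path
  new_glmm_fit(f, sigma2 = if (no_random) 0 else f$sigma2,
               boundary = FALSE, method = if (no_random) "glmm0" else "glmm",
               df = length(d$y) - 2)
}

check_gene_inputs <- function(y, condition, offset) {
  y <- as.numeric(y)
  if (any(y < 0) || anyNA(y)) stop("counts must be non-negative")
  cond <- factor(condition)
  if (nlevels(cond) != 2L) stop("condition must have exactly 2 levels")
  if (length(cond) != length(y)) stop("condition length must match y")
  if (is.null(offset)) offset <- rep(0, length(y))
  if (length(offset) == 1L) offset <- rep(offset, length(y))
  list(y = y, x = as.numeric(cond == levels(cond)[2L]), offset = as.numeric(offset))
}

new_glmm_fit <- function(f, sigma2, boundary, method, df) {
  structure(list(
    beta = stats::setNames(as.numeric(f$beta), c("intercept", "condition")),
    se = stats::setNames(as.numeric(f$se), c("intercept", "condition")),
    theta = as.numeric(f$theta),
    sigma2 = as.numeric(sigma2),
    loglik = as.numeric(f$loglik),
    converged = isTRUE(f$converged),
    n_iter = as.integer(f$n_iter),
    df = as.numeric(df),
    boundary = isTRUE(boundary),
    method = method
  ), class = "GLMMFit")
}

#' @export
print.GLMMFit <- function(x, ...) {
  cat(sprintf("NB %s fit: beta = (%.4f, %.4f), theta = %.3f, sigma2 = %.4g, ll = %.2f%s\n",
              x$method, x$beta[1], x$beta[2], x$theta, x$sigma2, x$loglik,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Wald test of a fitted coefficient
#'
#' The reference distribution is Student t on the fit's residual degrees of
#' freedom (`df = Inf` gives the standard-normal reference); combined with
#' the adjusted dispersion estimate this keeps the small-sample type-I error
#' near nominal.
#'
#' @param fit a `GLMMFit`.
#' @param coef coefficient name or index (default the condition effect).
#' @param df degrees of freedom of the t reference; defaults to the fit's
#'   residual df, `Inf` for a standard-normal tail probability.
#' @return List with `stat` (\eqn{\beta/SE}) and the two-sided `p`; both
#'   `NA` for non-converged fits.
#' @export
wald_test <- function(fit, coef = "condition", df = NULL) {
  b <- fit$beta[coef]
  s <- fit$se[coef]
  if (is.null(df)) df <- fit$df %||% Inf
  if (!is.finite(df) || df <= 0) df <- Inf
  if (!isTRUE(fit$converged) || !is.finite(b) || !is.finite(s) || s <= 0) {
    return(list(stat = NA_real_, p = NA_real_))
  }
  stat <- as.numeric(b / s)
  list(stat = stat, p = 2 * stats::pt(-abs(stat), df = df))
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up or Bonferroni adjustment, with `NA` p-values
#' excluded from the effective number of tests and preserved in place.
#'
#' @param p vector of p-values in `[0, 1]` (NAs allowed).
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted q-values in input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = method)
  q
}

#' Summarize one gene's fit
#'
#' Converts the condition coefficient to a log2 fold change, computes the
#' average log2 CPM (raw-library CPM with a 0.5 shift), the Wald statistic
#' and raw p-value, and — when a q-value is supplied — the regulation
#' direction (`up`/`down` when q < `alpha_fdr` and |log2FC| clears
#' `lfc_cutoff`, otherwise `ns`).
#'
#' @param fit a `GLMMFit`.
#' @param y the gene's raw counts.
#' @param raw_libsizes per-sample raw library sizes.
#' @param alpha_fdr significance threshold on the adjusted p-value.
#' @param lfc_cutoff minimum absolute log2 fold change called (default 0).
#' @param q_value adjusted p-value (NA when not yet computed).
#' @return One-row data frame with log2fc, avg_logcpm, wald_stat, p_value,
#'   q_value and direction.
#' @export
summarize_gene <- function(fit, y, raw_libsizes, alpha_fdr = 0.05,
                           lfc_cutoff = 0, q_value = NA_real_) {
  w <- wald_test(fit)
  log2fc <- as.numeric(fit$beta["condition"]) / log(2)
  if (!isTRUE(fit$converged)) log2fc <- NA_real_
  avg_logcpm <- mean(log2(y / raw_libsizes * 1e6 + 0.5))
  direction <- "ns"
  if (is.finite(q_value) && is.finite(log2fc) && q_value < alpha_fdr) {
    if (log2fc >= lfc_cutoff) direction <- "up"
    else if (log2fc <= -lfc_cutoff) direction <- "down"
  }
  data.frame(log2fc = log2fc, avg_logcpm = avg_logcpm,
             wald_stat = w$stat, p_value = w$p, q_value = q_value,
             direction = direction, stringsAsFactors = FALSE)
}

#' Differential-expression inference over a matrix
#'
#' Fits the per-gene NB model (mixed when `random` names a grouping column,
#' plain GLM otherwise) to every retained gene, tests the condition
#' coefficient with a Wald test, corrects across genes, and assembles the
#' result table. Normalization is encoded as a per-sample offset
#' \eqn{\log(s_j \nu_j)} (RLE size factor times raw library size) so the
#' likelihood keeps integer counts. Genes whose fit fails are reported with
#' `NA` p-values and excluded from the correction; the run never aborts on a
#' single gene. The procedure is deterministic.
#'
#' @param x a `preprocessed_counts` object from [preprocess()] (preferred:
#'   carries size factors and raw library sizes), or a raw [count_matrix()]
#'   whose offsets are then computed from itself.
#' @param design matching [design_table()]; defaults to the design stored in
#'   a `preprocessed_counts` input.
#' @param random name of one random-intercept grouping column of the design
#'   (`"sample_id"` gives a per-sample intercept); `NULL` for a fixed-effects
#'   NB GLM.
#' @param correction `"BH"` or `"bonferroni"`.
#' @param alpha significance level on adjusted p-values.
#' @param lfc_cutoff minimum |log2FC| for an up/down call (default 0; any
#'   user cutoff may be supplied).
#' @param overdispersed_only fit only genes classified overdispersed by
#'   [classify_dispersion()]; others are reported unscored.
#' @return Data frame with one row per gene: gene_id, log2fc, avg_logcpm,
#'   wald_stat, p_value, q_value, direction, converged, boundary, sigma2,
#'   theta.
#' @export
run_inference <- function(x, design = NULL, random = NULL,
                          correction = c("BH", "bonferroni"), alpha = 0.05,
                          lfc_cutoff = 0, overdispersed_only = FALSE) {
  correction <- match.arg(correction)
  if (inherits(x, "preprocessed_counts")) {
    if (is.null(design)) design <- x$design
    cm <- x$counts
    sf <- x$report$size_factors
    L <- x$report$raw_libsizes
  } else {
    if (is.null(design)) stop("design is required")
    cm <- as_count_matrix(x)
    L <- colSums(cm$values)
    sf <- tryCatch(rle_size_factors(scale_correct(cm)$matrix),
                   error = function(e) stats::setNames(rep(1, length(L)),
                                                       names(L)))
  }
  m <- count_values(cm)
  if (nrow(m) == 0L) {
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      avg_logcpm = numeric(), wald_stat = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      direction = character(), converged = logical(),
                      boundary = logical(), sigma2 = numeric(),
                      theta = numeric(), stringsAsFactors = FALSE))
  }
  al <- align_counts(cm, design)
  m <- al$matrix$values
  design <- al$design
  cond <- design_condition(design)
  offsets <- log(L[colnames(m)] * sf[colnames(m)])
  offsets <- offsets - mean(offsets)

  group <- NULL
  if (!is.null(random)) {
    if (length(random) != 1L) stop("exactly one random-effect column is supported")
    if (!random %in% names(design)) {
      stop("random-effect column '", random, "' not found in design")
    }
    group <- design[[random]]
  }

  fit_genes <- rep(TRUE, nrow(m))
  if (overdispersed_only) {
    disp <- classify_dispersion(al$matrix, design)
    fit_genes <- disp$table$label == "overdispersed"
  }

  ng <- nrow(m)
  res <- data.frame(gene_id = rownames(m), log2fc = NA_real_,
                    avg_logcpm = NA_real_, wald_stat = NA_real_,
                    p_value = NA_real_, q_value = NA_real_,
                    direction = "ns", converged = FALSE, boundary = FALSE,
                    sigma2 = NA_real_, theta = NA_real_,
                    stringsAsFactors = FALSE)
  Lj <- L[colnames(m)]
  for (i in seq_len(ng)) {
    y <- m[i, ]
    res$avg_logcpm[i] <- mean(log2(y / Lj * 1e6 + 0.5))
    if (!fit_genes[i]) next
    fit <- tryCatch({
      if (is.null(group)) fit_nb_glm(y, cond, offset = offsets)
      else fit_nb_glmm(y, cond, group = group, offset = offsets)
    }, error = function(e) NULL)
    if (is.null(fit)) next
    w <- wald_test(fit)
    res$converged[i] <- fit$converged
    res$boundary[i] <- fit$boundary
    res$sigma2[i] <- fit$sigma2
    res$theta[i] <- fit$theta
    if (isTRUE(fit$converged)) {
      res$log2fc[i] <- as.numeric(fit$beta["condition"]) / log(2)
      res$wald_stat[i] <- w$stat
      res$p_value[i] <- w$p
    }
  }
  res$q_value <- adjust_pvalues(res$p_value, method = correction)
  sig <- !is.na(res$q_value) & res$q_value < alpha & !is.na(res$log2fc)
  res$direction[sig & res$log2fc >= lfc_cutoff] <- "up"
  res$direction[sig & res$log2fc <= -lfc_cutoff] <- "down"
  res
}
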
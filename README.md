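# mixedde

Differential-expression inference for RNA-seq count matrices with
**negative binomial generalized linear mixed models**, for experiments where
per-sample random variation (sex, donor, any individual-level grouping)
should not be folded into the fixed condition effect. Tools built on
fixed-effects GLMs treat that variation as noise or as a fixed covariate;
modeling it as a random intercept reduces both missed DEGs and false
positives when biological variability is high.

Per gene, the model is NB2 with log link:

```
log mu_ij = beta0 + beta1 * x_j + o_j + b_g(j),   y_ij | b ~ NB(mu_ij, theta)
```

with `x_j` the condition indicator, `o_j = log(size factor x library size)`
an offset encoding normalization, and `b_k ~ N(0, sigma^2)` a random
intercept per group level. The marginal likelihood is maximized by Laplace
approximation (compiled code; deterministic initialization, so results are
bit-reproducible). The condition coefficient is tested with a Wald statistic
against a Student-t reference on the residual df, with Benjamini-Hochberg or
Bonferroni correction; `log2FC = beta1 / ln 2`.

Around the model, the package implements the full workflow:

- **Preprocessing** (`preprocess()`): library scale correction to the
  smallest library, relative-log-expression (median-of-ratios) size
  factors, then four ordered filters — all-zero genes, partially expressed
  genes failing a zero-comparison Wilcoxon test (5% level), constant
  genes, and genes at or below 1 average CPM — with a report whose stage
  tallies always partition the input gene set.
- **Dispersion diagnostics** (`classify_dispersion()`, `estimate_bcv()`):
  per-gene Poisson-GLM Pearson ratio (≤ 1 equidispersed, > 1
  overdispersed) and a dataset-level biological coefficient of variation
  `sqrt(phi)` from a Cox-Reid-adjusted common NB dispersion profile.
- **Inference** (`run_inference()`): per-gene NB GLMM (or NB GLM baseline)
  over all retained genes, never aborting on single-gene failures.
- **Simulation** (`simulate_fixed()`, `inject_random_effects()`):
  two-condition count matrices with known DEG labels and structural gene
  classes exercising every filter, plus truncated-normal random-effect
  injection (one draw per entry, clamped at zero, rounded to integers).
- **Benchmarking** (`confusion()`, `de_metrics()`, `benchmark_grid()`):
  precision/recall/accuracy against simulation truth, with
  preprocessing-removed genes scored as negative calls.

A thin command-line front end with `simulate` / `preprocess` / `diagnose` /
`run` / `evaluate` subcommands ships at `inst/cli/mixedde.R`.

## Worked example

Simulate a 2,000-gene experiment (6 replicates per condition, 10% DEGs),
degrade it with per-entry random effects (sdnd = 300), then preprocess,
infer, and score against the known truth:

```r
library(mixedde)

sim   <- simulate_fixed(sim_config(n_genes = 2000, replicates = 6,
                                   deg_proportion = 0.1, seed = 1))
noisy <- inject_random_effects(sim$matrix,
                               re_config(mean = default_re_mean(6),
                                         sdnd = 300, seed = 2))
pp <- preprocess(noisy, sim$design, truth = sim$truth)
pp$report
#> Preprocessing report
#>   input genes:              2000
#>   expressed in all samples: 188
#>   removed, all-zero:        0
#>   removed, Wilcoxon:        141 (kept partial: 1671)
#>   removed, constant:        0
#>   removed, low CPM:         0
#>   retained:                 1859
#>   true DEGs lost:           1.50%

estimate_bcv(pp$counts, sim$design)
#> Common dispersion 6.2878 (BCV 2.508)

res <- run_inference(pp, random = "sample_id", correction = "BH", alpha = 0.05)
head(res[res$direction != "ns",
         c("gene_id", "log2fc", "q_value", "direction")], 3)
#>        gene_id    log2fc     q_value direction
#> 84  gene_00094 -1.953967 0.005692313      down
#> 264 gene_00284 -1.454091 0.039750707      down
#> 378 gene_00406 -1.443223 0.001226796      down

m <- de_metrics(confusion(sim$truth, res$gene_id[res$direction != "ns"]))
unlist(m)
#> precision    recall  accuracy
#> 0.958     0.115     0.911
```

Reading the numbers: the injected noise leaves no gene fully unexpressed but
punches zeros into most genes (hence the large Wilcoxon-tested class), and
drives the biological coefficient of variation from ~0.3 to 2.5. Under that
much noise the mixed model recovers 11.5% of the true DEGs while keeping
95.8% of its calls correct; filtering cost only 1.5% of the true DEGs.

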
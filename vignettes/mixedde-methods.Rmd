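---
title: "Methods: preprocessing and mixed-model inference for RNA-seq counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing and mixed-model inference for RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixedde)
```

mixedde infers differentially expressed genes (DEGs) between two conditions
from raw RNA-seq count matrices, modeling each gene with a negative binomial
generalized linear mixed model (GLMM) so that random variation attached to
individuals — sex, donor, or any other per-sample grouping — can be separated
from the fixed condition effect. This vignette explains the model, the
preprocessing pipeline that precedes it, the simulator used to validate both,
and the numerical and design choices a maintainer would want spelled out.

## The model

For gene $i$ with counts $y_{ij}$ in samples $j = 1, \dots, n$, the
conditional model is NB2 with log link:

$$\log \mu_{ij} = \beta_0 + \beta_1 x_j + o_j + b_{g(j)}, \qquad
  y_{ij} \mid b \sim \mathrm{NB}(\mu_{ij}, \theta_i),$$

where $x_j$ indicates the second condition level, $o_j$ is a fixed
per-sample offset, $b_k \sim N(0, \sigma_i^2)$ is a random intercept per
level of the chosen grouping column, and the NB2 variance is
$\mu + \mu^2/\theta$. With no random term the model reduces to an NB GLM.
The condition coefficient $\beta_1$ is the log fold change of level 2 over
level 1 (reference = first level observed in the design file);
`log2fc` $= \beta_1 / \ln 2$.

**Estimation.** The marginal likelihood is maximized by Laplace
approximation: for each candidate $(\beta, \log\theta, \log\sigma^2)$, inner
Newton iterations solve for the conditional mode $\hat b_k$ of each group
(the per-group objective is strictly concave, so this is safe), and the
approximate marginal log-likelihood adds the usual
$-\tfrac12 \log(-h''(\hat b_k))$ curvature terms. The outer problem is
optimized by Nelder–Mead followed by Newton polish on central
finite-difference derivatives; standard errors come from the inverse
observed information at the optimum. Initialization is deterministic
(Poisson GLM for $\beta$, method-of-moments $\theta$, $\sigma^2 = 0.1$), so
identical inputs give bit-identical output. Convergence is declared when the
gradient norm falls below $10^{-6} \max(1, |\ell|)$ — the relative scaling
keeps the criterion meaningful as $|\ell|$ grows with $n$ — and a fit that
has not converged after 200 polish iterations is flagged and reported with
`NA` p-values, excluded from multiple-testing correction. One random term is
supported (the pairwise designs this package targets use at most one, e.g.
sex); richer random structures are out of scope.

**Boundary behavior.** When $\hat\sigma^2$ collapses to its lower bound
($10^{-8}$), the gene is refitted as an NB GLM and flagged `boundary`. This
keeps the number of tested genes stable instead of dropping genes whose
random-effect variance is not identifiable.

**Offsets instead of normalized counts.** Normalization is encoded as
$o_j = \log(s_j \nu_j)$ — RLE size factor times raw library size, centered —
so the likelihood always sees integer counts. Dividing the counts themselves
would invalidate the NB likelihood; the offset formulation is the standard
equivalent.

**Dispersion and the test.** The per-gene $\theta$ in the GLM path is
estimated by maximizing the Cox–Reid adjusted profile likelihood
($\ell - \tfrac12 \log\det X^\top W X$). Plain maximum likelihood
overestimates $\theta$ badly at typical replicate numbers (median
$\hat\theta \approx 13$ at true $\theta = 10$ with $n = 12$), which deflates
the Wald standard errors: measured on null simulations
($m = 2000$, $n = 6$ per group, $\theta = 10$), ML dispersion with a normal
reference rejects at 0.108 instead of 0.05. The Wald statistic
$\beta_1 / \mathrm{SE}$ is therefore referred to a Student $t$ with
residual degrees of freedom $n - \mathrm{rank}(X)$; variance parameters
($\theta$, $\sigma^2$) are not counted in the df, in either path, so the
mixed model and the baseline are treated symmetrically. With these two
choices the measured type-I error is 0.050 (GLM path) and 0.055 (GLMM path).
Setting `df = Inf` in `wald_test()` recovers the plain normal reference.
P-values are corrected by Benjamini–Hochberg (default) or Bonferroni;
`adjust_pvalues()` excludes `NA`s from the effective number of tests.

## Preprocessing

The pipeline runs in a fixed order, and each removed gene is attributed to
the first stage that removes it, so the stage tallies always partition the
input gene set:

1. **Scale correction.** With column sums $\nu_j$ and
   $\lambda = \min_j \nu_j$, every entry becomes
   $(\lambda / \nu_j)\, a_{ij}$; all corrected column sums equal $\lambda$
   (enforced to $10^{-9}$ relative).
2. **RLE normalization.** Median-of-ratios size factors over the genes with
   strictly positive counts in all samples — the standard reference-set
   choice.
3. **All-zero filter.** Genes with zero counts everywhere are removed.
4. **Wilcoxon filter.** Genes expressed in some but not all samples are
   compared against an all-zero vector of equal length with a two-sided
   Mann–Whitney test at the 5% level; survivors are grouped with the fully
   expressed genes. The null distribution is enumerated exactly for
   $n \le 8$ (memoized over tie patterns) and uses the tie-corrected normal
   approximation with continuity correction above that. The pooled
   comparison means that with two or three replicates per condition the
   pooled $n$ is too small ever to reach $P < 0.05$, so all partially
   expressed genes are removed at those depths — consistent with the
   filter's conservative purpose. Testing per condition instead of pooled
   would be an alternative reading; it is not implemented.
5. **Constant filter.** Genes with identical raw counts in every sample are
   removed. Equality is tested on raw integers, since library-size division
   destroys it.
6. **Low-CPM filter.** Genes whose average counts-per-million is at or
   below 1 are removed. CPM is computed from the raw counts and the raw
   (pre-correction) library sizes — the conventional definition; whether
   the original tool fed normalized counts into this filter is not
   recoverable, so the raw-library choice is documented rather than claimed.

Filters only delete rows; retained values are never altered. The
(real-valued) normalized matrix is kept for reporting and dispersion
diagnostics, while inference consumes the raw counts of the retained genes
through the offset mechanism above. When ground-truth DEG labels are
supplied, the report also gives the percentage of true DEGs lost, which the
benchmark scores as false negatives — filtering loss is a recall cost, not
a free action.

## Dispersion diagnostics

`pearson_ratio()` fits a Poisson GLM (intercept + condition; with this
design the MLE fitted means are the group means, so the ratio has a closed
form) and divides the Pearson chi-square by its residual df $n - 2$: at most
1 means equidispersed, above 1 overdispersed. Including the condition term
prevents true differential expression from masquerading as overdispersion;
an intercept-only mode is available for sensitivity analysis. Groups with a
zero fitted mean are skipped with the df reduced accordingly, and a gene
with no df left is conservatively labeled equidispersed.

`estimate_bcv()` estimates one common NB dispersion $\phi$ by profile
likelihood over $\log\phi \in [\log 10^{-6}, \log 10]$ (Brent, tolerance
$10^{-8}$), with counts equalized to the geometric-mean library size and
gene-by-condition means plugged in as group averages, plus a Cox–Reid
adjustment for those plugged-in means — without it the estimate is biased
low by roughly a factor $(n_g - 1)/n_g$ per group. The biological
coefficient of variation is $\sqrt{\phi}$. This approximates edgeR's
quantile-adjusted conditional ML (the pseudo-count machinery is not
reproduced) and agrees with `estimateCommonDisp` to the first decimal place
in the package's tests, which is the precision at which BCVs are reported.
It is a single dataset-level number by construction; per-gene or trended
dispersion estimation is deliberately out of scope.

## The simulator

`simulate_fixed()` draws two-condition count matrices with known DEG labels,
standing in for a full transcriptome simulator. Defaults describe a
whole-transcriptome experiment:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 38,293 | transcriptome scale (desk-scale analyses use 5,000) |
| `replicates` | 6 | per condition, supported range 2–15 |
| `deg_proportion` | 0.10 | study grid 0.10 / 0.20 / 0.30, up:down fixed 1:1 |
| `phi` | 0.09 | core NB dispersion, i.e. BCV 0.3 |
| `meanlog`, `sdlog` | 5, 2 | log-normal baseline means of expressed genes |
| `fc_range` | (1, 2) | uniform \|log2FC\| of DEGs |
| `f_all_zero` | 0.33 | unexpressed genes |
| `f_partial` | 0.10 | genes expressed in a random subset of samples |
| `f_constant` | 0.001 | identical counts in all samples |
| `f_low` | 0.22 | weakly expressed genes (mean CPM ≤ 1 at scale) |

The structural fractions mirror the observed composition of
whole-transcriptome matrices (roughly a third unexpressed, a tenth partial,
a fifth weakly expressed, a trace of constant genes), so every
preprocessing filter is exercised. Partial genes sit in the dropout regime
(means ~2–3 counts, log-normal(0.7, 0.7)): partial expression in real data
arises from low abundance, and this keeps the few Wilcoxon survivors below
the CPM cutoff at transcriptome scale, so the retained set is dominated by
the $\phi = 0.09$ core and its post-preprocessing BCV lands near 0.30. DEG
labels are drawn among the expressed core; truth counts are exact by
construction (`round(n_genes * deg_proportion / 2)` up and the same number
down). A single `set.seed(config$seed)` at generator entry makes the whole
matrix reproducible; a per-gene counter-split stream was considered and
dropped because base R has no counter-based generator, at the cost of
gene-subset reproducibility.

**Random-effect injection.** `inject_random_effects()` adds one independent
$N(\mathrm{mean}, \mathrm{sdnd}^2)$ draw per matrix entry, clamps negatives
to zero, and rounds half-away-from-zero to the nearest integer (ties at .5
have probability zero under normal draws, so the tie rule is
inconsequential). Per-entry granularity is an interpretation — per-gene or
per-sample addition would not create the partial-expression degradation the
injected datasets are supposed to show. The studied sdnd grid is
100–3,000, and the default injection means per replicate count
(2.028, 9.937, 7.158, −3.429, −1.615) were estimated from public
transcriptome series matched by replicate number; they ship as defaults so
no download is needed, and `estimate_random_effect_mean()` (average over
genes of the between-condition difference in replicate means, computed on a
preprocessed matrix) can regenerate the estimate from any dataset.

**What the generator does not emulate.** It draws NB counts around
log-normal baselines with a single core dispersion. It does not reproduce a
full mean–dispersion trend, regulatory-program structure, or the exact gene
composition of any real simulator's output. One visible consequence: the
common-dispersion BCV of the *unfiltered* synthetic matrix sits near 0.32
rather than the ~0.5 seen on real whole-transcriptome matrices, because the
removed gene classes here are low-count and carry almost no likelihood
weight. Passing tests on these fixtures therefore demonstrate correctness
of the pipeline's behavior and calibration, not distributional identity
with real data.

## Benchmarking

`confusion()` scores a call set against truth with genes filtered out
upstream counted as negative calls, `de_metrics()` reports precision,
recall and accuracy (precision at zero positive calls is 1 when there is
nothing to find and 0 otherwise — a corner real grids do not hit), and
`benchmark_grid()` runs caller functions over a replicates ×
DEG-proportion × sdnd grid with per-seed simulation and optional injection.
Bonferroni calls are always a subset of BH calls at equal $\alpha$, so
Bonferroni recall can never exceed BH recall on the same fits.

## Problem sizes and expected results

The packaged checks use 5,000-gene matrices: the preprocessing-loss grid
(replicates {2, 4, 6, 10} × DEG proportions {0.1, 0.2, 0.3} × 3 seeds)
keeps the median true-DEG loss around 2% — comfortably under the 6.7%
bound it is checked against; the fixed-effect BCV check stays near 0.31
(bound 0.35); and on the random-effects benchmark (sdnd {300, 1200}, 30%
DEGs, 4 replicates, 10 seeds) the mixed model's mean accuracy is at or
above the fixed-effects NB GLM baseline's. `scripts/acceptance.R`
recomputes the first two quantities from scratch for any seed.

## Known limitations

- Pairwise two-level designs only; no longitudinal or multi-factor fixed
  designs, no likelihood-ratio tests, no shrunken fold changes.
- One random-intercept term; crossed or nested random structures are not
  supported.
- The common-dispersion BCV is a dataset-level summary, not a per-gene
  estimate.
- The Wilcoxon filter's pooled reading removes all partially expressed
  genes at 2–3 replicates per condition (see above).
- External callers are scored from their exported call tables; this package
  does not wrap them.
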
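---
title: "Functionally informed kernel-based rare-variant association tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functionally informed kernel-based rare-variant association tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fikat)
```

## The model

fikat tests whether the rare variants of a gene jointly influence a
quantitative trait. For $n$ individuals with covariates $X$ ($n \times q$,
intercept included) and mean-centered minor-allele dosages $G$
($n \times m$) of the gene's qualifying variants, the phenotype is modeled
as

$$ y \sim N\!\left(X\alpha,\; \sigma^2_e I_n + \sigma^2_g K\right),
   \qquad K = \phi(G)\,\phi(G)^\top, $$

and the association test is the one-sided variance-component test of
$H_0: \sigma^2_g = 0$ against $\sigma^2_g > 0$. Everything biological —
which variants enter, how they are weighted, whether they are collapsed —
lives in the factor $\phi(G)$, an $n \times g$ matrix. Burden
(collapsing) tests are the special case $g = 1$, so burden and kernel
tests share one statistical machine.

### Variant weights and qualifying sets

Variants enter in four categories, each with a weight $w_i \in [0, 1]$
derived from effect predictions supplied as input tables:

* **pLOF** (stop gained/lost, start lost, frameshift, splice
  donor/acceptor): always qualifying, weight 1.
* **missense**: impact score $w_i = ((1 - s_{\mathrm{SIFT}}) +
  s_{\mathrm{PolyPhen}})/2$, the mean predicted probability of being
  deleterious. Qualifying when $w_i \ge 0.8$, or when another variant at
  the same amino-acid position of the gene reaches 0.8 (position rescue).
  Both scores must be present; rows missing either are dropped with a
  warning, since an impact score from one predictor alone would not be
  comparable to the two-predictor average.
* **splice**: weight = max of the four SpliceAI delta scores; qualifying
  at $\ge 0.1$.
* **RBP binding**: effect vector $v_{ij} = p_{ij,\mathrm{alt}} -
  p_{ij,\mathrm{ref}}$ over $R$ RBP model outputs (default $R = 8$);
  weight = $\max_j |v_{ij}|$, qualifying at $\ge 0.25$.

### Kernel designs

With $W^{1/2} = \mathrm{diag}(\sqrt{w})$ and $G_c$ the column-centered
dosages:

* `collapse_max` — per individual, the largest weight among carried
  variants (0 for non-carriers). Assumes effects share a direction and
  the strongest variant dominates.
* `phi_linear` — $\phi = G_c W^{1/2}$: independent per-variant effects
  (the weighted linear kernel).
* `phi_local_collapse` — $\phi = G_c W^{1/2} C$, where $C$ sums variants
  hitting the same amino-acid position into one column. With all
  positions distinct it reduces exactly to `phi_linear` (a tested
  invariant).
* `phi_rbp` — $\phi = G_c W^{1/2} L$ with $LL^\top = S = Q \circ R$:
  $Q$ holds cosine similarities of the RBP effect vectors (directional:
  opposing predicted effects are anti-similar), $R$ the Gaussian
  positional kernel $\exp(-\gamma d^2)$ with
  $\gamma = -\log(0.5)/50^2$, so two variants 50 bp apart have
  positional similarity exactly 0.5 and 100 bp gives $0.5^4 = 0.0625$.

For joint category + pLOF tests, the centered pLOF burden is appended as
one extra column (`concat_plof`); a variant annotated both splice and
pLOF counts once, on the pLOF side.

## The two-stage sLRT

The score test is fast and locally most powerful, but the restricted
likelihood-ratio test (RLRT) has more power at the large effect sizes
rare-variant studies care about. fikat therefore runs the score test
genome-wide and computes the RLRT only when a category's score test
falls below the nominal trigger $t = 0.1$ (the sLRT). Under the null
only a fraction $t$ of genes trigger, so the expensive stage runs on
roughly one gene in ten.

* **Score test.** $Q = r^\top \phi \phi^\top r / \hat\sigma^2_e$ with $r$
  the OLS null-model residuals and $\hat\sigma^2_e = r^\top r/(n-q)$. Its
  null law is $\sum_s \lambda_s \chi^2_1$ over the eigenvalues of
  $\phi^\top P \phi$ ($P$ the projection off the covariate space).
* **Tail probabilities.** Davies' characteristic-function inversion
  (via `mgcv::psum.chisq`), run at accuracy $10^{-7}$ with up to $10^6$
  integration terms whenever the p-value is below 0.1; above that a fast
  pass with absolute error $\le 2\times10^{-5}$ is kept, since no
  downstream decision can be affected there. A single eigenvalue is
  evaluated with the exact $\chi^2_1$ survival function. Invalid or
  non-positive Davies results fall back to a Kuonen saddlepoint
  approximation.
* **RLRT.** REML fits of null and alternative reduce, via the spectral
  decomposition of $\phi^\top P \phi$, to a one-dimensional profile
  search over the variance ratio $h = \sigma^2_g/\sigma^2_e$ (81-point
  log grid on $[10^{-8}, 10^8]/\mu_{\max}$, Brent refinement). The
  statistic $2(\ell_1 - \ell_0)$ is exactly 0 whenever the estimate hits
  the boundary, which happens for over half of null data sets.
* **Exact null sampling.** Because the RLRT null is a nonstandard
  boundary mixture, p-values come from simulation: the
  Crainiceanu–Ruppert construction draws exact finite-sample null
  statistics from the eigenvalues alone — no phenotype refits. Each draw
  maximizes the closed-form profiled criterion over a $\lambda$ grid
  ($\{0\} \cup$ 128 log-spaced points spanning
  $[10^{-5}, 10^5]/\mu_{\max}$), then sharpens the per-draw optimum with
  24 golden-section iterations on $\log\lambda$ (bracket width
  $\approx$ one grid step, so the refinement error in $\log\lambda$ is
  below $10^{-4}$). The sampler is validated against direct REML-fit
  null simulation by two-sample Kolmogorov–Smirnov in the test suite.
* **Pooled parametric null.** 100 statistics per triggered gene are
  pooled within each (phenotype × category × test-design) group and
  fitted with $\pi \chi^2_0 + (1-\pi)\, a\, \chi^2_d$: $\hat\pi$ is the
  observed zero fraction (statistics $\le 10^{-8}$), and $(a, d)$
  minimize squared differences between log empirical and log model
  survival over the top-decile order statistics. The exact weighting of
  this log-quantile regression is a design choice; the plain
  least-squares variant used here recovers a known generator
  ($0.6\,\delta_0 + 0.4\cdot 2\chi^2_1$, $10^5$ draws) to within
  $\pm 0.01$ on $\pi$ and $\pm 0.15$ on $a$ and $d$ in the acceptance
  suite. Pooling is justified by the mixture identity: with equal
  per-gene sample counts, the pooled p-value at any statistic equals the
  mean of the per-gene p-values, so Bonferroni control is unchanged.
  P-values from gene-specific versus pooled mixtures agree with
  $r^2(\log_{10} p) \ge 0.98$ on a 200-gene synthetic null study.
* **Cauchy combination.** The category-only and category+pLOF p-values
  are combined per track with the CCT,
  $T = \sum_i w_i \tan((0.5 - p_i)\pi)$, which is valid under
  dependence. Inputs below $10^{-6}$ use the stable tail form
  $1/(\pi p)$, making the combination exact for tiny p-values.

Conditional tests (for significant genes) add the conditioning dosage to
the covariates, resample 250,000 gene-specific null statistics, and fit
a gene-specific mixture — the paranoid check that a single nearby common
variant does not explain the signal.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maf_max` | 0.001 | study-wide MAF inclusion bound (fraction) |
| `hwe_min` | 1e-5 | exact HWE p below this excludes the variant |
| `call_rate_min` | 0.9 | minimum genotyping rate |
| missense / splice / rbp thresholds | 0.8 / 0.1 / 0.25 | qualifying-variant cutoffs |
| `slrt_t` | 0.1 | sLRT trigger threshold on the score p |
| `n_null_per_gene` | 100 | simulated RLRT null statistics per triggered gene |
| `n_null_conditional` | 250000 | gene-specific null statistics for conditional tests |
| `gamma` | $-\log(0.5)/50^2$ bp$^{-2}$ | positional kernel bandwidth |
| `alpha` | 0.05 | FWER level; Bonferroni over all emitted tests |

Boundary conventions: a variant exactly at `maf_max`, at the HWE
threshold, or at a qualifying threshold is retained ("at least" /
"below" semantics throughout). The Bonferroni denominator is the total
number of finalized p-values emitted across phenotypes, categories and
test types.

## Numerical choices

* Missing dosages are mean-imputed per variant before kernel
  construction; the call-rate filter bounds the impact. Imputed
  fractional dosages never create burden carriers.
* Burden and concatenated pLOF columns are mean-centered before testing,
  like the dosage columns; uncentered columns would shift the null
  eigenvalues.
* Eigenvalues below $10^{-10} \cdot \lambda_{\max}$ are discarded in
  both the score test and the RLRT sampler.
* The Cholesky factor of $S$ falls back to a ridge of
  $10^{-8}\,\mathrm{tr}(S)/m$, escalated tenfold up to $10^{-4}$, before
  erroring — $S$ is singular when variants share position and effect
  vector.
* Per-gene seeds are derived from the master seed by a string hash of
  (gene, test label), so genome-wide runs are reproducible and
  independent of gene processing order.
* P-values are floored at $10^{-300}$ to keep logs finite.

## The simulator and what it does (not) show

`sim_spec()`/`sim_study()` generate genotypes with a log-uniform MAF law
on $[1/(2n), \mathrm{maf}_{\max}]$ — the singleton-heavy spectrum of
sequenced rare variation; at biobank scale roughly half of the simulated
variants are singletons, and the exact fraction is emergent rather than
forced. Annotations are generated at the predictor level (SIFT/PolyPhen,
delta scores, binding probabilities), so simulated data exercise the
same annotation path as real tables, including dual splice/pLOF
annotation and amino-acid position sharing (default 20% of missense
variants share a position). Phenotypes follow
$y = X\alpha + G\beta + \varepsilon$ with configurable causal fraction,
sign mixture, and gene-level variance explained.

The simulator deliberately omits linkage disequilibrium, population
structure and relatedness. Passing calibration and FWER tests on this
output therefore shows the statistical machinery is correct under its own
assumptions; it does not show robustness to confounding — on real data
that is the job of the covariates (principal components, ancestry
scores) and of ancestry-based variant pruning, whose Fisher-exact
machinery is tested separately.

### Problem sizes used in the checks

The test suite runs at desk scale, chosen so every property is decided
by its statistical tolerance rather than by runtime: score calibration
at $n = 500$, $g = 5$, 1000 replicates; sampler equivalence at
$n = 100$, $K = 5$, 2000 draws; pooled-null agreement on 200 genes;
FWER on 20 seeds of a 2,000-gene × 3-phenotype null study at $n = 300$.
Because the biobank-scale MAF bound of 0.1% leaves at most one expected
carrier per variant at these sample sizes, the simulation studies use
`maf_max = 0.02` — still rare, but polymorphic at desk-scale $n$ — while
the package default stays 0.001.

## Design notes

* The package exposes module-style functions rather than a single
  monolithic fitter because the object of interest is a genome-wide
  procedure; the core per-gene test still follows the classic modelling
  idiom (`slrt()`, `fit_lmm_reml()`, `fit_null_mixture()` return classed
  objects with print methods).
* MAF is computed once on the full analysis sample and reused across
  phenotypes; per-phenotype recomputation would change qualifying sets
  between phenotypes for no inferential gain.
* "Selectively missing" in ancestry pruning means zero genotyped alleles
  in a population; no partial-missingness cutoff is applied.
* Allele counts (not genotype counts) enter the ancestry Fisher tests,
  matching the allele-frequency framing of the pruning rule.
* Variants qualifying in several categories are kept in each category's
  set; deduplication happens only inside joint pLOF-combined tests.
* Genes sharing exons are tested independently; identical variant sets
  can be flagged post hoc rather than merged.
* No MAF-based re-weighting of variants is performed anywhere — weights
  come from effect predictions only.

## Known limitations

* Quantitative traits only; no binary-trait (logistic / SPA) branch.
* Unrelated samples are assumed (no kinship random effect).
* VCF/BGEN ingestion is out of scope; PLINK bed/bim/fam and TSV tables
  are the interfaces.
* The RLRT cap on kernel columns is practical, not fundamental: the
  sampler cost grows with the number of nonzero eigenvalues.

## A worked example

```{r example}
spec <- sim_spec(n = 400, n_genes = 20, m_per_gene = 8, maf_max = 0.02)
study <- sim_study(spec, seed = 11, n_phenotypes = 1)
res <- run_study(study, study_config(maf_max = 0.02, master_seed = 11))
head(res[order(res$final_p),
         c("gene_id", "category", "test_type", "score_p", "final_p",
           "lrt_triggered")])
attr(res, "cutoff")
```
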
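---
title: "Methods: locus-level multivariable MR with cis-eQTL summary statistics"
author: "cismvmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-level multivariable MR with cis-eQTL summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cismvmr)
```

## The problem

GWAS have catalogued thousands of disease-associated variants but very few
causal *genes*. Multivariable Mendelian randomization (MVMR) with cis-eQTL
instruments offers a summary-statistics route to causal gene discovery: in a
locus of $p$ genes, regress the SNP–disease associations $\hat\alpha$
($m$-vector) on the SNP–expression associations $\hat B$ ($m \times p$),
using cis-eQTLs as instruments. The regression coefficient $\theta$ is the
vector of direct causal effects of the $p$ expression traits on disease
risk, with the other genes' effects held fixed.

Done naively this fails in several distinct ways, each addressed by a
component of this package:

1. **Block missingness.** Public cis-eQTL files report SNP–gene pairs only
   within ±1 Mb of each gene's TSS, so the union instrument set of a
   multi-gene locus has a banded missing pattern. (`mv_impute()` and
   friends.)
2. **Weak-instrument (measurement-error) bias.** The design matrix is
   itself estimated; regressing on it attenuates and distorts $\theta$.
   (`mrbee()`.)
3. **Correlated horizontal pleiotropy.** Instruments in LD with causal
   SNPs outside the instrument set confound the fit. (`chp_filter()`,
   pleiotropy pruning.)
4. **Estimated LD.** The LD matrix comes from a reference panel of a few
   hundred to a few thousand individuals; treating it as known inflates
   test statistics. (`corrected_inference()`.)
5. **Gene-dense loci.** Thirty genes in a 2 Mb window defeat a direct
   $p$-dimensional fit; screening selects the genes with direct evidence
   first. (`gscreen()`.)

All model fitting operates on the z-score scale ($\hat\beta/\mathrm{se}$),
where each summary statistic has unit error variance and the cross-gene
error covariance is a correlation matrix $\Sigma$.

## The estimator

With a regularized LD matrix $R_\lambda$ and error correlation $\Sigma$,
the bias-corrected estimator is

$$\hat\theta = (\hat B^\top R_\lambda^{-1}\hat B - m\Sigma)^{-1}
  \hat B^\top R_\lambda^{-1}\hat\alpha .$$

Internally everything is whitened by the symmetric root of
$R_\lambda^{-1}$, turning the problem into bias-corrected ordinary least
squares with independent errors; $m\Sigma$ is exactly the expected noise
Gram matrix of the whitened design, which is why subtracting it de-biases
the bread. The covariance of $\hat\theta$ uses a sandwich whose
estimating-function contributions are $x_j \hat e_j + \Sigma\hat\theta$;
the second term restores mean zero under measurement error in $x_j$. We do
not claim finite-sample exactness for this covariance; it is validated
through its calibration behaviour in simulation (see the test suite).

**Effective instrument counts.** $m\Sigma$ presumes every entry of
$\hat B$ carries fresh estimation noise. After imputation (or
zero-filling), unobserved entries carry little or none, and subtracting
the full $m\Sigma$ can push the bread matrix negative — catastrophically
so in practice. `bias_scale_matrix()` therefore computes effective counts
$N_{kl} = \sum_{i \in obs_k}\sum_{j \in obs_l} (R^{-1})_{ij}R_{ij}$ (equal
to $m$ for complete data, the co-observation count when $R = I$) and
$N \circ \Sigma$ replaces $m\Sigma$. This is the package's own refinement;
it reduces exactly to the textbook estimator on complete data.

**Degenerate bread matrices.** When instruments are very weak or $\Sigma$
is estimated from few SNPs, $\hat B^\top R_\lambda^{-1}\hat B - m\Sigma$
can still fail to be positive definite. Rather than flooring eigenvalues
(which produces arbitrarily large, unstable estimates in the floored
directions), the correction is *capped*: the largest $\gamma \in [0,1]$ is
found by bisection such that $G - \gamma m\Sigma$ keeps a positive margin
(5% of the average per-instrument information). The result is a partially
corrected — hence slightly attenuated — but finite-variance estimate, and
the condition is reported with a warning and the `bread_repaired` flag.

**Estimating $\Sigma$.** SNP rows whose squared z-scores are all below the
0.95 quantile of $\chi^2_1$ are treated as pure noise and their sample
correlation estimates $\Sigma$ ("insignificant effect estimates" device).
Within a single locus only a few dozen such complete rows may exist, and a
raw correlation from 25 rows injects more error into the bread correction
than it removes. `estimate_bias_matrix()` therefore applies Ledoit–Wolf
shrinkage towards the identity with intensity
$w = \min\!\big(1, \sum_{k\neq l}\widehat{\mathrm{Var}}(r_{kl}) \big/
\sum_{k\neq l} r_{kl}^2\big)$; the estimate interpolates between the
sample correlation (many rows) and the identity (few rows).

## Inference under an estimated LD matrix

If LD is estimated from $n$ reference individuals, modelling
$W \sim \text{Wishart}_m(n, R/n)$, the usual residual degrees of freedom
are mis-specified and the naive t-statistic $L = \hat\theta/\widehat{SE}$
over-rejects. The corrected statistic is

$$\tilde L = \sqrt{\tfrac{n - m + 1}{n}}\, L ,$$

compared to a t distribution with $m-1$ degrees of freedom ($m$ =
instruments used; the multivariable df is not settled, so `"m-1"` is the
default with `"m-p"` available).

A subtlety uncovered while validating this correction, and worth stating
plainly: the correction factor is calibrated for the *studentized* GLS
t-statistic, whose standard error uses the residual variance estimated on
the whitened scale — that is the form whose implicit assumption
"$(m-1)\widehat{\mathrm{Var}}/\mathrm{Var} \sim \chi^2_{m-1}$" the
derivation replaces. Standard summary-data IVW software instead fixes the
residual variance at 1 on the z-score scale (the fixed-effect convention).
Both moment analysis and simulation show:

* the fixed-effect statistic at $n = 500$, $m' \approx 200$ pruned
  instruments rejects a true null at $\approx 0.22$–$0.26$ instead of
  0.05, reproducing the published inflation level;
* rescaling that *fixed-effect* statistic by $\sqrt{(n-m+1)/n}$
  under-corrects (Type-I error $\approx 0.12$ at $n = 500$);
* rescaling the *studentized* statistic is calibrated at every panel size
  (asymptotically exactly: the product of the variance ratios is
  $\tfrac{(n-1)(n-m-1)(n-m+1)}{n^2(n-m)(n-m-3)} \cdot n \to 1$).

`run_inflation_experiment()` therefore reports the standard statistic
under the fixed-effect convention (what a practitioner's IVW software
computes) and the corrected statistic built from the studentized form
(what the correction is valid for). `ivw_fit()` exposes both conventions
via `resid_var`.

## Imputation of the block-missing design

Four methods are provided. `zero_impute()` fills unobserved cells with 0
(their marginal null expectation outside the cis window).
`soft_impute()` is iterative singular-value soft-thresholding holding
observed entries fixed. `normal_impute()` fills each gene's missing
z-scores with their conditional mean under $z \sim N(0,R)$.

`mv_impute()` is the LD- and noise-aware variant: it whitens with
$\Theta^{1/2}$ ($\Theta = R_\lambda^{-1}$), deflates the total
singular-value mass of the zero-filled start by the estimation-noise share
$a = 1 - \sum_k \eta_k / \sum_k d_k$, then runs the soft-threshold
iteration on the whitened scale and de-whitens. Numerical choices worth
recording:

* $\eta_k$ are the *noise singular values*: the square roots of the
  eigenvalues of the noise Gram matrix $N \circ \Sigma$. A Gram matrix's
  eigenvalues live on the squared singular-value scale, so reading
  $\eta_k$ as its raw eigenvalues would make $\sum\eta_k/\sum d_k$ scale
  like $\sqrt{m}$ and force $a \le 0$ for any z-scale input; the square
  root is the dimensionally coherent reading, with $a$ then estimating
  the fraction of singular-value mass attributable to signal.
* Deflation initializes the *missing* entries only; observed (whitened)
  entries are reset to their raw values each iteration. A fully observed
  matrix therefore passes through unchanged. Preserving observed data
  element-wise after de-whitening is only possible for $\Theta = I$
  (whitening mixes rows); the preservation contract is exact on the
  whitened scale.
* $a \le 0$ (noise mass exceeding total signal) falls back to zero
  imputation with a warning.
* $\lambda$ defaults to the minimizer of held-out error on 10% of
  re-masked observed entries (seedable); $\Theta^{1/2}$ is the symmetric
  eigendecomposition root, so SNP ordering is irrelevant; convergence is
  declared at a Frobenius change below $10^{-6}\|B^{(0)}\|_F$, capped at
  500 iterations.

## Screening and networks

`gscreen()` minimizes a Gaussian-kernel convolution-smoothed absolute
loss ($\ell_h(u) = \mathbb{E}|u + hZ|$, whose gradient is
$2\Phi(u/h)-1$; $h \to 0$ recovers the median check loss) plus the SCAD
penalty ($a = 3.7$), by proximal-gradient steps with local linear
approximation of the penalty and warm-started continuation along the
$\lambda$ grid. The hyper-parameters minimize
$\mathrm{BIC} = \log(\bar\ell) + |A|\log(m)/m$. The bandwidth default is
$\max(0.05, \sqrt{p/m})$ on the outcome scale. As a *screen* it is
deliberately inclusion-biased: simulations show it retains all truly
causal genes in well over 80% of replicates while occasionally admitting
one spurious gene, which the downstream MRBEE fit then handles; genes
screened out are still reported, flagged, so output is complete.

`fit_network()` estimates a sparse conditional-dependence network among
the locus's gene (and outcome) z-score columns: Spearman correlation with
the $2\sin(\pi\rho_s/6)$ Fisher-consistency transform, then an own
implementation of the graphical lasso (blockwise coordinate descent) over
a penalty grid. BIC is evaluated on a *relaxed refit* — the constrained
MLE on each candidate edge set (zero penalty on support, prohibitive off
it) — because BIC scored on the shrunken glasso estimate is known to
over-select; partial correlations below 0.01 are treated as zero. The
outcome column enters as an ordinary node by default
(`penalize_outcome = TRUE`); edge orientation is not attempted.

## The synthetic-data generators

`sim_config()` fixes the study conditions: 500 eQTLs with AR(1) LD at
$\rho = 0.5$ and a panel-size grid $\{500, 1000, 3000, 5000\}$ for the
inflation experiment (1000 replicates, pruning at $r^2 < 0.3^2$, nominal
level 0.05); 9 genes and 526 cis-eQTLs spread so that the ±1 Mb cis
windows produce a banded mask with a small complete-case core for the
imputation experiment. The printed pruning thresholds of the underlying
analyses are read as flattened superscripts ($0.3^2$, $0.5^2$, $0.7^2$ —
the conventional cut-offs); the literal values remain available as plain
arguments.

Where the source experiments used in-house individual-level data that is
not public, the generator substitutes a synthetic truth chosen once:
eQTL signal carried by ~30% of SNP rows (signals cluster near the TSS)
with z-scale 2 at signal SNPs, mixing a rank-3 shared (co-regulation)
component with 30% gene-specific variance — a purely low-rank signal
would make the gene columns collinear and the MVMR estimand
unidentifiable, which real loci avoid through gene-specific eQTLs. The
causal effect used in power comparisons is 0.3 on the standardized scale.

What the generators deliberately do *not* emulate: allele-frequency
structure, genome-scale LD beyond a locus, sample overlap between eQTL
and outcome GWAS (error cross-covariance is taken as zero), ancestry
mismatch between GWAS and panel, and trans-eQTLs. Passing tests
demonstrate internal correctness and the claimed statistical behaviour
under these stylized conditions, not performance on any particular real
dataset.

## Pipeline order and degenerate inputs

`run_pipeline()` processes each chromosome file and locus as: harmonize →
group genes into loci (transitive closure of "share an eQTL with
$p < 0.001$", kept if any union-set SNP has outcome $p < 0.005$) → impute
→ estimate $\Sigma$ → joint instrument test (Eq.-style $\chi^2_p$ screen;
locus preset $5\times10^{-3}$, genome-wide preset $5\times10^{-8}$) →
correlated-pleiotropy filter (drop instruments with $r^2 > 0.5^2$ to an
outside SNP within a 2 Mb flank; the narrower 1 Mb flank used in some
applications is a flag away) → LD prune ($r^2 < 0.7^2$) and shrink the LD
matrix to positive definiteness (minimal $s$ towards the identity,
eigenvalue floor $10^{-3}$) → screen genes → MRBEE with iterative
pleiotropy pruning (residual $\chi^2_1$ test, variance
$1 + \hat\theta^\top\Sigma\hat\theta$, threshold 0.05, at most 30
rounds) → panel-corrected inference → locus $R^2$ and Pratt indices.
Screening runs after the CHP filter so that the screen sees the
instruments the final fit will use.

Per-locus failures (no instruments surviving a filter, fewer than $p+1$
instruments, zero outcome variance) are logged with a reason and skipped;
they never abort the run. Duplicate SNP–gene rows are an error rather
than averaged — silent aggregation hides upstream problems. Coordinates
are 1-based with closed windows ($|pos - tss| \le$ window), matching GWAS
summary-file conventions. Strand-ambiguous (A/T, C/G) SNPs are kept under
exact-label matching by default, with a flag to drop them; allele
frequencies are not used anywhere in the model, so frequency-based
resolution is omitted.

## Fit statistics

The locus $R^2$ is $1 - RSS/TSS$ on the whitened scale with uncentered
moments (the regression has no intercept), and each gene's Pratt index is
$\tilde\theta_k r_k$ (standardized coefficient × marginal correlation).
With a least-squares $\hat\theta$ the Pratt indices sum to the $R^2$
exactly — for any design, by the normal equations; with the
bias-corrected $\hat\theta$ the identity is approximate. Both are
reported as *imperfect, interpretable* summaries: the locus $R^2$ equals
the heritability explained only when power to detect every causal eQTL is
1, and Pratt values slightly outside $[0, 1]$ can occur for unstable
fits.

Across loci, gene-level p-values are reported raw, with
`adjust_run_pvalues()` offering Bonferroni over the genes actually tested
(no procedure is prescribed by the underlying method).

## Problem sizes

The bundled experiments run at their study scale: 1000 replicates for the
inflation experiment at each of four panel sizes (a few minutes on one
core) and 200+ replicates of the 526 × 9 imputation experiment. The
acceptance script reruns the inflation experiment at
$df = 500$ from scratch; module tests use smaller instances chosen to
exercise the same code paths against brute-force oracles.

## Known limitations

* The sandwich covariance of MRBEE is a large-$m$ approximation; its
  finite-$m$ behaviour is only validated through calibration simulations.
* The $\sqrt{(n-m+1)/n}$ correction assumes the panel-estimated LD matrix
  is Wishart — reasonable for a homogeneous panel, wrong across
  ancestries; ancestry mismatch between GWAS and panel is out of scope.
* Imputation assumes approximate low-rank structure of the locus design;
  a locus of entirely independent genes gains nothing from it (and loses
  nothing: $\lambda$ selection degrades gracefully to zero-like fills).
* `gscreen()` support recovery degrades when true effects cancel through
  strongly correlated genes, and the BIC grid is finite.
* Only cis-instruments are modelled; trans-eQTLs, splicing and protein
  QTLs are out of scope.
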
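---
title: "Mixed-model gene set analysis: model, calibration, and design notes"
author: "mmgsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model gene set analysis: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgsa)
```

## The problem

A case-control expression study asks which *gene sets* — predefined groups
of functionally related genes, e.g. Gene Ontology biological-process
categories — are jointly differentially expressed between patients and
healthy controls. Testing sets rather than single genes pools weak but
concordant signals across related genes, which matters in small cohorts
(a dozen arrays) where almost no single gene survives multiplicity
correction. This is a *self-contained* set test: each set is judged against
the null of no group difference among its own genes, not competitively
against the rest of the genome.

## The model

For a set of $G$ genes measured on $n$ samples, the long-format outcome is
the log2 expression $y_{gs}$ of gene $g$ in sample $s$:

$$
y_{gs} = \mu + \beta\, \mathrm{I}[\text{group}(s) = \text{case}]
        + b_{\text{batch}(s)} + u_{\text{subject}(s)}
        + \sum_{k=1}^{K} a_{sk} E_{gk} + \varepsilon_{gs}
$$

with independent random terms
$b \sim N(0,\sigma_b^2)$ over batches,
$u \sim N(0,\sigma_u^2)$ over subjects,
$a_{sk} \sim N(0,\sigma_k^2)$ over samples and components, and
$\varepsilon \sim N(0,\sigma^2)$. The loadings $E_{gk}$ are the leading
eigenvectors of the within-set gene-gene correlation matrix, so the induced
per-sample covariance across genes is

$$
\Sigma = \sigma_u^2 J + \sum_k \sigma_k^2 E_k E_k^\top + \sigma^2 I ,
$$

a factor-analytic structure that absorbs heterogeneous co-expression inside
the set instead of letting it contaminate the group test. The screened
quantity is $\beta$, the common case-minus-control shift (log2 scale,
control as reference, so $\beta > 0$ means "up" in cases).

Two estimation details:

* **Correlation on group-centered residuals.** The correlation matrix
  feeding the eigendecomposition is computed after subtracting each gene's
  group-specific mean (`center_by_group()`). Without this, a true group
  effect would itself masquerade as a strong common factor and be absorbed
  away, costing power.
* **REML variance components, closed-form covariance algebra.** Because the
  eigenvector loadings are orthonormal, $\Sigma^{-1}$ and $\log|\Sigma|$
  have closed forms, and the batch/subject terms are a low-rank update
  handled by Woodbury identities; a likelihood evaluation costs
  $O(GnK + n_w^3)$ with $n_w$ the number of batch plus subject levels,
  never forming an $N \times N$ matrix. Gradients of the REML/ML objective
  are analytic (trace identities on the same structure), and variances are
  optimized on the log scale by L-BFGS-B with a floor (default $10^{-8}$);
  boundary fits are legitimate and mean the component is absent.

## Tests of the group effect

* **LRT (default).** Both nested models ($\beta$ free vs $\beta = 0$) are
  refit by full maximum likelihood and $2\,\Delta\ell$ is referred to
  $\chi^2_1$. This avoids choosing a denominator-degrees-of-freedom
  approximation, at the price of relying on asymptotics in the number of
  subjects.
* **Wald.** $\hat\beta / \mathrm{se}(\hat\beta)$ from the REML fit,
  referred to a $t$ distribution with *between-within* denominator degrees
  of freedom, (#subjects $-$ 2). The group contrast is a between-subject
  comparison, so the subject count — not the observation count $G \times n$
  — is the honest sample size; this is also the convention of the classic
  mixed-model software this family of analyses grew up in. With one gene,
  one batch and one sample per subject the Wald test *is* the pooled
  two-sample t-test, exactly — a reduction the test suite verifies to
  $10^{-6}$ and tighter.

Gene-level follow-up tables (`test_gene()`, `table_for_set()`) use the
single-gene reduction of the same model with the Wald test, keeping the
screen and its follow-up internally consistent; the per-gene inclusion
threshold (default $\alpha = 0.05$, unadjusted) is a reporting convention
for the follow-up table, not an inference claim.

## Choices made where the design was open

* **Number of components $K$.** $K = \min(K_{\max}, K_{\text{signal}},
  \mathrm{rank})$ with $K_{\max} = 5$ by default, where $K_{\text{signal}}$
  counts eigenvalues above the Marchenko-Pastur noise edge
  $(1 + \sqrt{G/\mathrm{df}})^2$ of a sample correlation matrix with
  $\mathrm{df} = n - 2$ residual degrees of freedom. A cumulative
  explained-variance rule was evaluated first and rejected: at
  $G = 20$ genes and $\sim 38$ df the noise bulk extends to eigenvalue
  $\approx 2.9$, so such rules retain directions indistinguishable from
  sampling noise, and conditioning on them measurably anti-conserves the
  group test. The random-matrix edge is the standard signal/noise cutoff
  for sample correlation spectra.
* **Per-component vs shared factor variances.** Both are implemented
  (`model_spec(factor_variance=)`): per-component gives each retained
  eigenvector its own $\sigma_k^2$ (the default); `"shared"` ties them to
  the eigenvalue profile, $\sigma_k^2 = \sigma_c^2 \lambda_k$, with one
  free parameter. In the calibration studies below the two behave
  identically; the underlying method family does not pin this choice down,
  so it is deliberately explicit.
* **FDR family.** Benjamini-Hochberg adjustment is computed across *every*
  set screened in a run — a displayed top table must never shrink the
  family.
* **Ties and determinism.** Screens sort by raw p-value with
  lexicographic set-name tie-breaks; a run's outputs are a pure function of
  its inputs and config, so re-running a manifest reproduces tables byte
  for byte.
* **Robustness over abort.** Zero-variance genes are dropped with a
  warning; a set whose fit fails is reported with `converged = FALSE` and
  `NA` p-values. One pathological set cannot kill an 800-set screen.

## The synthetic-data generator

`simulate_dataset()` runs the model forward: orthonormal loadings drawn by
QR of a standard-normal matrix, per-sample factor scores, batch offsets
shared by all genes of a sample, subject effects, and i.i.d. residuals; a
configurable fraction of sets receives a uniform case shift $\delta$.
Defaults mirror a small two-group microarray cohort on the log2 scale:
8 cases vs 4 controls, two batches assigned round-robin (balancing groups
across batches), `batch_sd` 0.2, `subject_sd` 0.3, `residual_sd` 0.5, and
rank-2 factor structure with score SDs 1.8 and 1.2. Because the loadings
are orthonormal, a factor's per-gene contribution is its score SD divided
by $\sqrt{G}$; at 20 genes per set the defaults correspond to per-gene
co-expression of about 0.40 and 0.27 log2 units — a substantial share
(~35%) of per-gene variance, as in genuinely co-expressed modules, and
magnitudes typical of RMA-normalized array data. Gene sets are disjoint by construction;
overlapping sets are out of scope because the screen treats sets
independently.

What the generator does *not* emulate: probe-level noise, normalization
artifacts, heavy-tailed residuals, set overlap, or real co-expression
networks. Passing calibration tests on this generator therefore shows the
estimator is correct *under its own assumptions*; it does not certify
behavior on arbitrary real data.

`simulate_qpcr()` generates threshold-cycle confirmation data: per-sample
reference-gene Ct around 20 cycles, a target $\Delta$Ct with configurable
group shift (biological SD 0.5 cycles by default), and triplicate
technical jitter of 0.1 cycles. A shift of $-1$ cycle corresponds to a
twofold expression increase under the perfect-doubling assumption of the
$2^{-\Delta\Delta Ct}$ method.

## Calibration results the test suite computes

The acceptance tests (and `scripts/acceptance.R`) recompute, from scratch:
agreement of the fitter with a dense multivariate-normal likelihood oracle
on tiny instances (within $10^{-4}$ in log-likelihood); exact single-gene
reduction to the pooled t-test; type-I error of the set-level LRT on 1000
null sets at $n = 20$ per group; monotone power across
$\delta \in \{0, 0.25, 0.5\}$; realized false-discovery proportion of BH
screens of 200 sets with 10% non-null sets at $\delta = 1$ under the
default cohort; group-effect recovery bias at $n = 50$ per group;
exactness of the BH step-up; and the qPCR identities. Problem sizes were
chosen so each study pins its quantity with Monte-Carlo error well inside
the tolerance being checked while the whole suite stays desk-runnable.
The type-I study *documents a deliberate failure* (its rejection rate runs
near 0.11 against a nominal 0.05), and the FDR study inherits some of the
same sensitivity: see the first limitation below.

## Known limitations

* **Conditioning on an estimated eigenbasis anti-conserves the test at
  desk-scale cohorts.** This is the package's most important caveat, and
  the test suite measures rather than hides it. When the true loadings are
  supplied to the fitter, the group test holds its nominal size
  (simulated null size 0.04-0.06 at $n = 20$ per group). With loadings
  *estimated* from the same samples — the method as defined — the null
  size is ~0.11-0.13 at $n = 20$ per group and worse at 12 samples, and
  this is insensitive to the variance parameterization, the $K$ selection
  rule, and the choice of LRT vs Wald reference. The mechanism is not the
  eigenvalue estimates but the projection: the GLS gene-space weights
  $\hat\Sigma^{-1}\mathbf{1}$ rotate with the estimated eigenbasis from
  dataset to dataset, adding sampling variance to $\hat\beta$
  (Monte-Carlo sd 0.131 versus model-based se 0.105 in the
  $n = 20$/group study) that a fit conditioning on that basis cannot see.
  The effect shrinks with $n$ but is material in any cohort small enough
  to motivate set-level testing in the first place. Practical guidance:
  treat small-cohort set p-values as a ranking device; for calibrated
  per-set inference use `K_max = 0` (simulated null size 0.055-0.058),
  which sacrifices the co-expression adjustment; confirm top sets on
  independent data, as the qPCR module supports.
* **Subject/eigenbasis confounding in the variance split.** The subject
  term induces uniform gene-gene correlation, itself a rank-1 direction,
  so estimated eigencomponents partially absorb it. The *total* fitted
  covariance — and therefore $\hat\beta$, which recovery studies show
  unbiased — is preserved, but the labeled subject vs eigenvector variance
  components should not be interpreted individually when the leading
  eigenvector is close to the uniform direction.
* **Symbol-level matching.** Gene identifiers are matched case-sensitively
  after whitespace stripping, with no alias resolution; sets are
  intersected with the measured universe and dropped below `min_size`
  (default 5) before testing.
* **qPCR efficiency fixed at 2.** No standard-curve calibration,
  melt-curve QC, or multi-reference normalization.
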
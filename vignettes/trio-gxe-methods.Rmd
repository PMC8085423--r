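---
title: "Testing gene-environment interaction in case-parent trios: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene-environment interaction in case-parent trios: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triogxe)
```

## The design and the model

A case-parent trio consists of an affected child and both biological
parents. At a biallelic marker, the child's genotype can be compared with the
three *pseudo-controls*: the genotypes the child could have inherited from
its parents but did not. Each parent contributes each of its two alleles to
exactly one of the four ordered transmission combinations; removing one
instance equal to the observed case genotype leaves the three matched
pseudo-controls. Because case and pseudo-controls share the same parents,
any confounding that operates through ancestry (population stratification)
is matched away — the comparison is within-family by construction.

With additive dosage coding ($G \in \{0,1,2\}$ counts of the effect allele)
and a binary maternal exposure $E$, the conditional logistic model for the
probability that the case carries $G_0$ rather than one of its
pseudo-controls $G_1,G_2,G_3$ is

$$
P(Y_0 = 1 \mid \textstyle\sum_l Y_l = 1, \{G_l\}, E)
  = \frac{e^{\beta_G G_0 + \beta_{GE} G_0 E}}
         {\sum_{l=0}^{3} e^{\beta_G G_l + \beta_{GE} G_l E}} .
$$

$\beta_G$ is the per-allele log relative risk in unexposed trios and
$\beta_{GE}$ the log relative-risk difference attributable to the exposure;
the per-allele effect in exposed trios is $\beta_G + \beta_{GE}$. Two Wald
tests are provided: the 1 df test of $\beta_{GE} = 0$ (interaction only) and
the 2 df joint test of $\beta_G = \beta_{GE} = 0$, which is sensitive to a
main effect, an interaction, or both.

## Estimation by exposure-stratum factorization

The exposure is constant within a trio, so the conditional likelihood
factorizes over exposure strata. Fitting the gene-only model separately in
unexposed trios (estimate $\hat\beta_u$, variance $v_u$) and exposed trios
($\hat\beta_e$, $v_e$) gives the full model exactly:

$$
\hat\beta_G = \hat\beta_u,\qquad
\hat\beta_{GE} = \hat\beta_e - \hat\beta_u,\qquad
\mathrm{SE}^2_{GE} = v_u + v_e,\qquad
\mathrm{cov}(\hat\beta_G,\hat\beta_{GE}) = -v_u .
$$

This reproduces the closed-form efficiency of the genotypic TDT while
delivering the full $2\times 2$ covariance needed by the 2 df test and the
joint meta-analysis. The test suite verifies the factorization against a
direct two-parameter maximization of the conditional likelihood (agreement
to $10^{-6}$ in both coefficients on 1,000 random synthetic SNPs).

In the classical limit where every informative trio has exactly one
heterozygous parent, the stratum estimate reduces to $\ln(b/c)$ with
variance $1/b + 1/c$ for $b$ transmissions and $c$ non-transmissions, the
textbook TDT closed form.

### Numerical choices

Each stratum fit is a one-dimensional Newton-Raphson on a concave
log-likelihood aggregated over the 15 Mendelian-consistent
(mother, father, child) genotype categories: start at 0, convergence at
$|\text{score}| < 10^{-10}$, at most 50 iterations, step-halving when a
proposed step lowers the log-likelihood. One subtlety: near the optimum the
log-likelihood is flat to machine rounding, so a step is rejected only when
the decrease exceeds $10^{-10}(|\ell|+1)$; halving on *any* decrease can trap
the iteration on the floating-point plateau just above the score tolerance.
Estimates diverging past $|\beta| > 15$ are flagged as separation (e.g. the
effect allele always transmitted in a stratum) with the sign of divergence;
such SNPs propagate `NA` statistics and are reported, never dropped.
Extreme p-values are computed with the upper-tail chi-square directly, which
remains accurate far into the tail.

Trios uninformative at a SNP (all four transmission combinations identical)
contribute nothing and are excluded from `N_INFORMATIVE`. A trio whose
exposure is missing is excluded from that exposure's analysis only.
Dominant and recessive codings are available by recoding the pseudo-control
dosages before likelihood evaluation; additive is the default and the only
coding exercised by the acceptance suite.

## Quality control

Per-SNP QC follows standard trio-GWAS practice, with all thresholds strict
in the failing direction:

| filter | statistic | default fail condition |
|---|---|---|
| MAF | minor-allele frequency among founders (each parent once) | < 0.05 |
| MISS | missing calls / (3 × trios) | > 0.05 |
| MENDEL | inconsistent trios / fully genotyped trios | > 0.05 |
| HWE | exact test among founders | p < 1e-4 |
| INFO | imputation R² (imputed SNPs only) | < 0.3 |

The HWE test is the exact conditional test (probability of each heterozygote
count given the allele counts; two-sided by summing outcomes no more
probable than the observed), which is well defined at low counts where the
chi-square approximation is not. At SNPs that pass QC, any residual
Mendelian-inconsistent trio has its genotypes set missing at that SNP — the
trio is retained elsewhere — so pseudo-control construction is always
defined. This makes `apply_qc` idempotent.

## Meta-analysis

Per-study summary statistics are harmonized on (chromosome, position): the
first study carrying a SNP fixes the orientation; swapped alleles negate
both coefficients (the covariance is unchanged because both betas flip);
alleles matching only after strand complement are complemented first;
palindromic mismatches (A/T, C/G) cannot be resolved and are dropped. SNPs
present in a single study are carried through as single-study results.

The 1 df path is the scalar fixed-effect inverse-variance rule
$\hat\beta = \sum_i \omega_i\hat\beta_i / \sum_i \omega_i$,
$\mathrm{SE} = (\sum_i \omega_i)^{-1/2}$, $\omega_i = \mathrm{SE}_i^{-2}$.
The 2 df path combines $(\hat\beta_G, \hat\beta_{GE})$ with matrix weights
$W_i = V_i^{-1}$ and tests $\hat\beta^\top (\sum_i W_i) \hat\beta$ on 2 df.
Whether the original two-study analysis used the within-study covariance
between the two coefficients or only the two standard errors cannot be
determined from the published description, so both modes exist
(`use_within_study_cov`); the covariance-aware mode is the default because
the covariance is available analytically here ($-v_u$) and using it is
statistically correct. With diagonal weights the joint statistic provably
reduces to the sum of the two coordinate-wise scalar meta chi-squares, a
numeric identity in the test suite. Only fixed-effect combination is
offered; Cochran's Q is emitted as a diagnostic column and never used for
inference.

## Diagnostics

The genomic inflation factor is median-based:
$\lambda = \mathrm{median}(\chi^2) / q_{0.5}(\chi^2_{df})$ with null medians
0.4549364 (1 df) and $2\ln 2$ (2 df). QQ tables use the $(k-0.5)/n$ expected
quantile convention, avoiding the 0 and 1 endpoints. Manhattan tables place
SNPs at the within-chromosome position plus the summed observed lengths of
preceding chromosomes, and flag $p < 5\times10^{-8}$ (genome-wide) and
$p < 10^{-6}$ (suggestive) with strict inequalities — a p-value exactly at a
threshold is not flagged. Flagging at these two fixed thresholds is the only
multiplicity handling, matching how trio GWAS of this kind report results.

## The synthetic-study generator

`simulate_study()` generates the statistical structure the analysis assumes,
and only that structure:

* **Founders** are drawn in Hardy-Weinberg proportions,
  $\mathrm{Binomial}(2, \mathrm{maf})$ per parent, with population-specific
  allele frequencies and linkage equilibrium across SNPs.
* **Exposure** is a trio-level Bernoulli draw with population-specific rates,
  so gene-exposure correlation across strata (the confounding scenario the
  within-family design is supposed to resist) arises when allele frequencies
  and exposure rates co-vary across populations.
* **Ascertainment**: the affected child's genotype is drawn from the
  Mendelian transmission law tilted by the multiplicative relative risk,
  $P(g \mid \text{affected}) \propto m(g\mid g_m,g_f)\,
  e^{\beta_G g + \beta_{GE} g e}$. This conditional draw reproduces the
  retrospective likelihood exactly and needs no penetrance constant. A
  rejection-sampling mode (accept with probability
  $f_0 e^{\beta_G g + \beta_{GE} g e}$) demonstrates the same law through
  the rare-disease mechanism; the two are verified to agree distributionally.
* **Contamination**: independent per-call missingness and per-(SNP, trio)
  Mendelian-error replacement, each logged so the clean study can be restored
  exactly (`revert_errors`), which pins down the QC module's accounting.

All randomness flows from one master seed through named sub-streams
(parents, exposure, child, errors), so each component is independently
reproducible.

Defaults mirror a large two-population trio study of orofacial clefts:
1,939 trios, 40% European / 60% Asian, and sharply population-differentiated
maternal exposure rates (smoking 0.30/0.03, alcohol 0.40/0.03, multivitamin
0.60/0.19 for European/Asian respectively, derived from published
descriptive tables of such studies). Allele frequencies default to
Uniform(0.05, 0.5), i.e. common variants that pass the MAF filter.

What the generator does **not** emulate: linkage disequilibrium (the tests
are single-SNP, so LD affects multiplicity interpretation but not
calibration of each test), haplotypes, parent-of-origin or maternal-genotype
effects, continuous or misclassified exposures, genotyping batch structure,
and imputation uncertainty (imputation R² is carried as an annotation, not
generated from a model). Passing calibration here shows the estimator and
its variance are correct under the assumed sampling law — not that real
genotyping artifacts are handled beyond what the QC filters remove.

## Problem sizes used by the checks

The packaged verification uses sizes chosen to make Monte-Carlo error small
relative to the tolerances while staying desk-scale: null calibration on
10,000 SNPs × 1,000 trios (exposure rate 0.3), where the 1 df rejection rate
at $\alpha=0.05$ must fall in the exact binomial 99% interval and
$\lambda \in [0.95, 1.05]$; a confounded two-population null (MAF 0.1 vs 0.5,
exposure 0.1 vs 0.5) where $\lambda \in [0.9, 1.1]$; estimator bias over 200
replicates of 5,000 trios at $\beta_{GE} \in \{0, 0.5\}$ (|bias| < 0.03,
Monte-Carlo SE ≈ 0.005); and closed-form/direct-maximization agreement on
1,000 random SNPs. Published suggestive interaction markers are reconstructed
from their printed relative risks and 95% CIs
($\hat\beta = \ln RR$, $\mathrm{SE} = (\ln U - \ln L)/(2 \times 1.959964)$);
agreement with printed p-values is limited by the 3-significant-figure
rounding of the published estimates, which at $|z| \approx 5$ allows
deviations of a few percent in the p-value.

## Known limitations

* Autosomes only; X/Y/MT transmission is not modeled.
* Biallelic markers only; multiallelic records are skipped, not split.
* Hard-call genotypes (0/1/2); imputed dosages must be thresholded upstream.
* No robust/sandwich variance: with multiplex families or related trios the
  conditional-likelihood variance would be optimistic; the package assumes
  independent trios.
* Separation at rare-genotype × rare-exposure combinations yields `NA`
  statistics rather than penalized estimates; how the original genome-wide
  analyses handled such SNPs is not documented, and NA-propagation is this
  package's own choice.
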
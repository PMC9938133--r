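---
title: "Tissue-partitioned multivariable Mendelian randomisation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-partitioned multivariable Mendelian randomisation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmr)
```

## The problem

Body mass index, like many complex exposures, is heterogeneous: the same
unit of BMI can reflect different underlying biology in different people.
Standard Mendelian randomisation (MR) estimates a single causal effect of
BMI on an outcome, averaging over that heterogeneity. `tpmr` implements a
two-sample approach that partitions BMI-associated variants by the tissue
in which their effect is plausibly mediated — here "adipose-like" versus
"brain-like", although the machinery is tissue-agnostic — and estimates the
separate contribution of each partition to disease risk.

The partitioning signal is genetic colocalization between the exposure GWAS
and tissue-specific eQTLs: a variant whose BMI association shares a causal
variant with the expression of a nearby gene in subcutaneous adipose tissue
is evidence that its BMI effect runs through adipose biology, and likewise
for brain. The posterior probability of a shared causal variant (PPA4) is
used twice: as an inclusion threshold (PPA4 ≥ 0.8) to define each tissue's
instrument set, and as a per-SNP weight on the SNP–exposure effect inside
the multivariable model.

## The model

For SNP $i$ with exposure effect $\hat\beta_i$ and tissue-$t$
colocalization posterior $\text{PPA4}_{i,t}$, the weighted design is

$$B^*_{i,t} = \hat\beta_i \cdot \text{PPA4}_{i,t},$$

built on the union of the tissue instrument sets (deduplicated by rsid;
a SNP selected in one tissue contributes its sub-threshold posterior, or 0
when no colocalization was evaluated, in the other). With outcome effects
$\hat\gamma_i$ and standard errors $s_i$, the tissue-level estimates solve
the weighted least-squares problem

$$\hat\theta = \arg\min_\theta \sum_i \frac{(\hat\gamma_i - \sum_t B^*_{i,t}\,\theta_t)^2}{s_i^2},$$

with no intercept. Standard errors carry a multiplicative random-effects
factor $\max\{1, \sqrt{Q/(L-K)}\}$, so heterogeneity can widen but never
narrow intervals. Exposure standard errors are **not** rescaled by PPA4:
the weight shrinks the signal a SNP contributes, not its sampling
uncertainty. This is the conservative reading of "weighting the betas"; the
alternative (scaling SEs alongside) would overstate the precision of
down-weighted SNPs in the strength diagnostics.

Instrument strength per tissue is measured by the conditional
F-statistic: regress tissue $t$'s weighted column on the other columns by
WLS with weights $1/\text{se}^2_{x,i}$ (exposure covariances taken as
diagonal, the usual convention when no phenotypic covariance matrix is
available), and set $F_t = Q_t/(L-K+1)$ where $Q_t$ is the weighted
residual sum of squares, $L$ the number of SNPs and $K$ the number of
exposures. $F_t > 10$ is the conventional adequacy rule. Note that $F_t$ is
a *per-instrument* strength: adding instruments of similar quality grows
$Q_t$ roughly linearly while leaving $F_t$ roughly constant.

## Colocalization

Per locus, the single-causal-variant enumeration is used. Each SNP and
trait gets a Wakefield approximate log Bayes factor: with $z = \beta/se$,
$V = se^2$, prior effect variance $W$ and shrinkage $r = W/(V+W)$,

$$\log\text{ABF} = \tfrac12\log(1-r) + \tfrac12 r z^2 .$$

Hypothesis evidence is accumulated over configurations in log space
(log-sum-exp): H1/H2 sum single-trait ABFs, H4 pairs same-SNP ABFs, H3
pairs distinct-SNP ABFs. Log-space accumulation is required because
biobank-scale GWAS routinely produce $|z|$ near 100, whose plain ABFs
overflow double precision. Priors default to the published defaults of the
method: $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, prior SD 0.15 for
quantitative and 0.2 for case–control traits; all configurable. Posterior
scale-invariance (rescaling one trait's betas and SEs) holds when the prior
SD is expressed on the trait's own SD scale and rescales with it; with a
fixed prior SD the ABF shrinkage changes, so the package treats the prior
SD as a trait-scale quantity.

Two further conventions: SNPs present in only one trait in a region are
ignored (intersection matching), and when several genes are tested at one
locus the SNP's tissue PPA4 is the **maximum** over genes — the only
reduction consistent with "any proximal gene colocalizes" at the variant
level. The colocalization window around a lead SNP defaults to ±500 kb.

## Harmonisation and clumping

Instruments are lead SNPs from greedy p-value clumping: rank by ascending
p, keep a SNP iff $p < 5\times10^{-8}$ and it is independent of everything
already kept ($r^2 < 0.01$ with an LD matrix, or ≥ 10 Mb distance without
one — a deliberately strict window that guarantees at-least-equivalent
independence in synthetic workflows). Ties in p are broken by rsid so the
result is order-invariant. The extended HLA region (chr6:25–35 Mb) is
masked by default because its long-range LD defeats the single-causal
-variant assumption.

Outcome estimates are aligned to the exposure effect allele; swapped or
strand-flipped alleles negate the outcome beta. Palindromic SNPs are
oriented by allele frequency when both minor-allele frequencies are below
0.42 (the common two-sample-MR convention; the limit is configurable) and
dropped as ambiguous otherwise. SNPs missing from the outcome may be
replaced by a user-supplied proxy with $r^2 \ge 0.8$. Every decision is
recorded per SNP with a reason.

## Univariable estimators

Total-effect analyses use IVW (WLS through the origin, weights
$1/se_y^2$, multiplicative random-effects SE floored at 1; Wald ratio for a
single SNP), MR-Egger (WLS with intercept after orienting exposure betas
positive; the intercept is the directional-pleiotropy test), the weighted
median (ratio estimates, inverse-variance weights from the first-order
delta-method SE $se_y/|\beta_x|$, midpoint-convention interpolation of the
weighted CDF at 0.5, parametric-bootstrap SE with a mandatory seed), and
the penalised weighted median (heterogeneity contributions
$Q_i = w_i(r_i-\hat\theta)^2$ converted to upper-tail $\chi^2_1$
probabilities $q_i$, weights multiplied by $\min(1, 20\,q_i)$, median
recomputed). The penalty constant 20 and bootstrap default of 1000
replicates follow the published conventions of those estimators. The
first-order ratio variance is the default because it makes results exactly
reproducible against a closed-form oracle; a second-order option exists.

## The simulation engine

The generator works entirely at the summary level — no individual-level
genotypes — which matches two-sample practice and keeps the full power
grid at desk scale. Defaults encode the reference study conditions: a pool
of 915 independent loci from an exposure GWAS of $n = 700{,}000$; 86
adipose-like and 140 brain-like instruments; true effects
$\{0.1, 0.125, 0.15\}$; outcome sample sizes 10k–100k; per-tissue variance
explained 0.5%–3%.

Per SNP: MAF $\sim U(0.05, 0.5)$; $se = 1/\sqrt{2p(1-p)n}$; each tissue's
true effects are zero-mean normal draws rescaled so the realised
$\sum 2p(1-p)\beta^2$ equals the variance-explained target *exactly*;
estimated betas add Gaussian noise at the analytic SE. Own-tissue PPA4 is
drawn from Beta(8, 2) truncated to ≥ 0.8 (instruments re-selected each
replicate at that threshold), cross-tissue and unlabelled PPA4 from
Beta(1, 9). Unlabelled pool SNPs carry background effects (2% variance
explained by default) representing BMI pathways through neither modelled
tissue; they are essentially never selected. The outcome model is
$\gamma_i = \sum_t \theta_t \beta_{t,i}$ on the *true, unweighted* tissue
effects. In the power grid both tissues receive the cell's effect size and
rejection is recorded per tissue. Determinism: each replicate reseeds with
`seed + (cell − 1)·10⁴ + rep`, cells in lexicographic (effect, n_outcome,
varexp) order.

What the generator does **not** emulate: LD between pool SNPs, sample
overlap between exposure and outcome GWAS, population stratification,
winner's-curse selection of instruments, and allele/strand bookkeeping
(simulated SNPs are already harmonised). Passing simulation tests
therefore demonstrate statistical behaviour of the estimator under clean
two-sample assumptions, not robustness to those data pathologies.

## What the weighting does to the estimand

Because the truth in the generator is unweighted
($\gamma = \theta\,\beta$) while the fit uses $\beta \cdot \text{PPA4}$,
the tissue coefficients are *rescaled* relative to $\theta$ whenever PPA4
is not exactly 0/1: own-tissue weights in $[0.8, 1)$ inflate the
coefficient by roughly $1/\overline{\text{PPA4}}$, cross-tissue leakage
(small weights on the other tissue's instruments) deflates it, and
sampling noise in the exposure betas attenuates it by roughly $1/F$. At
the default study conditions these effects largely cancel, leaving a
residual downward bias of a few percent of $\theta$ on the smaller
(adipose, 86-instrument) partition — visible in the acceptance suite's
parameter-recovery check, whose bias bound at 1000 replicates is tighter
than this structural residual. Confidence-interval coverage and type-I
error remain calibrated. This is the quantitative face of the method's own
caveat: tissue-partitioned estimates index the *relative contribution* of
a partition, not a plain causal effect, and should be read comparatively
(which tissue's signal survives joint modelling) rather than as unbiased
effect sizes.

## Numerical choices

* All Bayes-factor aggregation in log space; posteriors normalised by
  softmax, asserted to sum to 1 within $10^{-10}$.
* Weighted least squares through `stats::lm`/`lm.wfit`; SEs from the
  explicit $(X^\top W X)^{-1}$ so the random-effects floor is applied to
  the fixed-effect SE, never to the residual-scaled one.
* A weighted design with condition number above $10^8$ aborts with a
  "collinear exposures" error instead of returning unstable estimates.
* Clumping ties broken lexicographically by rsid; greedy selection is
  deterministic given the tie rule.
* Ratio-undefined SNPs (exposure beta exactly 0) are dropped from median
  estimators with a warning; an error is raised only if fewer than 3
  remain.
* Degenerate inputs (empty instrument union, a tissue column entirely
  zero, no overlapping SNPs in a coloc region, all-missing SEs) raise
  immediate, named errors.

## Problem sizes used in the checks

The test suite runs the oracle comparisons at 100 random instances per
estimator, colocalization enumeration at up to 4 SNPs × 100 regions, the
recovery/calibration study at 1000 replicates of the full 915-SNP pool
(variance explained 1%, outcome $n = 75{,}000$), and the pipeline
end-to-end on planted fixtures of 20–28 loci. The acceptance script
recomputes instrument strength from 200 subsamples of 30 instruments per
tissue and recovery/power/type-I at 500 replicates. These sizes were
chosen so each Monte-Carlo conclusion has standard error well below the
tolerance it is compared against.

## Known limitations

* Single-causal-variant colocalization only; loci with multiple causal
  variants (or strong uncorrected LD) can produce misleading PPA4 in
  either direction.
* The conditional-F convention assumes diagonal exposure covariance; with
  strongly correlated exposure measurement errors it is optimistic.
* Proxy substitution trusts the user-supplied proxy table; the package
  never computes LD.
* The scale distortion described above means cross-study comparisons of
  tissue-partitioned coefficients should hold the PPA4 distribution
  roughly constant (e.g. via the fixed 0.8 threshold).
* eQTL meta-analysis, LD-panel construction and genome-build liftover are
  out of scope; inputs are assumed to be on one build.
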
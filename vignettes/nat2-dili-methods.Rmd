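---
title: "Methods: NAT2 acetylator status and isoniazid liver injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NAT2 acetylator status and isoniazid liver injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nat2pgx)
```

# The problem

Isoniazid, a first-line tuberculosis drug, causes liver injury (DILI) in
a minority of patients. The main pharmacogenomic determinant is *NAT2*:
patients carrying two low-activity haplotypes — slow acetylators (SA) —
clear the drug slowly and face roughly ten-fold odds of DILI. This
package implements the full analysis chain used to establish and quantify
that relationship in a small multi-ethnic case-control cohort (24 cases,
79 controls), from genotype QC through phenotype inference, association
testing and the clinical-validity calculus that turns an odds ratio into
decision-relevant quantities (PPV, NPV, PAF, NNT).

Because the underlying individual-level data are not deposited, the
package ships a cohort simulator whose defaults encode the study
conditions. Every statistical claim the package tests is evaluated
against either closed-form oracles or that generator, for which the truth
is known.

# The cohort simulator

## Generative model

Each sample draws two NAT2 haplotypes from its stratum's haplotype
distribution. The packaged haplotype table uses star-allele-like
definitions (*4 and *13A rapid; *5B, *5C, *6A, *7B, *14A slow) whose
marginal variant-allele frequencies match the control-group MAFs of the
emulated cohort (e.g. rs1041983 at 0.367, rs1799930 at 0.222). The table
is a synthetic stand-in: no per-ethnicity haplotype frequencies were
published for this cohort, so one table serves all strata and ethnic
structure enters only through background SNPs. The number of slow
haplotypes (0/1/2) is the latent acetylator class (RA/IA/SA) and, by
construction, agrees exactly with the rule-based caller at zero
missingness — a consistency check the suite enforces.

Disease status follows a retrospective logistic model

$$\operatorname{logit} P(\text{DILI}) = \beta_0 + \beta_{SA}[SA] +
\beta_F[\text{female}],$$

with defaults $\beta_0 = -5$, $\beta_{SA} = \log 10$ (the reported
covariate-adjusted OR of 9.98) and $\beta_F = \log 4.9$ (the cross-product
OR of the female excess among cases). The rare-disease baseline matters:
with a common-disease $\beta_0$ the logistic saturates, the marginal
case/control SA contrast compresses, and the cohort no longer shows the
reported ~34% slow acetylators. Case/control totals (24/79, split
Chinese 12/57, Malay 5/10, Indian 1/7, Others 6/5) are enforced exactly,
as in a retrospective design: a latent population pool is grown per
stratum, statuses are drawn Bernoulli, and the configured numbers of
cases and controls are sampled uniformly from the realized groups.
Cases then receive a DILI grade from the configured distribution
(10/24, 13/24, 1/24 over grades 2/3/4); a `grade_trend` switch tilts
slow-haplotype carriers towards higher grades to emulate a risk-allele
frequency rising with severity. Strong tilts deliberately deplete slow
carriers from grade 2, so the monotone-trend property is only expected
for moderate tilts (the suite uses 0.8).

The tag SNP rs1495741 is modelled as a direct class-flip: with
probability `tag_concordance` (default 0.981) the genotype class agrees
with the latent acetylator class (AA for SA; AG/GG split by the G-allele
frequency otherwise). This mirrors the only published quantity — a
concordance percentage — rather than inventing haplotype phase between
the tag and the coding SNPs. Background SNPs (default 200) are unlinked,
with base MAF uniform on (0.05, 0.5) and per-stratum logit-normal
perturbation (SD 0.15) that gives PCA something real to find. One seed
drives every draw; runs are byte-reproducible.

## What the simulator does not emulate

Array intensities, genotype-calling error modes, linkage disequilibrium
beyond the NAT2 haplotypes, age effects on risk, and dose or co-medication
effects. Passing tests therefore demonstrate that the *statistical
machinery* is correct under the declared model, not that the biological
effect sizes would replicate in new data.

# Quality control

Samples are filtered before variants at call rate ≥ 95% each. The exact
Hardy-Weinberg test conditions on the minor-allele count and sums the
probabilities of all heterozygote counts no more probable than the one
observed; it is validated exhaustively against a full-enumeration oracle
for all genotype configurations with n ≤ 50. HWE filtering (α = 10⁻⁶) is
done within the largest, genetically most homogeneous stratum (Chinese by
default) because population mixture alone produces heterozygote deficits.
Identity-by-state uses the mean of (2 − |dosage difference|)/2 over
shared non-missing sites with a configurable 0.9 flag threshold, and
heterozygosity outliers are flagged beyond 3 SD; the source study stated
no thresholds for either, so these defaults are documented choices, not
inferences. Sex checks from array intensities are out of scope: upstream
sex-mismatch calls are injected by id. PCA mean-imputes missing dosages,
standardizes variants, drops zero-variance columns and fixes each
component's sign by its largest-magnitude loading, which makes
coordinates reproducible up to machine error under variant permutation.

# Acetylator inference

The 4-SNP panel (rs1801280, rs1799930, rs1799931, rs1801279) is a config
table, not hard-coded; the caller verifies counted-allele orientation
against the genotype matrix and fails loudly on mismatch. rs1801279 is
expected monomorphic in the cohort's ancestries and is imputed to
homozygous reference (with a flag) when missing; any other missing panel
SNP refuses the call under the default policy rather than silently
imputing an informative genotype. The rules are total over complete
dosage vectors — RA/IA/SA partition the space — and adding variant burden
never moves a call towards rapid.

# Association and multiplicity

Each candidate SNP is tested under additive, dominant and recessive
codings by maximum-likelihood logistic regression with sex and the first
two PCs; ORs carry Wald 95% CIs. A coded genotype constant within cases
or within controls, or a separated fit (|coefficient| > 15), is reported
as inestimable with a reason instead of a number — with one homozygous
group empty the recessive model in a 24-case cohort frequently lands
here. Wald rather than profile intervals match conventional reporting;
Firth correction is a stated non-goal.

Multiplicity over the SNP × model family is handled by the
correlated-test adjustment: the correlation of test statistics is
approximated by the correlation of covariate-residualized coded
predictors, and each adjusted p is one minus the multivariate-normal
rectangle probability at the test's |z|, integrated quasi-randomly to
absolute tolerance 10⁻⁴ and clipped to [raw p, 1]. A non-PSD correlation
estimate (inevitable with duplicated predictors) is repaired by
eigenvalue clipping with a warning. The construction is validated at its
two analytic limits — independence (Šidák) and perfect correlation (no
adjustment) — to within 2 × 10⁻³, and the family size actually adjusted
is reported rather than fixed in advance. Two-by-two exact tests use the
point-probability two-sided convention with the sample cross-product OR
(the conditional-MLE OR some software reports will differ on extreme
tables).

For baseline covariate comparisons the package applies the conventional
"as appropriate" rule: t-test or Mann-Whitney for continuous variables,
Yates-corrected chi-square for a standalone binary variable when all
expected counts reach 5 (Fisher otherwise), and Fisher for each level of
a multi-level categorical against the rest. This mixed convention is what
reproduces the emulated study's printed baseline p-values; a pure-Fisher
rule does not.

Design power is estimated by simulating case/control allele counts under
the allelic OR (case allele frequency from the odds transform) and
testing each replicate's allelic 2×2 at the target α, with a Monte Carlo
SE alongside.

# Clinical validity

Sensitivity (18/24) and specificity (62/79) are carried as exact
fractions; all rounding lives in `round_half_up()` at report time,
because the downstream numbers (NNT 4.08, PPV 28%) are only reproducible
from unrounded inputs. PPV and NPV come from Bayes' theorem at an
*assumed* population prevalence (default 10%), since case-control
sampling fractions make within-sample predictive values meaningless; a
5–20% sweep quantifies prevalence sensitivity (PPV varies widely, NPV
stays high — the clinically load-bearing fact for rule-out use). The
absolute risk reduction is implemented as the risk difference between
exposed and unexposed, risk_exposed − risk_unexposed = PPV − (1 − NPV):
that reading reproduces NNT = 4.08, whereas the incidence-minus-exposed
formulation printed alongside it does not, and the discrepancy is
documented here deliberately. Both PAF estimators are computed always:
the case-based p_c·(OR−1)/OR (which, with OR 9.98, yields the printed
0.67) and the incidence formula (IP_t − IP_o)/IP_t (≈ 0.66 at 10%
prevalence); since it cannot be determined which the original analysis
used, neither is treated as "the" value and both appear in every report.

# ROC comparison

Risk models are in-sample logistic fits (the emulated workflow reported
apparent AUCs; no cross-validation is attempted), with ethnicity coded as
indicators against the largest stratum. AUC uses the exact
pairwise/Mann-Whitney statistic with half-credit ties; the trapezoidal
curve is only for plotting. DeLong's test compares two models' AUCs on
the same samples through placement values; its variance is checked
against a brute-force placement recount, its p against pROC's reference
implementation, and — as an exact small-sample oracle — against a
10,000-draw per-sample score-exchange permutation, which agrees to
within ~0.01 at n = 30. A caveat the suite encodes: *refitting* a model
on permuted labels does not give apparent AUCs centred at 0.5 (in-sample
fitting is optimistically biased, ~0.57 at n = 103 with three
predictors); chance-level calibration holds for fixed scores against
permuted labels.

# Problem sizes and numerical choices

The test suite runs the generator at the emulated scale (103 samples;
200 cohort replicates for parameter-recovery checks, which keep the
nominal 95% CI coverage of the true OR above 90%), enumerates the exact
test oracles exhaustively (HWE to n = 50, Fisher to n = 40), and uses
2,000 replicates for the power computation — sizes chosen to make Monte
Carlo error small relative to every asserted tolerance while the whole
suite stays comfortably fast on one core. Exact-test ties in p-value
summations use relative tolerances (1 + 10⁻⁷ for hypergeometric, 1 + 10⁻⁹
for HWE) so that floating-point noise cannot flip table inclusion;
Youden ties break towards higher specificity; quasi-random integration
seeds are fixed arguments so adjusted p-values are reproducible.

# Known limitations

Star-allele naming and phasing are not implemented (the acetylator rules
need only dosages). Conditional-MLE odds ratios, Firth regression,
ordinal severity models, meta-analysis and cost-effectiveness are out of
scope. The simulator's tag-SNP model cannot express LD decay, and its
single haplotype table across strata understates real inter-ethnic
variation in NAT2 frequencies.
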
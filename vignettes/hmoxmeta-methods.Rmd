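---
title: "Methods: meta-analysis of the HMOX1 promoter (GT)n polymorphism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of the HMOX1 promoter (GT)n polymorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmoxmeta)
```

## The scientific problem

The promoter of heme oxygenase 1 (HMOX1) contains a (GT)n dinucleotide
microsatellite. Longer repeat tracts reduce the inducibility of this
antioxidant enzyme, so the long (L) repeat class is a plausible risk
allele for oxidative-stress diseases such as COPD. Primary case–control
studies classify alleles into short (S), medium (M) and long (L) classes
(the repeat-number cutoffs vary between studies and are upstream of this
package) and report either per-group allele counts, the dominant
carrier contrast — type I (at least one L allele) versus type II (no L
allele) — or both. `hmoxmeta` pools such published counts.

## Effect-size model

Each comparison reduces a study to a 2×2 table
(a = exposed cases, b = unexposed cases, c = exposed controls,
d = unexposed controls). Three constructions are supported:

* **allele** (`allele_S`/`allele_M`/`allele_L`): one allele class
  against the other two, counting each of the 2N chromosomes in a group
  as an independent observation. This is the standard allele-counting
  model; it ignores the within-subject correlation between a person's
  two chromosomes, which is the convention in this literature and is
  what makes published allele odds ratios reproducible. The caveat is
  deliberate and documented rather than corrected.
* **genotype**: type I vs type II subjects, cases vs controls.
* **severity**: type I vs type II subjects, with the more-severe COPD
  stratum in the "case" role, so OR > 1 means L-carriers are enriched
  in severe disease.

The per-study effect is the Woolf estimator: log OR = ln(ad/bc) with
large-sample variance 1/a + 1/b + 1/c + 1/d. When any cell is zero, 0.5
is added to **all four** cells (flagged `corrected`); the packaged data
contain no zero cells, so the policy only matters for simulated or user
data. Confidence intervals use z = 1.959964 throughout, and all
p-values are two-sided; "p < 0.001" flooring happens only in printed
output, never in stored values.

## Pooling and heterogeneity

Fixed-effect pooling is inverse-variance: weights $w_i = 1/v_i$, pooled
estimate $\hat\theta = \sum w_i \theta_i / \sum w_i$, SE
$1/\sqrt{\sum w_i}$. Cochran's statistic
$Q = \sum w_i(\theta_i - \hat\theta)^2$ is always computed with the
fixed weights, with $I^2 = \max(0, (Q - df)/Q) \times 100$ banded as
low (< 25%), moderate (25–75%) or high (> 75%) inconsistency.

Random-effects pooling is DerSimonian–Laird: the method-of-moments
between-study variance $\tau^2 = \max(0, (Q - df)/C)$ with
$C = \sum w_i - \sum w_i^2/\sum w_i$, and re-weighting by
$w_i^* = 1/(v_i + \tau^2)$. Q and I² are reported from the fixed-weight
pass regardless of the pooling model. When $Q \le df$, $\tau^2$
truncates to zero and the random-effects result coincides exactly with
the fixed-effect one.

**Model choice.** The classical decision rule — fixed effect when the
heterogeneity test gives $p_Q > 0.10$, random effects otherwise, with
the boundary resolving to random effects — is implemented
(`select_model()`, `pool(effects, "rule")`). The *default* pipeline,
however, applies DerSimonian–Laird to every comparison. This is a
deliberate design choice: with τ² truncated at zero the DL model
reproduces the fixed-effect answer automatically wherever the data show
no excess dispersion (for example the Asian allele subgroups), while
remaining conservative where moderate heterogeneity exists but the
0.10 rule would still pick the fixed model (the seven-study genotype
comparison, $p_Q = 0.14$, is the motivating case: its published
interval matches the random-effects computation). A single default rule
that degrades gracefully is easier to reason about than a data-driven
switch, and the switch remains available as an explicit mode.

One rounding note: the five-study L-allele pooled interval is
2.02 [1.31, 3.11] at 2-decimal rounding; the lower bound sits at
1.3103, so sources that print 1.32 have rounded differently. The
package does not special-case this: it reports what the arithmetic
gives.

## Hardy–Weinberg testing

Controls should conform to Hardy–Weinberg equilibrium; departure
suggests genotyping error or population stratification and feeds the
sensitivity analysis. Two Pearson chi-square tests are provided:

* `hwe_multiallelic()` for a full k-allele genotype table (df =
  k(k−1)/2; df = 3 for S/M/L) — the test a primary study would run.
* `hwe_biallelic()` (df = 1) for the L vs non-L collapse. Published
  marginals (L-allele count, type I/type II split) determine the
  collapsed genotype triple exactly via `collapse_to_biallelic()`:
  LL = L − typeI, L-het = 2·typeI − L, non-L hom = typeII. Results
  obtained this way are *derived, not primary*: they use less
  information than the full tri-allelic table, and they do not in
  general reproduce HWE p-values computed by the original authors on
  the complete genotype distributions. The packaged fixture therefore
  carries no HWE p-value column; the tests are tools, not regression
  targets.

Expected counts of exactly zero (an allele absent from the sample)
contribute nothing to the statistic; the empty-sample test is an error.

## Publication-bias diagnostics

* **Egger regression**: ordinary least squares of the standardized
  effect $\theta_i/se_i$ on precision $1/se_i$; the intercept measures
  small-study asymmetry and is tested two-sided against a t
  distribution with n − 2 df. The unweighted form is used (the variant
  with additional weighting is not implemented): it is the form under
  which the packaged data reproduce the published bias p-values.
  It needs n ≥ 3 and varying precision.
* **Begg–Mazumdar rank correlation**: Kendall's score S between the
  variance-standardized deviates
  $t_i = (\theta_i - \bar\theta)/\sqrt{v_i - 1/\sum w}$ and the
  variances $v_i$, referred to
  $z = S/\sqrt{n(n-1)(2n+5)/18}$ — the normal approximation **without**
  continuity correction, which again is the convention under which the
  published values reproduce (the corrected variant gives visibly
  larger p on five studies). Ties contribute zero to S and leave the
  null variance unadjusted, with a warning, making the test mildly
  conservative under ties; a non-positive conditional variance
  $v_i - 1/\sum w$ is guarded to a small positive value, with a
  warning.

`funnel_data()` returns plot-ready (OR, SE) pairs plus the pooled
reference line; the package draws nothing.

## Subgroups and sensitivity

Five study-level stratifiers are supported: ethnicity, genotyping
method, control source, quality (the Newcastle–Ottawa dichotomy:
higher = NOS ≥ 7, lower = NOS < 7) and publication language. Strata are
pooled independently with the default model; empty strata are omitted
with a notice, single-study strata return the single estimate, and a
missing stratifier value is a hard error naming the study. No
between-subgroup heterogeneity test is performed. In the packaged
fixture the language labels are stored as data (three Chinese-language
studies, four English), not inferred from any other column.

`leave_one_out()` re-pools with each study omitted and reports the
min/max pooled OR plus a stability flag (every omission keeps the OR on
the same side of 1 and all omission intervals overlap).

## The simulator

`simulate_meta()` generates study tables with exactly the structure the
analysis assumes, so calibration and recovery are testable offline:

1. Control genotypes are multinomial over the six S/M/L genotypes under
   tri-allelic HWE with frequencies $(p_S, p_M, p_L)$.
2. The study-level carrier log OR is $\theta_i \sim N(\mu, \tau^2)$.
3. Case carrier (type I) counts are binomial with probability derived
   from the control carrier odds $q_0/(1-q_0)$ times $e^{\theta_i}$,
   where $q_0 = 1-(1-p_L)^2$.
4. Case carrier genotypes are split LL vs L-heterozygous using the
   control HWE conditional ($P(\mathrm{LL}\mid\mathrm{carrier}) =
   p_L^2/q_0$), heterozygote partner alleles by relative S/M frequency,
   and non-carriers multinomially over SS/SM/MM — so allele counts are
   consistent with genotype counts *by construction*.
5. Covariates are assigned uniformly at random; an optional severity
   stratification splits cases with a chosen carrier log OR on
   severity; an optional selective-publication rule suppresses a study
   with probability π when its own association p-value exceeds α.

The effect model is **carrier-level (dominant)**, matching the
type I/type II contrast. Allele-level odds ratios *emerge* from it
rather than being imposed, so allele-comparison recovery tests must use
the simulator-computed induced truth, not μ. Defaults
($p = (0.45, 0.45, 0.10)$, μ = ln 1.8, τ² = 0.05, study sizes drawn
from the ranges seen in this literature, roughly 30–270 per group) are
chosen to resemble the packaged studies. A root seed is mandatory;
per-study substreams are derived from it, so a fixed seed reproduces
the data exactly.

What the simulator does **not** emulate: raw (GT)n repeat lengths or
genotyping error, shared control cohorts between studies, covariates
correlated with effect size, and within-subject chromosome correlation
beyond HWE. Passing calibration tests therefore show the estimators are
correct under the stated model, not that real studies satisfy that
model.

## Numerical and testing choices

* z₀.₉₇₅ = 1.959964; τ² truncation at 0; Q-rule boundary p = 0.10
  resolves to random effects; OR/CI agreement with published tables is
  asserted at 2-decimal rounding, matching their print precision.
* Degenerate inputs: an all-zero 2×2 table is an error (flagged on the
  table); a single study pools to itself with Q = 0 and an undefined
  heterogeneity band; an empty effect list is an error.
* Test problem sizes, chosen to make Monte-Carlo error small at desk
  scale: Q-test calibration uses 5,000 replicates of five studies of
  200 cases/200 controls under τ² = 0 (rejection at the 0.10 threshold
  asserted within ±0.02); recovery uses 40 replicates of 20 studies of
  500/500 at μ = ln 2, τ² = 0.1 (mean pooled OR within 10% of 2);
  HWE nominal-rate and severity-null checks use 1,000 and 10
  replicates respectively.
* Severity pooling is exercised only on simulated data: the published
  severity genotype counts were never printed as a main-text table, so
  the severity comparison is supported as schema plus a simulated null
  check (carrier OR 1 generates pooled severity intervals covering 1),
  not as a numeric reproduction.

## Known limitations

* Only the Woolf odds ratio is implemented; Peto and Mantel–Haenszel
  pooling, REML/Paule–Mandel τ², and Hartung–Knapp adjustment are out
  of scope (inverse-variance FE was chosen over Mantel–Haenszel because
  it is what the published subgroup values correspond to).
* Trim-and-fill, Peters' test and contour-enhanced funnels are not
  provided.
* Meta-regression on continuous covariates (year, NOS as a number) is
  not provided; quality enters only as the ≥ 7 dichotomy.
* Two packaged studies report identical control genotype counts,
  consistent with a shared control cohort; the analysis pools them as
  printed, as the original analysis did, which slightly understates the
  pooled variance if the cohorts truly overlap.
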
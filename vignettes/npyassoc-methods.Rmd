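---
title: "Methods: SNP diversity and marker-trait association in laying hens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP diversity and marker-trait association in laying hens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npyassoc)
```

npyassoc implements the analysis pipeline of a candidate-gene SNP study
in laying hens: variant discovery in the coding region of a candidate
gene (here neuropeptide Y, NPY), per-breed population-genetic
characterisation of the discovered markers, and fixed-effect
association of marker genotypes with egg-production traits. This
vignette is the package's account of the statistical methods, the
tunable parameters, the design choices that were genuinely open, and
what the synthetic-data tests do and do not establish.

## The study structure

The shipped reference data describe 117 hens from four breeds — 59
Pradu Hang Dum (PH), 20 Chee (C), 20 black-bone (BB) and 18 commercial
Hy-Line Brown layers (LC) — genotyped at seven biallelic SNPs in the
NPY coding sequence (`npy_loci()`: g.130 A>G through g.647 G>T) and
phenotyped for eight egg-production traits (`trait_definitions()`:
AFEP in days, FEW/EW_9M/EW_12M in grams, NE_9M/NE_12M/EperM in eggs,
EMs in g/hen/day). Per-breed genotype counts (`npy_genotype_counts()`)
and per-breed trait means and SDs (`npy_trait_params()`) are
transcribed from the published study tables; individual hen records
are not deposited anywhere, which shapes what can and cannot be
reproduced (see "Scope of reproduction" below).

## Variant discovery

Direct Sanger genotyping of diploid birds yields one consensus
sequence per hen in which heterozygous positions appear as IUPAC
two-base ambiguity codes. `call_variant_sites()` scans alignment
columns against a user-designated reference:

* coordinates are 1-based on the *ungapped* reference: columns where
  the reference carries a gap are skipped without advancing the
  coordinate, so positions are stable under re-alignment;
* an unambiguous non-reference base is a homozygous alternate call; a
  two-base code whose pair is exactly {ref, alt} is a heterozygote;
  gaps, `N` and three/four-base codes are missing (no indel calling);
* columns where more than two alleles segregate are excluded from the
  biallelic catalogue and reported separately;
* allele polarity is reference-first (matching "A>G"-style naming);
  when the reference base is absent from every sample the major sample
  allele is taken as ref and the site is flagged `ref_unobserved`.

The reference accession anchoring the coordinates is deliberately the
user's choice: the package treats whatever reference is supplied as
the coordinate system.

## Diversity statistics

For genotype counts $(n_{AA}, n_{Aa}, n_{aa})$ with $n$ non-missing
hens, allele frequencies use gene counting,
$p = (2 n_{AA} + n_{Aa}) / 2n$, the maximum-likelihood estimator for a
codominant biallelic marker. Derived statistics use the uncorrected
forms:

* expected heterozygosity $H_E = 1 - p^2 - q^2 = 2pq$ (no
  $2n/(2n-1)$ small-sample correction — the uncorrected form is what
  the shipped reference table's cells recompute to);
* polymorphism information content, Botstein's biallelic form
  $\mathrm{PIC} = 1 - (p^2 + q^2) - 2 p^2 q^2 = H_E - 2 p^2 q^2$,
  with maximum 0.375 at $p = 0.5$. The natural $k$-allele
  generalizations of both are implemented (vector input) but the
  biallelic case is the supported surface;
* the Hardy-Weinberg test is the plain $\chi^2$ goodness of fit of the
  three observed genotype counts to $(p^2, 2pq, q^2)\,n$, without
  continuity correction (the shipped table's values match the
  uncorrected statistic).

Two degrees-of-freedom conventions are exposed because they genuinely
disagree in practice. With one estimated allele frequency and three
classes, df = 1 is the statistically standard choice
(`alleles_based`, the default). Treating the three genotype classes as
a plain three-category goodness-of-fit test gives df = 2
(`classes_minus_1`, critical value 5.99 at $\alpha = 0.05$); only this
convention reproduces the published per-breed in/out-of-HWE
classification (e.g. a C-breed locus with $\chi^2 = 4.36$ called "in
HWE" and one with 6.50 called out). Reports therefore default to
df = 1, and replication of the published classification uses df = 2.

Monomorphic loci return $\chi^2 = 0$ with df = 0, `in_hwe = TRUE` and
an explicit `monomorphic` flag rather than an error, so whole-table
scans do not fall over on fixed loci.

### Rounding

Printed reports round half away from zero (2 decimals), computed with
a small epsilon guard so decimal halves stored fractionally low in
binary floating point (0.255, say) still round up. Comparisons against
published two-decimal values in the tests use a |difference| ≤ 0.005
band instead of re-rounding, which also absorbs values the source
itself printed at three decimals.

## Association model

The association model is the one-way fixed-effect linear model
$y_{ij} = \mu + g_i + e_{ij}$, fitted by ordinary least squares on the
cell-means parameterization (`fit_oneway()`): one mean per genotype
class (or breed), an overall F test of the factor against the pooled
residual mean square, and least-squares means with standard errors
from $\hat\sigma^2 (X^\top X)^{-1}$. Without a covariate, LS means are
exactly the arithmetic group means; with an optional numeric covariate
(e.g. age) a common slope is added and LS means are evaluated at the
covariate grand mean. The default scan pools breeds — the only model
consistent with a single LS-means column per genotype in the published
report layout — while breed-as-factor or covariate-adjusted fits are
available by calling `fit_oneway()` directly with the corresponding
arguments.

Pairwise comparisons (`pairwise_ttests()`) are two-sided t tests on
LS-mean differences using the pooled residual variance and the error
df — unadjusted by default, in line with typical GLM letter reports;
Bonferroni and Tukey HSD are selectable. The compact letter display
(`compact_letter_display()`) uses insert-and-absorb: levels are swept
in descending-mean order, each joining every letter group it is
mutually non-significant with; a level rejected by all groups splits
each conflicting group on its compatible subset, and subset groups are
absorbed. The sweep order makes the output deterministic and gives the
highest mean the letter "a". The letter invariant — a pair shares a
letter iff its pairwise p ≥ α — is property-tested against random
p-value matrices.

Degenerate inputs follow reporting conventions rather than hard
failures where a value is still meaningful: genotype classes with one
hen stay in the fit but are excluded from letters (their SD/SE would
be undefined in a summary); loci with a single observed class are
reported non-testable; fewer than two factor levels or zero residual
df raise design errors.

`levene_test()` is the Brown–Forsythe variant — the one-way ANOVA,
through the same engine, of absolute deviations from group medians;
median centering is the robust choice and the convention is
cross-checked against an independent implementation in the tests.
Normality screening is out of scope; instead an optional outlier
screen is provided (`filter_outliers()`, off by default): within breed
and trait, values whose modified z-score $0.6745(x -
\mathrm{median})/\mathrm{MAD}$ exceeds 3.5 are set missing. The
modified z-score is used deliberately: a mean/SD z-score is bounded by
$(n-1)/\sqrt{n}$, so a 3.5 rule could never fire in a 20-hen breed.

## The synthetic-data generator

`sim_config()` describes a study: breed sizes, loci, a per-breed
genotype law, per-breed trait baselines (mean, SD), and optional
per-locus additive/dominance effects. Two genotype laws are supported:

* **frequency mode** — genotype class probabilities copied directly
  from a table (the default configuration copies the published
  per-breed genotype frequencies, so Hardy-Weinberg deviations carry
  over verbatim);
* **p/F mode** — an inbreeding-style deviation
  $(p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq)$, the simplest one-parameter
  mechanism for heterozygote deficit/excess; $F = 0$ gives exact HW
  proportions, $F = 1$ eliminates heterozygotes, and configurations
  implying negative probabilities are rejected.

Phenotypes follow the generative mirror of the analysis model: breed
baseline + per-locus genotype value ($-a$, $d$, $+a$) + Gaussian noise
with the breed SD, truncated at zero because the traits are ages,
weights and counts. With the shipped baselines the truncation
probability is at most ~1% (EperM in the C breed) and negligible
elsewhere, a slight and documented distortion of exact normality.
Every draw uses a substream seed derived from the global seed and the
(breed, locus) or (breed, trait) labels, so adding loci or traits
never perturbs existing draws and identical configurations produce
byte-identical files (`generate_study()` writes the tables, the
latent-truth file and a YAML configuration echo).

The default configuration (`default_sim_config()`) reproduces the
study dimensions: 117 hens, four breeds, seven loci, eight traits,
published frequencies and baselines, and no genotype effects.

### What the generator does and does not emulate

It emulates the study's sampling structure: breed sizes, per-breed
genotype frequencies including their HWE departures, and per-breed
trait locations and scales. It does not emulate pedigree or linkage
between the seven loci (loci are drawn independently, whereas real
coding-region SNPs a few hundred bases apart are typically in strong
LD), polygenic background, non-normal trait shapes, or the derivation
of egg mass from egg number and weight — EMs is simulated as an
independent trait because its published derivation is unstated.
Passing tests on synthetic data therefore establish the correctness
and calibration of the *computations*, not the biological claims of
any particular dataset.

## Calibration design

One design point deserves emphasis. In the default configuration both
the trait baselines and the genotype frequencies depend on breed, so
breed confounds the pooled trait ~ genotype model: even with no
genotype effects, the pooled scan finds (real, breed-mediated)
associations. That is a property of the design, not a defect of the
test, and the workflow's step 4 shows it. Type-I calibration must
therefore be measured where the null actually holds:
`null_calibration_config()` keeps the genotype structure but applies
one set of trait baselines (the PH row) to all breeds, making trait
and genotype independent. Under it, the cell-level rejection rate of
the scan at $\alpha = 0.05$ and the df = 1 HWE test under $F = 0$
(p = 0.5, n = 500) both sit within Monte-Carlo tolerance of 0.05, and
a one-residual-SD additive effect at one locus is detected with
monotone LS means in well over 90% of replicates. The test suite runs
these at 200 scan replicates, 2000 HWE replicates and 200 power
replicates; the workflow script uses smaller counts as a quick
demonstration.

## Scope of reproduction

From the published per-breed genotype counts, every diversity
statistic is exactly recomputable, and 33 of the 35 population × locus
rows agree with the published table to within 0.005 on allele
frequencies, PIC, $H_E$ and $\chi^2$ simultaneously. The two
exceptions are documented data quirks, not model choices: one pooled
PIC cell is printed as 0.50, which exceeds the biallelic maximum of
0.375 and is almost certainly a transcribed $H_E$; and one $\chi^2$
cell does not recompute from its own printed counts (51.2 recomputed
vs 30.35 printed). The package reproduces the correct values and the
tests pin both discrepancies down rather than matching them.

The published association and breed-comparison tables, by contrast,
are functions of the undeposited individual hen records; their numeric
cells cannot be audited from the published material at all (one EMs
column even contains a letter-ordering surprise). They are covered
structurally — report shape, LS-means logic, letter logic — and by the
oracle-equivalence, calibration and recovery tests above, with no
attempt to match their numbers.

## Problem sizes and runtime

All simulations are sized to run on a single CPU in minutes: the
oracle-equivalence sweep uses 50-60 random designs of 6-60 samples;
calibration uses 200 null scans of the 117-hen design (11,200 cells)
and 2000 HWE replicates at n = 500; recovery uses 200 replicates each
for effect detection and baseline recovery. These sizes put the
Monte-Carlo standard error of each estimated rate at ≲ 0.005, well
inside the ±0.015 acceptance bands used in the tests.

## Known limitations

Single-locus, single-factor models only: no mixed models or REML, no
heritability estimation, no multi-locus or epistatic models, no
F-statistics, linkage disequilibrium or haplotype phasing. Variant
discovery performs no alignment itself and calls no indels. The letter
display is minimal only relative to its sweep order, as is standard
for insert-and-absorb letter algorithms.
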
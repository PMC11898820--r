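# npyassoc

SNP-marker diversity and marker–trait association analysis for
candidate-gene studies in laying hens, built around a published study
of seven coding-region SNPs in the neuropeptide Y (NPY) gene across
four hen breeds — two Thai native breeds (Pradu Hang Dum, Chee), a
black-bone breed and a commercial Hy-Line Brown layer — and eight
egg-production traits. It is written for animal-breeding researchers
who run candidate-gene panels: the same few computations (allele
frequencies, marker informativeness, Hardy–Weinberg testing, one-way
genotype models with letter displays) recur in every such study, and
this package implements them once, tested, with a simulator to
exercise the whole pipeline when raw records are unavailable.

## What it computes

For genotype counts $(n_{AA}, n_{Aa}, n_{aa})$, $n$ hens, per breed
and locus:

- allele frequencies by gene counting, $p = (2n_{AA} + n_{Aa})/2n$;
- expected heterozygosity $H_E = 2pq$ (uncorrected);
- polymorphism information content,
  $\mathrm{PIC} = 1 - (p^2+q^2) - 2p^2q^2$ (Botstein, biallelic);
- Hardy–Weinberg $\chi^2 = \sum (O - E)^2/E$ over the three genotype
  classes, no continuity correction, with df = 1 (standard) or df = 2
  (three-class goodness-of-fit convention) selectable.

For each trait and locus (or breed), the one-way fixed-effect model
$y_{ij} = \mu + g_i + e_{ij}$ by ordinary least squares:
least-squares means, overall F test, pairwise t comparisons on the
pooled residual variance (unadjusted / Bonferroni / Tukey), and
compact letter displays. Variant sites can be called from an aligned
FASTA of the coding region (IUPAC ambiguity codes as heterozygotes),
and synthetic studies with known structure are generated by
`sim_config()` / `generate_study()`.

## Worked example

The package ships the published per-breed genotype counts, which
determine every diversity statistic exactly:

```r
library(npyassoc)

gt  <- counts_to_genotype_table()      # 117 hens rebuilt from counts
div <- diversity_table(gt, populations = c("PH", "C", "BB", "LC"),
                       df_convention = "classes_minus_1")
rep <- format_diversity_report(div)
rep[rep$locus == "g.130 A>G",
    c("population", "n", "p", "q", "pic", "he", "chi2", "in_hwe")]
```

```
 population   n    p    q  pic   he  chi2 in_hwe
         PH  59 0.76 0.24 0.30 0.36 23.08     no
          C  20 0.83 0.18 0.25 0.29  0.36    yes
         BB  20 0.80 0.20 0.27 0.32  9.45     no
         LC  18 0.67 0.33 0.35 0.44 10.13     no
        All 117 0.76 0.24 0.29 0.36 41.55     no
```

Reading the SNP1 (g.130 A>G) block: the A allele dominates everywhere
(p = 0.67–0.83); the marker is reasonably informative in every breed
(PIC 0.25–0.35, below the biallelic maximum 0.375); and under the
df = 2 convention (critical value 5.99) only the Chee breed is in
Hardy–Weinberg equilibrium at this locus — the large Pradu Hang Dum
χ² (23.08) reflects its strong heterozygote deficit (8 observed
heterozygotes vs ≈ 21 expected).

The analysis workflow lives in `analysis/` as numbered scripts, each a
thin driver over the package:

```
analysis/01_simulate_study.R    simulate the 117-hen study      -> results/study/
analysis/02_discover_sites.R    variant discovery demo (FASTA)  -> results/discovery/
analysis/03_diversity.R         diversity + HWE classification  -> results/diversity/
analysis/04_association.R       breed summary + 56-cell scan    -> results/association/
analysis/05_calibration.R       type-I error and power checks   -> results/calibration/
```

Run them in order with `Rscript analysis/01_simulate_study.R`, etc.
Step 3 reproduces the published Hardy–Weinberg classification exactly
(C out of equilibrium only at SNP4; LC out only at SNP1–SNP2; BB in
equilibrium only at SNP6–SNP7; PH out at all seven loci).

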
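# ervfootprint

Endogenous retroviruses (ERVs) are the germline-integrated remnants of
past retroviral infections. Host genomes silence them, largely by CpG
methylation — and methylated cytosines deaminate over evolutionary time,
converting CpG to TpG (and, read from the complementary strand, to CpA).
A silenced provirus therefore accumulates a legible sequence footprint:
CpG depletion, mirrored TpG/CpA excess, trinucleotide-context structure in
what was lost, CpG-island architecture, and — where APOBEC3G rather than
methylation drove the G→A changes — a characteristic downstream-context
mutation bias.

`ervfootprint` is an R package for reading those footprints from
full-length proviral sequences and per-cytosine bisulfite reports, aimed
at viral genomicists comparing endogenous proviruses with their exogenous
counterparts. Everything takes and returns tidy data frames, results
support `tidy()`/`glance()`, and plot helpers are included.

## What it computes

- **D-ratios** (`d_ratio()`, `d_ratio_table()`): observed/expected motif
  frequencies. Trinucleotides use a first-order Markov expectation,
  `P_exp(XYZ) = P_obs(XY)·P_obs(YZ)/P_obs(Y)`; dinucleotides use the
  classical product form `P_obs(X)·P_obs(Y)` (CpG O/E). Strand-specific,
  N-aware, with explicit undefined flags.
- **Rank statistics** (`group_compare()`, `deamination_correlation()`,
  `meth_vs_oe_correlation()`): Mann-Whitney / Kruskal-Wallis + Dunn
  comparisons of D-ratios between variant classes, and the
  deamination-signature Spearman correlation (CpG vs mean TpG/CpA;
  CGC vs TGC/CAC).
- **CpG islands** (`window_profile()`, `call_islands()`): 100 bp
  sliding-window Gardiner-Garden O/E and GC%, islands as maximal unions
  of passing windows (O/E ≥ 0.6, GC ≥ 50, length ≥ 200 — or 100 for
  short proviruses).
- **Methylation summaries** (`site_methylation()`,
  `context_methylation()`, `provirus_track()`): per-site percents from
  Bismark-style cytosine reports, CGA/CGC/CGG/CGT context preference
  tests, binned provirus tracks and overall medians.
- **APOBEC3G hypermutation** (`classify_contexts()`, `hypermut_test()`,
  `hypermut_scan()`): context-stratified one-sided Fisher test of G→A
  enrichment against a consensus or supplied reference.
- **Motif enrichment** (`scan_motif()`, `sea_enrich()`,
  `bespoke_filter()`, `cgi_overlap_filter()`): exact-threshold PWM
  scanning, presence/absence Fisher enrichment between sequence sets with
  Bonferroni E-values, a strict all-vs-at-most-one significance rule, and
  CpG-island restriction of promoter-mark motifs.
- **Simulator** (`simulation_config()`, `simulate_lineages()`,
  `emit_cytosine_report()`, …): Markov-background proviruses with exact
  CpG O/E calibration, context-dependent methylation, generational
  deamination, sampled bisulfite reports, motif implantation.
- **Pipeline** (`run_pipeline()`): one YAML config in, one results
  directory of TSV/BED tables plus a reproducibility manifest out.

## Worked example

Simulate eight lineages (ancestors = exogenous, deaminated descendants =
endogenous), then ask the three headline questions:

```r
library(ervfootprint)
library(dplyr)

cfg <- simulation_config(length = 4000, n_lineages = 8, seed = 42)
bundle <- simulate_bundle(cfg, "demo")

tbl <- d_ratio_table(bundle$seqs, c("CG", "TG", "CA"))
d_ratio_medians(tbl)
#>   virus  variant_class motif     n median_d mean_d
#> 1 simERV endogenous    CA        8    1.19   1.20
#> 2 simERV endogenous    CG        8    0.629  0.662
#> 3 simERV endogenous    TG        8    1.23   1.18
#> 4 simERV exogenous     CA        8    0.988  0.992
#> 5 simERV exogenous     CG        8    1.03   1.01
#> 6 simERV exogenous     TG        8    0.973  0.973

glance(group_compare(filter(tbl, motif == "CG"), "d_ratio", "variant_class"))
#>   method       statistic  p_value n_groups n_total effect_direction
#> 1 mann-whitney         0 0.000155        2      16               -1

deamination_correlation(filter(tbl, variant_class == "endogenous"))
#> <erv_cor_test> spearman: r = -0.9048, p = 0.004563, n = 8
```

Endogenized descendants are CpG-depleted relative to their ancestors
(median CpG D-ratio 0.63 vs 1.03, Mann-Whitney p ≈ 1.6e-4) with the
depletion mirrored by TpG/CpA gain, and across descendants the CpG
D-ratio anticorrelates with mean TpG/CpA (Spearman r ≈ −0.90) — the
deamination signature.

The bundle also writes a sampled cytosine report for the first
descendant:

```r
trk <- provirus_track(read_cytosine_report(bundle$cytosine_report),
                      seq_length = 4000)
trk
#> <erv_meth_track> des_1: 40 bins of 100 bp, overall median 7.7%
```

The low median is itself the mechanism speaking: in an old lineage most
*methylated* CpGs have already deaminated away, so the CpGs that survive
to be assayed are biased toward never-methylated sites.

## Coordinates and conventions

Internal coordinates are 0-based half-open (BED-compatible); cytosine
reports stay 1-based at the I/O boundary. Non-ACGT symbols become `N` on
read and are excluded from all k-mer statistics. Significance is 0.05
throughout. See the vignette
(`vignettes/endogenization-footprints.Rmd`) for the models, assumptions,
design decisions and limitations.
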
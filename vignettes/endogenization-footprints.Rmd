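---
title: "Detecting epigenetic sequence footprints of retroviral endogenization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epigenetic sequence footprints of retroviral endogenization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervfootprint)
library(dplyr)
```

## The problem

When an exogenous retrovirus integrates into the germline and becomes an
endogenous retrovirus (ERV), the host genome silences it, largely through
CpG methylation. Methylated cytosines deaminate to thymine at an elevated
rate, so over evolutionary time a silenced provirus bleeds CpG
dinucleotides: each deamination converts a CpG to TpG on one strand, which
the complementary strand reads out as CpA. The mutational history of
silencing is therefore legible in the sequence itself — as CpG depletion,
as compensating TpG/CpA excess, and as context structure (which CGN
trinucleotides lost most). `ervfootprint` implements the estimators needed
to read that history and a mechanistic simulator to validate them.

## The core statistic: the D-ratio

For a motif $m$ in a sequence, the D-ratio is the observed frequency over
the frequency expected from a background model,

$$D(m) = \frac{P_{\mathrm{obs}}(m)}{P_{\mathrm{exp}}(m)}.$$

For trinucleotides the expectation uses a first-order Markov model of
conditional probabilities,

$$P_{\mathrm{exp}}(XYZ) =
  \frac{P_{\mathrm{obs}}(XY)\,P_{\mathrm{obs}}(YZ)}{P_{\mathrm{obs}}(Y)},$$

so that $D(XYZ)$ measures structure beyond dinucleotide composition. For
dinucleotides a first-order expectation would be identically 1, so the
package uses the classical zeroth-order product
$P_{\mathrm{obs}}(X)\,P_{\mathrm{obs}}(Y)$ — the standard CpG O/E
definition. The two conventions are deliberate and never conflated; the
dinucleotide choice matters because all headline CpG O/E values rest on it.

Counting details that affect exactness on short sequences: frequencies use
per-k window denominators (the number of N-free windows of that length),
counting is linear and strand-specific, and no reverse-complement folding
is applied anywhere — the deamination analysis depends on TpG and CpA
being distinct observations. Windows containing `N` are excluded from both
numerator and denominator. When $P_{\mathrm{exp}} = 0$ the result carries
an explicit undefined flag rather than a silent 0 or infinity.

```{r dratio}
seqs <- tibble(
  id = c("young", "old"),
  virus = "demoERV", variant_class = c("exogenous", "endogenous"),
  seq = c(gen_markov_sequence(4000, 1.0, seed = 11),
          gen_markov_sequence(4000, 0.5, seed = 12))
) |> mutate(length = nchar(seq))

d_ratio_table(seqs, c("CG", "TG", "CA")) |>
  select(seq_id, motif, p_obs, p_exp, d_ratio)
```

Group aggregation uses the median (`d_ratio_medians()` also emits the mean
for comparison), matching how grouped O/E values are conventionally
summarized; whether published per-virus cells are medians or means across
replicates is not always stated, and the median is the assumption here.

## Comparative statistics

`group_compare()` applies a two-sided Mann-Whitney U test for two groups
and Kruskal-Wallis plus Dunn's pairwise z-tests for three or more. The
Mann-Whitney switches from the exact null distribution to the
tie-corrected normal approximation at a combined n of 20 — typical
endogenous/exogenous set sizes straddle the range where exactness is
feasible. Dunn's p-values are Bonferroni-adjusted by default (the
convention of mainstream graphing software), with Holm available.
Significance is fixed at 0.05 throughout.

`deamination_correlation()` operationalizes the deamination signature as
Spearman's rank correlation between the CpG D-ratio and the per-sequence
arithmetic mean of the TpG and CpA D-ratios. The mean is a design choice —
how the two product motifs are combined is not standard — and
`combine = "separate"` reports each correlation individually for anyone
who prefers not to average. The same function serves the
trinucleotide-level signature (CGC against TGC/CAC).

`meth_vs_oe_correlation()` relates per-virus median CpG methylation to
median CpG O/E. Pearson's r is reported after Shapiro-Wilk normality
checks on both margins; if either fails, the function falls back to
Spearman and says so in the result rather than reporting a Pearson
coefficient whose assumption failed. A labelled point can be excluded and
is carried as an annotated outlier — the motivating case is a very recent
integrant that is heavily methylated but has not yet had time to lose
CpGs, which sits off the trend the older integrants form.

## CpG islands

`window_profile()` slides a 100 bp window (the conventional size) and
records GC% and the Gardiner-Garden window O/E,
$\#CG \cdot w / (\#C \cdot \#G)$. `call_islands()` marks windows passing
both thresholds (O/E ≥ 0.6, GC ≥ 50), merges passing windows into maximal
unions of their spans, filters by minimum length (200 bp by default;
100 bp for short proviruses whose islands fragment), and re-measures GC
and O/E over each merged interval.

The union-of-passing-windows definition is chosen over smoothing-based
callers because it is deterministic and directly testable: output islands
are disjoint, sorted, satisfy their thresholds when re-measured from
scratch, behave monotonically in every threshold, and shift exactly under
sequence translation. One consequence worth knowing: a window passes as
soon as half of it overlaps a GC-rich block, so called islands extend up
to half a window beyond the underlying block on each side, and a block
shorter than the length cutoff can still produce a reportable island once
widened. Smoothing-based implementations differ on exactly these edge
cases; the divergence is documented rather than hidden.

## Methylation summaries

`read_cytosine_report()` ingests the strand-resolved 7-column per-cytosine
report dialect (1-based positions at the I/O boundary; everything internal
is 0-based half-open). `site_methylation()` computes per-site percent with
a coverage floor; plus- and minus-strand calls stay separate by default
because the report is strand-resolved — `collapse_dyads = TRUE` merges
complementary CpG calls when dyad-level values are wanted. The default
coverage floor is 1 (permissive, matching bulk summaries); the validation
properties all use ≥ 20. Trinucleotide context is taken from the report's
own column, never re-derived, so no reference genome is needed.

`context_methylation()` summarizes CGA/CGC/CGG/CGT site distributions and
runs the cross-context rank test — the question being whether
methyltransferase activity shows a context preference (CGC/CGG elevated is
the expected pattern). `provirus_track()` bins coverage-weighted means
across the provirus and reports the overall per-site median, the x-axis of
the methylation-versus-O/E comparison. Medians are over sites, not over
integrant copies, which is an assumption: aggregated reports do not say
which was intended.

## Hypermutation

APOBEC3G attacks retroviral replication intermediates and leaves
plus-strand G→A changes in a downstream `G R D` context (R ∈ {A,G},
D ∈ {A,G,T}). `classify_contexts()` stratifies reference G positions by
that context (the convention is pinned but overridable for other APOBEC
family members), and `hypermut_test()` applies the one-sided Fisher's
exact test for mutation enrichment in the primary stratum. The reference
defaults to the column-wise majority consensus of the aligned set with
alphabetical tie-breaking — deterministic, and recorded in the output
metadata since the choice of reference is an assumption. Alignment itself
is out of scope; inputs must be pre-aligned.

`hypermut_calibration()` measures the test's operating characteristics by
simulation. On an 8 kb background at equal G→A rates of 0.05 in both
strata the measured type-I error sits below the nominal 0.05 (exact-test
conservatism); at 0.15 versus 0.01 power is essentially 1. The equal-rate
value of 0.05 is this package's choice of null simulation intensity — high
enough that both strata see mutations, low enough to stay in the regime
real alignments show.

## Motif enrichment

`scan_motif()` scores both strands with log-odds (bits) against the
motif's background and calls hits above the score whose null exceedance
probability is at most `threshold_quantile` (default 1e-4), computed
exactly by dynamic programming over the discretized per-column score
distributions (millibit grid; the same integer grid scores the sequence,
so threshold and scores are consistent). For a sharp 10-column consensus
motif this threshold typically admits perfect and single-mismatch matches.

`sea_enrich()` reduces each sequence to presence/absence (≥ 1 hit) and
applies a one-sided Fisher test between sets, with a Bonferroni E-value
(`p × motifs tested`). This fixed-threshold presence design is a
deliberate simplification of optimal-threshold enrichment machinery; what
the downstream biology consumes — the presence pattern — is preserved
exactly, including the strict rule implemented by `bespoke_filter()`: a
motif counts only if (E ≤ 0.05) and it is present in *all* primary
sequences with at most one control, or all but one primary with zero
controls. `cgi_overlap_filter()` additionally restricts hits of
promoter-associated marks (H3K4me3, H3K27ac, H3K27me3) to called CpG
islands; other marks pass through.

## The simulator: what it emulates and what it does not

`simulation_config()` fixes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `length` | 8000 bp | full-length provirus scale |
| `target_cpg_oe` | 1.0 | undepleted background at integration |
| `context_meth_prob` | CGC 0.9, CGG 0.8, CGA 0.5, CGT 0.5 | methyltransferase context preference |
| `deamination_rate` | 0.05/generation | per-methylated-CpG loss rate |
| `generations_range` | 1–40 | spread of lineage ages |
| `n_lineages` | 20 | panel size |
| `coverage` | 30 | mean reads per cytosine |

The Markov background is uniform except the C→G transition, solved with
`uniroot` against the chain's stationary distribution so the stationary
CpG O/E equals the target exactly (the naive linear scaling of the
transition probability is biased by ~15% at target 0.5). Methylation is
dyad-symmetric; deamination picks a strand with probability ½ each (a
`minus_strand_bias` knob exists to emulate APOBEC-like asymmetry); a
deaminated site leaves the CpG pool and cannot fire again. Survival after
$g$ generations at rate $r$ is exactly $(1-r)^g$ per methylated site,
which the tests check against $0.9^{10} \approx 0.349$. Bisulfite
evidence is Poisson coverage with binomial methylated counts.

All randomness flows from one mandatory seed through fixed per-stream
sub-seeds, so sub-streams are independently reproducible.

Deliberately absent: back-mutation, selection, indels, recombination,
multiple integration waves, bisulfite conversion failure, and mapping
artifacts. Passing tests therefore demonstrate that the estimators recover
the deamination mechanism when it is the only force acting — they do not
demonstrate robustness to the confounders of real alignments, which is
the appropriate reading of every simulation-based result here.

## End-to-end check

```{r panel}
panel <- simulate_lineages(simulation_config(length = 3000, seed = 7))
des <- tibble(id = paste0("des_", panel$lineage), virus = "simERV",
              variant_class = "endogenous",
              length = nchar(panel$descendant), seq = panel$descendant)
deamination_correlation(d_ratio_table(des, c("CG", "TG", "CA")))
```

Lineage age spreads CpG loss, and the CpG D-ratio anticorrelates strongly
with the mean TpG/CpA D-ratio — the signature the comparative module is
designed to detect. (This chunk uses 3 kb sequences to keep the vignette
quick; the validation suite runs the full 8 kb default.)

## Numerical choices and problem sizes

- D-ratio equivalence against a brute-force string-scan oracle is exact to
  1e-12 over 200 random sequences up to 500 bp.
- Generator calibration is checked at L = 10,000 (±0.05 of target).
- The hypermutation calibration uses 2,000 null and 500 alternative
  simulations on an 8 kb reference.
- Exact tests (Mann-Whitney, Fisher) are verified against full
  enumeration at small margins; ties fall back to corrected asymptotics.
- All undefined quantities (zero expectations, constant correlations)
  carry explicit flags; output tables keep flagged rows.

## Known limitations

- Island calls diverge from smoothing-based callers at block edges, as
  described above.
- The enrichment stage does not learn motifs and does not model
  position-specific priors; backgrounds above order 0 are out of scope.
- Bisulfite read alignment, deduplication and M-bias trimming are
  upstream of this package: it consumes reports, it does not produce
  them.
- Reproducing published per-virus values requires the corresponding
  public sequence sets; the package ships only generated data.
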
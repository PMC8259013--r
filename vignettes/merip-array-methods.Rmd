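---
title: "Methods and design of the meripArray pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the meripArray pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripArray)
```

# The measurement model

An m6A epitranscriptomic array measures each RNA sample twice: the
anti-m6A immunoprecipitated fraction (IP, Cy5) and the supernatant
(SUP, Cy3) hybridize as the two channels of one array. For transcript $t$
in sample $s$ the idealized signals are

$$\mathrm{IP}_{ts} = A_{ts}\, m_{ts}\, 2^{a_s^{IP}},\qquad
  \mathrm{SUP}_{ts} = A_{ts}\,(1 - m_{ts})\, 2^{a_s^{SUP}},$$

where $A_{ts}$ is the linear transcript abundance, $m_{ts}\in(0,1)$ the
methylation fraction, and $a_s^{c}$ a per-sample, per-channel log2 scaling
(labeling yield, hybridization, scanner gain). Exogenous spike-in RNAs of
fixed amount are added to both fractions, so their signal isolates
$a_s^{c}$; this is what makes the design identifiable.

**Normalization.** With $f(s,c)$ the mean log2 spike-in intensity of
array/channel $(s,c)$ and $\bar F$ the grand mean of all $f(s,c)$,
normalized log2 intensities are $\log_2 x - f(s,c) + \bar F$. Subtracting
$f(s,c)$ removes $a_s^c$; recentring by $\bar F$ (rather than to zero)
keeps values on an intensity-like scale so that percent modification and
expression remain interpretable. A consequence worth knowing: rescaling one
sample's raw intensities shifts $\bar F$, which multiplies *all* normalized
intensities by one common constant. Percent modification is exactly
invariant under such rescaling; expression is invariant up to that single
global factor, so all expression ratios and fold changes are unaffected.

**Quantification.** Percent modification is
$m = 100\,\mathrm{IP}/(\mathrm{IP}+\mathrm{SUP})$ on *linear* normalized
intensities (percentage semantics; no log transform), bounded in
$[0, 100]$ by construction. Expression defaults to the channel sum
$\mathrm{IP}+\mathrm{SUP}$: the total RNA is what the IP step splits into
the two measured pools. Whether a two-channel study's "expression" profile
should instead be the supernatant channel alone is genuinely ambiguous —
descriptions of this design use both readings — so
`expression_level(mode = "supernatant")` is provided and the choice is
recorded in the output metadata; the default is the sum because it is
invariant to the methylation fraction itself.

# Differential calling

Per comparison (e.g. M1-L vs M0-L), each transcript gets a linear fold
change of group means and a **pooled-variance** (equal-variance) two-tailed
Student's $t$ with $n_a + n_b - 2$ degrees of freedom — the classical
"Student's t" reading rather than Welch, which matters at $n = 3$ vs 3
($df = 4$). Calls use FC $\ge$ 1.5 or $\le$ 0.7 (inclusive boundaries,
asymmetric as conventionally printed: 0.7, not $1/1.5$) and raw
$P < 0.05$ (strict). No multiplicity correction enters the calls; a
Benjamini–Hochberg column is emitted for information. Tests run on the
linear percent-modification and expression values to mirror the reported
quantities.

Numerical edge cases: a zero reference mean is floored at `mean_floor`
($10^{-6}$, flagged) so the fold change stays finite; zero pooled variance
yields $P = 1$ for equal means and the smallest positive double (flagged
`degenerate`) for unequal means, keeping $P \in (0, 1]$. Spike-in probes
are excluded from testing.

Hierarchical clustering of the differential matrix uses Euclidean distance
and average linkage — the method names no metric, and this pair is the
common display default — with `stats::hclust`, whose deterministic
first-occurrence tie handling we inherit.

# Quadrants, concordance and the printed report

Crossing the methylation call (hyper/hypo) with the expression call
(up/down) yields four quadrants; transcripts missing either call are
`unassociated`. "Negative correlation" across two comparisons is
operationalized as the **fully opposite quadrant** (both directions flip:
Hyper-Up ↔ Hypo-Down, Hyper-Down ↔ Hypo-Up), an involution. The
concordance denominator is the number of transcripts quadrant-assigned in
*both* comparisons; because published reports of this kind rarely state
their denominator, both `n_opposite` and `n_both` are exposed rather than
a single ratio. Report percentages are rounded to one decimal with ties
going away from zero, matching how such tables are typically printed
(base R's round-half-even would render some printed values differently).

# Fisher's exact over-representation

`fisher_exact(k, n_query, K, N)` computes the two-sided P by the
minimum-likelihood rule: summing the hypergeometric probabilities of all
tables with the observed margins whose probability does not exceed the
observed table's. Probabilities within a relative $10^{-7}$ of the
threshold count as ties — the dominant convention, shared by
`stats::fisher.test`, which serves as an independent cross-check in the
tests alongside a `choose()`-based enumeration oracle. The enrichment
score is $-\log_{10} P$, strictly decreasing in $P$, so ranking by score
equals ranking by ascending $P$ with ties broken by set name.

The default universe is the intersection of array coding-gene symbols with
genes appearing in at least one gene set: array-aware (a gene that cannot
be queried should not inflate the background) yet restricted to testable
genes. `build_universe()` also offers all-array and all-GMT modes since
the background of any given study is rarely stated.

# lncRNA genomic context and cis linkage

Coordinates are 0-based half-open (BED) externally and 1-based `GRanges`
internally. Context classification is total and single-valued by
precedence: exon overlap (same strand) > intron overlap (same strand,
within the gene body) > natural antisense (opposite strand, exon hit) >
intronic antisense > bidirectional > intergenic (fall-through, "between
two coding genes"). *Bidirectional* means divergent transcription start
sites within 1 kb on opposite strands without overlap — the class is
conventionally named without a distance, and 1 kb is the common promoter
definition; it is configurable (`bidirectional_gap`).

Cis linkage emits every same-chromosome gene whose **boundary gap** is at
most the 300-kb window, inclusive ($\le 300{,}000$; a gap of 300,001 bp is
out). A boundary gap — zero for touching or overlapping intervals — rather
than TSS-to-TSS distance is the documented choice because "within a
window" statements about neighboring genes usually refer to interval
proximity. The implementation uses interval overlap queries
(`GenomicRanges::findOverlaps` with `maxgap`), but the contract is output
equality with an all-pairs brute-force scan, which the tests enforce on
every generated layout.

# qPCR arithmetic

MeRIP percent input adjusts the input-tube Ct by $-\log_2(1/\text{
fraction})$ for the reserved input fraction (default 0.1; studies rarely
print theirs, so it is an explicit argument) and reports
$100 \cdot 2^{\,\mathrm{Ct_{input,adj}} - \mathrm{Ct_{IP}}}$. Relative
expression uses $2^{-\Delta\Delta Ct}$ against a GAPDH-like reference.
SEM and the two-group Student's $t$ are computed on the $\Delta$Ct scale,
where values are closer to normal; folds are reported as transformed
means. Identities that pin the arithmetic: self-comparison gives fold 1;
one cycle of Ct difference halves percent input; forward and reverse folds
multiply to 1.

# What the synthetic generator emulates

The generator mirrors the measurement model above at reduced scale.
Defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `n_mrna`, `n_lncrna` | 2200, 800 | ~3000 transcripts, preserving the roughly 2.6:1 mRNA:lncRNA ratio of a 38k-probe rat array at a size the full suite can sweep repeatedly |
| `groups`, `n_replicates` | M0-L/M1-L/M2-L, 3 | the three-phenotype, n = 3 design being emulated |
| `n_spikein` | 24 | commercial arrays carry dozens of control probes; averaging over 24 makes the normalization-factor error small against measurement noise |
| `baseline_log2_mean/sd` | 10, 1.5 | typical dynamic range of log2 array intensities |
| methylation Beta(α, β) | 2, 2 | bounded, symmetric, mid-weighted fractions; effects act on the logit scale so fractions stay in (0, 1) |
| `array_effect_sd` | 0.3 | per-sample/channel log2 scaling spread large enough that unnormalized analyses visibly fail |
| `noise_log2_sd` | 0.1 | multiplicative log-normal measurement noise, the standard array error model |

Design decisions that shape what the tests can show:

* **Noise is applied independently per measured intensity** (per channel),
  not to the shared abundance term. A shared-only noise term would cancel
  in the IP/(IP+SUP) ratio, leaving every within-group methylation
  variance zero and making null calibration of the $t$ test meaningless.
  Array effects, by contrast, are shared by all probes of one
  sample/channel including spike-ins — precisely what normalization needs.
* **Planted methylation effects land on non-saturated transcripts.**
  Baseline fractions for methylation-effect targets are drawn from the
  Beta(2, 2) truncated to [0.2, 0.6]. A +2-logit shift on a transcript
  already at $m_0 > 0.61$ produces a percent-space fold change below 1.5
  and is undetectable at the call thresholds by construction; planting
  where the effect is biologically visible is also what a real
  perturbation of a partially methylated transcript looks like.
* **Effect panel.** Methylation shifts (|logit| in [2, 3]) target 4% / 2%
  of transcripts in the second/third group; expression shifts (|log2| in
  [1, 2]) another 6% / 4%. Half the methylation targets carry a joint
  expression shift cycling through the four sign combinations, so all
  quadrants are populated; because a shift planted in one group is hyper
  against the baseline group and hypo in the reverse-order comparison,
  sign-flip concordance arises without separate machinery.
* **One probe per transcript.** Aggregation rules across probes are
  design-specific and unstated for the emulated platform, so none is
  invented.
* **Determinism.** One master seed drives every stage through fixed
  offsets; identical config + seed yields byte-identical output files.
* **Genome layout.** One coding gene (3–5 exons, exons flanking both gene
  boundaries) per mRNA probe, 110 genes per synthetic chromosome at 140-kb
  spacing; lncRNAs cycle through placements realizing all six context
  classes whenever at least six are generated (fewer triggers a coverage
  warning, not an error).

What the generator does **not** emulate — and hence what passing tests do
not establish about real arrays: probe-level replication and
cross-hybridization, dye bias beyond a per-channel scaling, background and
spatial artifacts, IP-efficiency variation between samples (an m6A
spike-in mixture could calibrate this; no correction is applied),
biological replicate variance beyond the measurement noise term, and any
correlation structure between transcripts.

# Problem sizes and calibration checks

The shipped suites exercise: exhaustive Fisher agreement on all 2×2
tables with $N \le 60$; 1000 random 3-vs-3 pooled-$t$ comparisons against
the closed form plus null calibration (significant fraction within
[0.03, 0.07] at $\alpha = 0.05$) over 2000 null transcripts for each of
ten seeds; planted-effect recovery over twenty default-scale simulations
(sensitivity $\ge 0.9$ at |logit shift| $\ge 2$, false-discovery
proportion $\le 0.15$); brute-force equality of cis linkage and context
round-trips on generated layouts with exact 300,000/300,001 bp boundary
checks; and a 200-seed Monte-Carlo of 2^−ΔΔCt recovery of a true 2-fold
change (median within 20% at $n = 3$, Ct sd 0.2). These sizes are the
package's own test design, chosen to make each property estimable with
comfortable margins.

# Known limitations

Raw-P calling with an FC filter is reported faithfully but is not a
modern moderated analysis; limma-style empirical Bayes would borrow
strength across transcripts and is deliberately out of scope. Paired
designs, batch covariates, amplification-efficiency (Pfaffl) correction
and multi-reference qPCR normalization are not implemented. Symbol-level
joins assume a consistent annotation release.
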
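---
title: "Methods: cross-omics differential expression and fold-change concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-omics differential expression and fold-change concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concord)
```

## The problem

In species without a sequenced genome — here the design is modelled on a
dopamine-agonist study in goldfish hypothalamus — transcriptomic and
proteomic measurements cannot be joined through genome annotation. The
transcriptome comes from a cDNA microarray of ESTs; the proteome from iTRAQ
4-plex LC-MS/MS searched against a related-species database. The two layers
share no common identifier, so differentially expressed (DE) ESTs must be
matched to DE proteins by *translated sequence alignment*, and only then can
one ask the biological question: do mRNA and protein changes agree in
direction under the same treatment?

`concord` implements that whole chain as testable units: a synthetic-data
generator with known ground truth, microarray normalization and DE calling,
iTRAQ protein quantitation, translated matching, and the concordance
statistics, plus a packaged transcription of the published pair table so the
headline numbers can be recomputed exactly.

The two treatment arms follow the iTRAQ plex layout throughout: label 114 is
the untreated control, label 115 the D2 agonist (LY), label 117 the D1
agonist (SKF).

## Microarray normalization and DE calling

Each array measures a treatment sample against a common reference pool, so
per-spot log ratios are directly comparable across arrays (a *one-class*
design). Arrays are represented as point configurations in the (A, M) plane
— A the mean log2 intensity, M the log2 ratio — and aligned by Generalized
Procrustes Analysis (GPA): translation (centering), isotropic scaling to
unit centroid size, and rotation onto an iteratively refined consensus.
Aligned configurations are mapped back through the mean centroid size and
grand centroid so output stays on the intensity scale. Dye-reversal arrays
are re-oriented (channels swapped back) before alignment.

Numerical choices, made here because the published description fixes none of
them: convergence is declared when the squared consensus change drops below
`tol = 1e-13` (tight enough that re-normalizing normalized data is a no-op
to ~1e-6 relative); scaling is isotropic; rotations are proper (determinant
+1, no reflection); the iteration cap is 200 and the consensus residual
sum of squares is recorded per iteration (it is non-increasing, which the
test suite checks on random inputs).

DE calling uses the one-class SAM statistic. Duplicate spots are averaged
per array first (standard practice; the collapse rule is not stated in the
source design). For gene $i$ with mean log ratio $\bar r_i$ and standard
error $s_i$,

$$ d_i = \frac{\bar r_i}{s_i + s_0}, $$

with the fudge factor $s_0$ defaulting to the 5th percentile of the $s_i$
distribution. That default is stable on small gene counts; the full
coefficient-of-variation minimization over $s$-quantile windows is available
via `s0_method = "cv-min"`. A gene with zero scatter and $s_0 = 0$ gets
$d = \pm\infty$ and deterministically ranks above all finite statistics; a
gene with fewer than two finite replicates is flagged and excluded.

Null distributions come from sign flips of whole replicate arrays: under the
null the log ratios are symmetric about zero, so negating an array is a
symmetry of the data. With $k$ arrays there are $2^k$ flip patterns and the
requested number of permutations samples them with replacement. Flipping
individual observations instead would leave every strong gene reproducing
its own $|d|$ in an eighth of the permutations (all four signs agreeing), which
floors attainable q-values at ~0.125 for a four-array design; whole-array
flips avoid this, and the per-gene q uses the *median* false-positive count
across permutations precisely so the two degenerate patterns (identity and
global negation) cannot dominate. A step-up pass makes q monotone
non-increasing in $|d|$ rank. Transcripts with $q < 0.05$ (strict) are
selected, and ratios are reported as signed fold changes: $+r$ for
$r \ge 1$, $-1/r$ otherwise, with the boundary $r = 1$ mapped to $+1$.

## iTRAQ protein quantitation

PSMs are filtered before quantitation: identification confidence at least
0.95 (the conventional 1.3 on the $-\log_{10}(1-c)$ score scale), summed
signal-to-noise strictly greater than 9, and no peptides shared between
proteins. Identification error is monitored with a reversed-database decoy
FDR — decoys above a score threshold divided by targets above it; the
estimate is reported as-is, without monotonization.

For each protein and treatment channel, per-PSM log2 ratios against label
114 are averaged arithmetically (the log scale treats up- and
down-regulation symmetrically, matching the reciprocal fold-change
convention). With $n$ spectra, mean $m$ and standard error $SE$:

* ratio $= 2^m$;
* error factor $EF = 2^{t_{0.975,\,n-1} \cdot SE}$, so the true ratio lies
  in $[\mathrm{ratio}/EF,\ \mathrm{ratio} \times EF]$ with 95% confidence;
* p-value = two-sided one-sample t-test of $m$ against 0, the exact dual of
  the EF interval ($p < 0.05$ iff 1 lies outside it).

Proteins with three or more spectra are tiered "confident", with exactly two
"reported"; a single usable spectrum refuses quantitation with the reason
class "peptide signal was too low". Zero scatter at $n \ge 2$ gives
$EF = 1$, $p = 0$, and a flag. Selection is strict $p < 0.05$ in at least
one treatment with no multiple-testing correction, mirroring the original
selection of 42 proteins from 621; Benjamini–Hochberg adjustment is
available behind `bh_adjust` because the source description is ambiguous
about whether its p-values were FDR-adjusted — both outputs are offered,
neither asserted. An optional median-centering bias correction
(`bias_correct`) is off by default since it is not part of the published
procedure.

## Translated matching

DE protein sequences form a searchable database ($n$ = total residues). Each
DE EST is translated in all six frames (stops as `*`, N-containing codons as
`X`) and aligned to every database protein by Smith–Waterman local alignment
with BLOSUM62 and affine gaps (open 11, extend 1 — the BLAST defaults for
protein search). Alignments never cross a stop codon: frames are split into
stop-free segments and the best segment wins. Significance uses the
Karlin–Altschul formula

$$ E = K m n e^{-\lambda S}, \qquad \lambda = 0.267,\ K = 0.041, $$

the published gapped-BLOSUM62 constants, with $m$ the translated frame
length; the edge-effect length correction is omitted — at these database
sizes (tens of proteins) the thresholds are order-of-magnitude decisions.
The full dynamic-programming search replaces a seeded heuristic aligner
deliberately: a desk-scale database makes exact alignment affordable and
exactly testable against an independent oracle. Hits are kept at
$E \le 10^{-5}$ and flagged annotation-grade at $E \le 10^{-8}$, the two
thresholds used for the published table; one best hit per EST, ties broken
by accession then frame order. Coordinates are 0-based half-open internally.

When several ESTs match one protein, "similar expression" is interpreted as
sign agreement in every treatment where both are measured: similar
duplicates collapse to the EST with the largest absolute fold change;
opposite signs — or measurement under disjoint treatments only — keep all
ESTs, flagged starred, since they may represent distinct genes. This
reproduces the starred duplicate rows of the published table.

## Concordance statistics

The pair table has one row per retained (protein, EST) match, plus rows for
DE proteins with no matched mRNA; absent fold changes stay absent and are
never imputed. For a treatment, agreement counts only rows where *both*
layers carry a fold change; the fraction is undefined (not zero) with no
pairs. Shared-entity counts and Venn-style counts count each entity once
across treatments. Rows whose protein and mRNA fold changes exist only under
different treatments contribute to shared entities but to no treatment's
pair count — this is what reconciles 21 shared entities with 14-and-7-scale
per-treatment denominators. Starred duplicate rows each contribute their own
pair.

Recounting the packaged table's SKF column yields 15 rows with both fold
changes present against the externally stated denominator of 14 (the
agreement numerator, 8, reproduces exactly; with the recount the fraction is
53% rather than 57%). Which row the original count excluded is not
identifiable, so `concordance_summary` surfaces both numbers in a
`denominator_note` rather than silently adopting either.

A simple null test accompanies the observed agreement: mRNA signs redrawn
i.i.d. with probability 1/2 ("independent random sign pairing"), with the
exact two-sided binomial($n$, 0.5) p-value returned alongside. The i.i.d.
scheme (rather than permutation of the observed sign vector without
replacement) is chosen deliberately so the Monte-Carlo estimate converges to
the binomial reference.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions: two treatments; per gene a true
mRNA and protein log2 effect per treatment; four replicate arrays per
treatment against a common reference pool, the fourth a dye reversal; genes
printed in duplicate; multi-spectrum peptide evidence per protein with
lognormal reporter noise; reversed-sequence decoy PSMs.

Defaults and their origins:

* `effect_size_log2 = 1`: all nonzero effects have fixed magnitude with a
  random sign. A fixed magnitude makes sign concordance the single
  controlled quantity, which is what the downstream estimator is tested on;
  1 log2 unit (2-fold) sits in the middle of the published fold-change range
  (1.1–8.6).
* `concordance_rate`: probability that a gene DE in both layers shares its
  effect sign across layers.
* `overlap_rate = 0.5`: fraction of DE-protein genes drawn from the DE-mRNA
  set. The published data has 21 of 42 DE proteins with a matched DE mRNA;
  without this control the both-layer set — the only place `concordance_rate`
  acts — would be the tiny random intersection of the two DE sets.
* `spectra_per_protein = 14` (Poisson mean): the source experiment recorded
  ~8.6k spectra over ~620 identified proteins, ~14 per protein. Confidence
  scores are Beta(8,1) for targets and Beta(1,8) for decoys — separable but
  overlapping, so the decoy-FDR estimator is exercised non-trivially; only
  about a third of target PSMs clear the 0.95 confidence filter, which is
  why a realistic spectral density matters for the n ≥ 2 quantitation floor.
* `reporter_cv = 0.25`, `array_sd = 0.2` (log2 sd, lognormal): multiplicative
  noise keeps intensities positive and is the standard model for intensity
  data; values are typical mid-range technical CVs for the two platforms.
* `decoy_fraction = 0.1` of all PSMs; tryptic digestion with no missed
  cleavages and a 6–30 residue window.
* One RNG stream per output table at a fixed offset from the master seed, so
  adding arrays never perturbs the PSM simulation and every output is
  bit-reproducible from `seed`.

Deliberately *not* modelled: pooling variance (the source pooled three
hypothalami per RNA tube but used single hypothalami per iTRAQ label; the
generator treats one biological unit per replicate), raw spectra, retention
times and SCX fractionation, missed cleavages, isotope-impurity cross-talk,
print-tip or scanner spatial effects, background subtraction, and serum
hormone data. Passing tests on synthetic data therefore demonstrate
statistical correctness of the estimators under the stated noise model, not
robustness to every artefact of real arrays or spectra.

## Problem sizes used by the checks

The test suite exercises: ground-truth recovery at 1000 genes; SAM
calibration on 20 global-null repeats of 1000 genes × 4 arrays and full
recall at effect 4 log2 with sd 0.1; error-factor coverage on 2000 proteins
with 5 spectra and log2 noise 0.3 (the same computation
`scripts/acceptance.R` reports); alignment equality with an independent
exhaustive DP oracle up to length 12; and full-pipeline concordance recovery
at rates 0.2/0.5/0.8 with 240 genes. These sizes are the package's own
choices: large enough that binomial sampling bounds are informative, small
enough that the whole suite runs in about a minute and a half.

## Known limitations

* The GPA variant is fixed (isotropic scaling, proper rotations); the
  original normalization's exact options are unknown.
* Karlin–Altschul constants are the published gapped-BLOSUM62 values without
  length correction; E-values are comparable to, not identical with, BLAST's.
* The SAM q-value uses no $\pi_0$ estimate (the null-gene proportion is
  taken as 1), making q conservative when many genes are DE.
* With four arrays the permutation null has only 16 distinct patterns;
  q-values are correspondingly grainy.
* The EF-based p-value assumes approximately normal PSM log ratios; heavy
  tails inflate the error factor rather than the error rate.
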
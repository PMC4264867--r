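---
title: "Measuring the functional cost of miRNA seed-region mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the functional cost of miRNA seed-region mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseed)
```

## The question and the model

A mature animal miRNA pairs with its mRNA targets mainly through the seed
region, the 7 nucleotides at mature positions 2–8 (1-based, inclusive —
every coordinate in this package follows that convention). Because target
recognition is concentrated in so short a window, the "functional cost" of a
seed mutation — how much of the regulated target spectrum is lost or
replaced — can be studied combinatorially: compare the predicted (or
observed) target sets of miRNA pairs whose seeds differ by 0, 1, ..., 7
nucleotides.

`mirseed` operationalizes this with three statistics:

* the **Hamming distance** between two seeds (the number of substitutions
  needed to turn one into the other), with mismatch positions reported in
  mature coordinates;
* the **cosine similarity** of two gene sets,
  $\mathrm{cos}(A,B) = |A \cap B| \,/\, \sqrt{|A|\,|B|}$, a score in [0, 1]
  whose square-root normalization damps miRNAs with unusually large target
  sets. It is always at least the Jaccard index; both are reported;
* the **Pearson chi-square test of association** on a 2×2 table comparing
  the overlap and cost counts of two miRNA pairs, where the cost of a pair
  is defined as $|A \cup B| - |A \cap B|$ — the genes regulated by exactly
  one of the two miRNAs. The union-minus-intersection construction is the
  only symmetric count consistent with treating "overlap" and "cost" as the
  two outcomes of one classification; it is a design choice of this package,
  exposed through `overlap_cost_counts()`. No continuity correction is
  applied (the intended use is tables with hundreds to thousands of genes
  per cell, where Yates' correction is negligible and the uncorrected
  statistic is standard).

## Target prediction

Targets can come from two sources behind one interface:

* **the package's own seed-match scanner** (`seed_match_sites`,
  `predict_targets`): a gene is targeted when its 3′UTR (supplied as the
  mRNA-sense strand; only that strand is scanned) carries at least
  `min_sites` canonical sites. Site classes follow the conventional
  taxonomy: *7mer-m8* (exact match to the reverse complement of seed
  positions 1–7), *7mer-A1* (match to the reverse complement of seed
  positions 1–6 followed by an A), *8mer* (both), *6mer* (the 6-nt core
  alone). Each core occurrence is reported once, as the strongest requested
  class it satisfies, so an 8mer is never double-counted as its constituent
  7mers. The default `site_types` excludes the weakly effective 6mer class.
* **precomputed prediction tables** (`load_prediction_table`): a
  miRanda-mirSVR dialect retaining records with score strictly below −0.2
  (the conventional stringency cut-off; the boundary is configurable, and
  the strict inequality means a score of exactly −0.2 is excluded), and a
  generic two-column dialect for TargetScan/PicTar-style lists, which keeps
  everything.

Target sets have gene-level set semantics: multiple sites or duplicate table
rows collapse to one membership, so results are invariant to record order
and duplication.

## The differential-expression pipeline

The pipeline consumes a normalized (log2) expression matrix — normalization
itself is out of scope, though `quantile_normalize()` is provided for
convenience — and mirrors a classic microarray workflow:

1. **presence filtering**: features with present calls in fewer than half of
   all samples (both groups pooled) are removed; exactly 50% is kept. Calls
   are supplied by the caller (computing MAS5-style detection calls needs
   raw probe data, which the package does not handle); marginal calls should
   be coded absent.
2. **annotation filtering**: features without a gene symbol are dropped.
3. **SNR collapse**: per gene, the single probe set with the highest
   signal-to-noise ratio (mean/sd across all samples) is kept. A zero-sd
   probe gets infinite SNR (it wins, with a warning); ties break to the
   lexicographically smallest probe id so the collapse is deterministic.
4. **SAM-style testing**: the moderated statistic
   $d_i = (\bar{x}_{i,1} - \bar{x}_{i,2}) / (s_i + s_0)$, with $s_i$ the
   pooled standard error of the mean difference. The fudge factor defaults
   to $s_0 = \mathrm{median}(s_i)$ — a deliberate simplification of the
   percentile search in the original formulation, chosen because it is
   scale-free, stable at small sample sizes, and a single line to audit; a
   numeric override is accepted. Null distributions come from group-label
   permutations: all distinct assignments when there are at most
   `n_permutations` (a 3 vs 3 contrast has exactly 20, all enumerated),
   otherwise a seeded uniform sample. Genes are called at the smallest
   $|d|$ threshold whose estimated FDR — the median across permutations of
   the null exceedance count divided by the observed count — is at or below
   the target (default 2%). A 90th-percentile variant of the null summary is
   exposed via `null_summary`.
5. **gene lists**: significant genes split into up- and down-regulated sets;
   `de_overlap()` compares two contrasts either on the combined sets or
   direction-tagged ("directional" mode), where a gene up in one contrast
   and down in the other does not count as shared.

### What recovery to expect, honestly

With triplicates and effects of ~3 within-group standard deviations, the
standard error of a group-mean difference is $\sqrt{2/3}\,\sigma$, i.e. the
effect is a ~3.7-sigma signal. At a 2% FDR over thousands of genes this is
simply not enough for high recall: across seeds, even an oracle threshold
that knows the planted truth recovers only ~35–60% of planted genes before
true FDR exceeds 2%, and the permutation pipeline lands in the same range
(~40–50%) with an approximately calibrated FDR estimate. Recall above 90%
requires either stronger effects (~5 sd at n = 3) or more replicates. The
test suite asserts high recall only where it is statistically attainable;
on pure-null data the pipeline calls essentially nothing.

## Cross-species comparison

Ortholog maps are two-column tables (a BioMart-export style layout). For
inter-species comparison each side's target set is restricted to genes with
an ortholog, and species B is mapped into species A's namespace by default
(the direction is configurable; the underlying biology does not dictate
one). One-to-many orthologs expand into all partners — the only policy that
cannot silently drop true overlap — and many-to-one relations merge under
set semantics; maps with such relations are flagged with a warning.
`species_overlap_report()` reports intra-specific overlap (between miRNAs
within a species) next to inter-specific overlap (the same miRNA across
species), the contrast that exposes target-site turnover.

## The synthetic-data generators

Every pipeline stage is testable without downloads because the generators
emit data *and* ground truth:

* `gen_mirna_panel()` builds mature panels in which specified pairs have
  exactly k seed mismatches (optionally at specified mature positions) and
  identical non-seed regions — the in-silico analogue of synthetic miRNA
  derivatives that isolate the seed as the only variable. Contradictory
  constraints are an error, not silently resolved.
* `gen_utr_pool()` plants 8mer windows (reverse complement of the seed plus
  the A1 anchor) at non-overlapping random offsets and rejection-samples the
  background until, for every panel seed, the number of windows qualifying
  under the chosen `site_types` equals the planted count exactly. Planted
  windows are written verbatim, so count equality implies a zero off-target
  rate: planted-site recovery is exact, deliberately cleaner than real UTRs
  (no G:U wobble, no near-sites, uniform base composition — a GC-bias knob
  exists but defaults off). One structural constraint matters: two distinct
  seeds that share mature positions 2–7 share their 6mer core, so a planted
  window for one is intrinsically a 7mer-A1 site for the other; the
  generator detects this and requires m8-anchored `site_types`
  (`c("8mer", "7mer-m8")`) for such panels. This is why the
  mismatch-class simulations below use those two classes.
* `gen_expression()` draws Gaussian log2-scale signals (per-gene baselines
  ~N(7, 2), noise sd 1 by default — typical magnitudes for normalized
  arrays) and shifts a planted fraction of genes (default 10%, the order of
  a strong transfection response) by ±`effect_size` noise-sd in the treated
  group, in recorded directions. Default design is 3 vs 3, matching
  triplicate transfection contrasts.
* `gen_ortholog_scenario()` copies a planted species-A pool as the
  species-B orthologs and independently disrupts each planted site with
  probability `turnover_rate` by resampling its 8-nt window (revalidated so
  no new site arises). Inter-specific overlap for an all-genes plan is then
  ~`sqrt(1 - rate)` while intra-specific overlap of identical-seed miRNAs
  stays 1 — the signature of target-site turnover under conserved seeds.

Identical `rng_seed` gives byte-identical output; generators save and
restore the caller's RNG state.

What passing tests on this synthetic data do *not* show: performance on real
UTRs (near-sites, conservation structure, 3′-supplementary pairing are all
absent), on real array noise (heteroskedasticity, batch effects), or
agreement with any particular external predictor release. The simulation
asserts the *shape* of the mismatch-cost relationship — identical seeds
overlap near-completely, one mismatch collapses overlap to chance, further
mismatches add little — not any published percentage.

## Problem sizes and numerical choices

The shipped simulations use 2,000 UTRs of 240 nt with a 10% target fraction
for the mismatch-class profile (a 9-miRNA panel: an identical-seed pair plus
a 7-step mutation chain whose pairwise distances deterministically span
classes 0–7); 5,000 genes, 3 vs 3, for the DE pipeline; and 300 ortholog
pairs over a turnover grid of 0/0.25/0.5/0.75 with 20 replicates. These
sizes give per-class standard errors well inside the asserted margins while
keeping a full run on one CPU in the low minutes.

Quartiles use linear interpolation (R's default type 7); whiskers follow the
Tukey convention (most extreme values within 1.5×IQR of the box), with the
multiplier configurable — box conventions differ across the literature, so
the choice is explicit rather than implicit. Percent overlaps are reported
at full precision internally and rounded only in formatted output.

Degenerate inputs are errors, not guesses: empty sets for cosine similarity,
zero column totals in the chi-square table, ambiguity codes in sequences
(a seed with an N has no defined match set), zero-variance genes with
`s0 = 0`, unmapped genes passed to `map_target_set()` without prior
restriction.

## Command-line interface

`inst/cli/mirseed.R` is a thin wrapper over `cli_main()`, with subcommands
`seed-dist`, `predict`, `overlap`, `de`, `cross-species`, `simulate` and
`demo`; options may come from flags or a YAML config (flags win; unknown
keys are an error). Every run writes a JSON manifest (package version,
config echo, rng seed, input checksums) so a result is reproducible from its
manifest alone. Exit codes: 0 ok, 2 usage error, 3 data error.

## Known limitations

* The scanner models canonical seed matching only — no free-energy or
  context scoring, no conservation features, no 3′-supplementary pairing.
* Presence calls are consumed, not computed; raw CEL/probe-level processing
  and array QC are out of scope.
* The SAM simplifications (median-based $s_0$, symmetric $|d|$ thresholding,
  median-exceedance FDR) favor auditability over exact equivalence with any
  specific SAM release.
* Published overlap percentages from specific prediction-tool releases and
  array datasets are not reproduction targets; the package asserts the
  relationships those numbers illustrate.
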
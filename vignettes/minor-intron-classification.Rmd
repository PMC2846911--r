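---
title: "Detecting and classifying minor-spliceosome introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying minor-spliceosome introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minorintron)
```

## The model

Two spliceosomes excise introns in eukaryotes. The major (U2-dependent)
machinery removes the overwhelming majority of introns, which carry the
5' splice-site consensus `AG/GTRAGT`, a branch site near `CTRACT`, a
pyrimidine-rich tract and a terminal `YAG`. The minor (U12-dependent)
machinery removes a rare class with a much more constrained 5' site
(`/RTATCCTT`) and branch site (`TCCTTAACT`), a weak 3' site and no
pyrimidine tract. Most U12 introns use `GT–AG` termini; a minority use
`AT–AC`. Because the discriminating information sits almost entirely in
the 5' and branch signals, intron classification reduces to scoring those
two windows under class-specific position weight matrices (PWMs).

`minorintron` implements this end to end: inferring introns from
EST-to-genome matches, scoring them under two established schemes, flagging
candidates with a deterministic 5'-sequence rule, and following the fate of
a minor intron across homologous genes.

## Matrices and scoring

All matrix algebra lives in one place. A `splice_matrix` is a
positions-by-base table in one of three kinds:

* `counts` — a frequency matrix; for a matrix built from *n* sites every
  position's column sum equals *n*;
* `probs` — a PWM. `to_pwm()` normalizes rows and applies a probability
  floor (default `1e-4`): without it a single zero entry would veto any
  sequence with one off-consensus base in product scoring. The floor is
  applied before a final renormalization, so floored entries end an
  infinitesimal amount below the nominal floor; the package treats the
  floor as a numerical guard, not a calibrated parameter.
* `logodds` — `log2(((count + pseudocount) / (total + 4 pseudocount)) /
  background)`, pseudocount 0.001, background uniform `0.25` by default.
  The background is overridable per run; uniform is the neutral choice when
  the training composition of the source matrices is unknown.

Window conventions follow the SpliceRack layout: the 5' window has 13
positions of which the first 3 are exonic; the 3' window has 17 positions
of which the last 3 are exonic; the branch matrix has 12 intronic
positions. The branch site is not annotated — it is *searched for*:
`score_branch_max()` scans every fully contained window in the interval
`(-40, -5)` relative to the 3' splice site and keeps the maximum, with ties
going to the leftmost window for determinism. Windows are additionally
barred from overlapping intron positions +1..+10, so the scan of a short
intron never reads into its own 5' splice site; if no window fits the
intron is reported as too short rather than silently mis-scored. The scan
window length always equals the supplied matrix's length, so 12-position
and 13-position branch conventions both work unchanged.

Ambiguity codes in scored sequences contribute the background probability
under a probability matrix and weight 0 under a log-odds matrix — unknowns
are neither rewarded nor penalized.

When no curated major-class branch matrix exists, one is constructed the
way practitioners do: `build_u2_branch_matrix()` takes a set of U2 introns,
finds each intron's best window under a U12 branch PWM, and tallies those
windows into a frequency matrix. Each contributing intron adds exactly one
count to every position. The position of the branch-point adenosine within
the 12-position window is deliberately not modeled: only the window is
recorded.

## Intron discovery

ESTs are single-pass cDNA reads; aligning them to genomic contigs exposes
introns as gaps between consecutive aligned blocks (HSPs). The package
accepts precomputed 12-column tabular alignments from any local-alignment
tool, or uses a built-in matcher sufficient for high-identity,
substitution-only data: exact k-mer anchors (default k = 16) located
through a single hashed join, merged per alignment diagonal, then extended
without gaps under an X-drop rule (match +1, mismatch −3). Both EST
orientations are tried and minus-orientation hits are reported on the
coding strand. Coordinates are 0-based half-open throughout.

The downstream contract mirrors standard EST-mapping practice:

* HSPs must reach 98% identity and 35 nt (both bounds inclusive);
* when an EST hits several contigs, the contig covering the most distinct
  EST bases wins, ties going to the lexicographically smallest id;
* local alignment cannot always place a junction exactly — when flanking
  HSPs overlap by *b* bases on the EST, all *b* + 1 splits are enumerated
  (each slides the junction one base while conserving every EST base, and
  all share one intron length), then PWM scoring picks the true one.

Placement resolution scores each candidate's 5' and 3' windows under one or
more matrix sets. A candidate that simultaneously maximizes both scores
wins; otherwise the largest 5' + 3' sum wins; remaining ties go to the
leftmost genomic start. Sets from different species are combined by
averaging log probabilities (a symmetric, deterministic choice — the
combination rule for multi-species scoring is genuinely open, and averaging
was preferred over sequential application because it is order-free). The
package default instead supplies one set per intron class combined by
per-candidate maximum: an equal-weight mixture matrix was tried first and
blunted both classes' signals, producing ±1-base junction shifts where the
class-aware maximum resolves them.

Intron length bounds default to 30–20000 nt, bracketing the intron sizes
observed in compact invertebrate and protist genomes with wide margin.
Multi-intron ESTs are processed gap by gap independently; one intron is
inferred per EST gap.

## Classification

Two schemes are computed side by side, as their disagreement is itself
informative.

**Probability-product scheme with z-scores.** For each intron the 13-nt 5'
window probability is computed under the U12 matrices matching its termini
(AT–AC introns use AT–AC matrices, everything else GT–AG U12; GC–AG introns
are scored with GT–AG matrices, the 2nd-position mismatch being absorbed by
the probability floor) and under the GT–AG U2 matrices; the branch maxima
likewise. The log2 ratios `s5` and `sb` are normalized to z-scores by
subtracting the sample mean and dividing by the sample standard deviation,
making scores comparable across species and matrix sets. An intron is
flagged `B` when both z-scores are at least the minima of a reference U12
set scored with the same matrices and placed in the query sample's z-space
— an inclusive rectangle rule, so an intron exactly on the boundary
qualifies. The original reference set of minor introns is unpublished, so
the package ships a reproducible stand-in: 20 introns sampled from the U12
generator matrices at a fixed seed (`reference_introns()`); users may
supply their own reference. The thresholds are relative to the query
sample's normalization by construction, so they cannot be compared across
runs with different samples.

**Log-odds scheme.** The 5' window is scored under all four class log-odds
matrices and the best 12-nt branch window under the U12 branch matrix
matching the termini. The `S` flag requires the U12-class 5' score to beat
the corresponding U2-class score (GT–AG vs GT–AG U2, GC–AG vs GC–AG U2,
AT–AC vs GT–AG U2, there being no U2 AT–AC class) and both U12 scores to
meet per-class minima. The original discriminant cutoffs are only cited in
the literature, never printed, so the defaults are 0 — the U12 score must
merely be positive and beat the U2 alternative. This is a documented
stand-in, not a calibrated reproduction; the minima are configurable.
Whether thresholding should happen on raw log-ratios or z-scores is
similarly underdetermined; the z-score reading is implemented because the
score-space scatter plots that motivate the rectangle rule are drawn in
z-space. Introns with non-canonical termini are reported `OTHER` and not
scored. An AT–AC intron failing the U12 test is tallied separately
(`OTHER_ATAC`) in summaries, since AT–AC termini alone do not make a minor
intron.

**The 5' rule.** Effective minor-spliceosome splicing requires the intron
to begin `RTATCCTT` with at most one of the Cs at +5/+6 replaced by T.
`five_prime_rule()` implements exactly that predicate; it is deterministic,
needs no matrices, and marks the strongest candidates (`R` flag).

`classify_introns()` wires all three together and returns a result object
with `tidy()`, `glance()` and `autoplot()` methods; `summarize_counts()`
reproduces the per-category table layout with 5'-rule counts in
parentheses, split by method.

## Ortholog fate

To ask what became of a minor intron in a relative that lost U12 splicing,
the intron's position is expressed in coding coordinates (codon index plus
phase) and projected through a protein alignment onto the homologous gene.
Homolog search itself is out of scope — the module consumes gene structures
plus an alignment, with `Biostrings::pairwiseAlignment()` wrapped as
convenience plumbing for synthetic tests. A position aligned to a gap is
unmappable (`UNKNOWN`). Otherwise: an intron of the partner at the same
codon and phase is `CONSERVED_U12` or `U12_TO_U2_SAME_SITE` depending on
its class; an intron within `shift_max` codons (default 5, phase ignored —
a shifted site moves within the frame) is a shifted conversion; no intron
within range means `U12_LOST`. Same-site calls require matching phase; a
same-codon different-phase intron counts as shifted with distance 0. The
shift window is kept small deliberately: a large window would conflate a
shifted site with an independent loss plus gain.

## The synthetic generator

The generator emulates the data regime the pipeline targets, not any
particular genome: multi-exon genes (3–6 exons of 80–300 nt) on one contig
each with 100-nt flanks; intron lengths log-normal with modal length 62 nt
(the empirical mode for compact genomes falls in the 51–95 nt band),
truncated to 50–2000 nt; a class mix of 90% U2 GT–AG, 2% U2 GC–AG, 5% U12
GT–AG, 2% U12 AT–AC and 1% non-canonical, enriched for the minor class
relative to real genomes (where U12 introns are ~1 in 1000) so classifier
behavior is measurable at feasible sample sizes; and per-gene ESTs — one
full-length transcript plus one random 300–900 nt fragment — with
substitution errors at 1% per base (capped at 2% so the 98% identity filter
stays meaningful). Splice signals are written in from consensus-derived
matrices: U12 positions carry 0.85 consensus mass, U2 positions 0.55,
mirroring the relative conservation of the two signal families; degenerate
consensus bases split the mass equally and the remainder spreads uniformly.
Branch windows are planted at recorded offsets in [−40, −26], inside the
scan range and clear of both the 5' region and the 14 3'-terminal positions
the 3' matrix occupies; the 50-nt minimum intron length guarantees an
admissible window always exists. A configurable fraction of U12 introns
(default 20%) carries exact-consensus 5' and branch windows, emulating
textbook-strength minor introns; because a consensus window's probability
product dominates any sampled window, these introns pass the reference
rectangle deterministically, which turns "strong candidates are never
missed" into a testable invariant rather than a coin flip.

What the generator does *not* model: indels in ESTs (substitution-only by
design, keeping the identity filter and junction-ambiguity enumeration
separately testable), codon structure, GC content, transcript abundance, or
repeat-induced multi-mapping. Passing tests on synthetic data therefore
demonstrate the correctness of the inference machinery under the stated
error model, not robustness to the full messiness of real EST archives.

## Numerical choices and degenerate inputs

* Ties are broken deterministically everywhere: leftmost branch window,
  leftmost genomic start among junction candidates, lexicographically
  smallest contig id, smallest length for the modal-length statistic.
* z-normalization requires at least two introns and positive score
  variance; both failure modes raise errors rather than returning NaNs.
* HSP pairs separated by unaligned EST bases yield no intron candidates: a
  clean junction conserves every EST base under the substitution-only
  model.
* Empty inputs return empty, correctly-typed tibbles (discovery) or
  all-zero tables (summaries); empty matrix inputs are errors.
* Identical configurations, including the seed, generate byte-identical
  synthetic datasets; `reference_introns()` restores the caller's RNG
  state.

## Problem sizes

The shipped tests validate the pipeline at the scale the statistics
require and no larger: brute-force oracle equivalence on 100+ random branch
scans and 10 matrix constructions; the full recovery check on one
synthetic dataset of ~145 genes / ~500 introns (canonical-junction boundary
recovery ≥ 99%, class agreement ≥ 95%, all consensus-site U12 introns
inside the reference rectangle); fate recovery on 40 random homolog pairs.
Non-canonical junctions are excluded from the boundary-recovery denominator
because they carry no splice-site signal — for them every junction split is
equally consistent with the alignment, so exact placement is
information-theoretically unresolvable, and the package's leftmost
tie-break is as good as any.

## Known limitations

* The matcher is an anchor-and-extend tool for high-identity spliced
  matches, not a general spliced aligner; it has no affine-gap model and no
  intron-aware dynamic programming.
* The packaged matrices are consensus-derived, not estimated from curated
  site collections; absolute score values (especially log-odds cutoffs)
  should be recalibrated before biological use on real genomes.
* The candidate fixture's surrogate sequences are N-padded between their
  printed terminal fragments, so only window-based statistics over those
  terminal regions are meaningful on them.
* GC–AG introns passing the U12 test are reported in the GT–AG U12
  category; the category enumeration has no separate U12 GC–AG class.
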
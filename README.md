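# minorintron

Discovery and classification of minor-spliceosome (U12-type) introns from
EST-to-genome matches.

## The problem

Eukaryotic genomes carry two intron classes removed by distinct
spliceosomes: the common U2 type (5' consensus `AG/GTRAGT`, branch
`CTRACT`, a pyrimidine tract before the 3' `YAG`) and the rare U12 type,
whose 5' splice site (`/RTATCCTT`) and branch site (`TCCTTAACT`) are far
more conserved while its 3' site is weak. Whether a lineage still performs
U12 splicing — and what happened to its ancestral U12 introns — can be read
off EST data: aligning expressed sequence tags to genomic contigs exposes
introns as genomic gaps, and position weight matrices (PWMs) over the
splice signals separate the two classes.

`minorintron` packages that analysis as a tested, reusable pipeline for
anyone studying minor-spliceosome evolution or annotating introns in
EST-era genome assemblies:

* **Intron discovery** — import 12-column tabular local alignments or use
  the built-in k-mer anchor/extend matcher; filter HSPs (identity >= 98%,
  length >= 35 nt); pick the best-matching contig per EST; enumerate every
  junction placement consistent with the alignment overlap and resolve the
  exact splice sites by PWM scoring.
* **Classification** — two schemes per intron. The probability-product
  scheme scores the 13-nt 5' window `P(X|U12) / P(X|U2)` and the best
  branch window in `(-40, -5)`, normalizes both log2 ratios to z-scores
  over the scored sample, and flags introns (`B`) inside the inclusive
  rectangle spanned by the minima of a reference U12 set. The log-odds
  scheme (pseudocount 0.001) flags introns (`S`) whose U12 5' score beats
  the corresponding U2 score with 5' and branch scores above configurable
  minima. The relaxed `RTATCCTT` 5'-terminal rule (one C at +5/+6 may be a
  T) gives the `R` flag.
* **U2 branch matrix construction** — build a major-class branch frequency
  matrix from the per-intron best windows under a U12 branch PWM.
* **Ortholog fate** — project a U12 intron's codon/phase position through a
  protein alignment onto a homologous gene and classify its fate:
  conserved, converted to U2 at the same site, converted via a shifted
  site, lost, or unknown.
* **Synthetic data** — a generator that emits genomes, gene structures and
  error-bearing ESTs with planted intron classes, branch windows and a
  machine-readable truth table, so the whole pipeline is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted results, `autoplot()` for the z-score scatter.

## Worked example

The package ships a curated set of 16 U12 intron candidates identified in
public *Trichinella spiralis* EST data (*T. spiralis* is the deepest-
branching nematode known to retain U12 splicing, unlike *C. elegans*):

```r
library(minorintron)
fx <- u12_candidate_fixture()
cl <- classify_introns(fx)
print(cl)
#> <u12_classification> 16 introns
#> thresholds: z5 >= -2.628, zb >= -0.629
#> # A tibble: 6 x 5
#>   category   burge_n burge_rule_n sheth_n sheth_rule_n
#> 1 U12_ATAC         3            3       3            3
#> 2 U12_GTAG         8            6       6            5
#> 3 U2_GCAG          0           NA       0           NA
#> 4 U2_GTAG          5           NA       7           NA
#> ...
sum(five_prime_rule(fx$sequence))
#> [1] 11   # 11 candidates conform to the RTATCCTT rule; 5 do not
table(classify_termini(fx$sequence))
#> AT_AC GT_AG
#>     3    13
```

The terminal dinucleotides split the candidates 3 AT-AC / 13 GT-AG, and 11
of 16 pass the 5'-terminal consensus rule — the strong predictions.

End to end on synthetic data with planted ground truth:

```r
ds <- simulate_dataset(sim_config(seed = 7, n_genes = 20, est_error_rate = 0))
ds
#> <sim_dataset> 20 contigs (34502 nt), 40 ESTs, 81 planted introns
introns <- discover_introns(ds$genome, ds$ests)
rec <- evaluate_recovery(tidy(classify_introns(introns)), ds$truth)
rec$boundary_rate_canonical
#> [1] 1          # every canonical planted junction recovered exactly
rec$class_rate
#> [1] 0.9559     # class agreement with the generator truth
intron_length_stats(ds$truth$length)$mode
#> [1] 76         # modal intron length, nt
```

Fate of a U12 intron between homologous genes:

```r
pairs <- fate_pair_fixture()
classify_intron_fates(pairs$a[[1]], pairs$b[[1]])
#> # A tibble: 1 x 7
#>   codon_index phase mapped_codon mapped_phase mappable fate              shift_codons
#> 1          12     0           15            0 TRUE     U12_TO_U2_SHIFTED            3
```

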
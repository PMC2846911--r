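#' Curated Trichinella spiralis U12 intron candidate set
#'
#' Loads the packaged reference set of 16 minor-spliceosome intron
#' candidates identified in public *T. spiralis* EST data: the source EST
#' accession, the printed 5'-terminal (10 nt) and 3'-terminal fragments of
#' each intron with 3 nt of flanking exon, the intron length, the
#' probability-scheme flag (`B`), the 5'-rule flag (`R`), and the fate of
#' the homologous intron in *C. elegans* where resolvable. A surrogate
#' full-length sequence is reconstructed by joining the terminal fragments
#' with an `N` spacer of the correct length, so window-based scoring of the
#' terminal regions works unchanged.
#'
#' @return A tibble with one row per candidate: `est_id`, `exon5`, `exon3`,
#'   `sequence` (N-padded surrogate), `length`, `donor`, `acceptor`,
#'   `terminal`, `burge_flag`, `rule_flag`, `fate`, `ortholog`.
#' @export
u12_candidate_fixture <- function() {
  path <- system.file("extdata", "trichinella_u12_candidates.tsv",
                      package = "minorintron", mustWork = TRUE)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = NULL)
  mid <- raw$length - nchar(raw$five_frag) - nchar(raw$three_frag)
  stopifnot(all(mid >= 0))
  seq <- paste0(raw$five_frag, strrep("N", mid), raw$three_frag)
  tibble::tibble(
    est_id = raw$est_id,
    exon5 = raw$exon5,
    exon3 = raw$exon3,
    sequence = seq,
    length = raw$length,
    donor = substr(seq, 1L, 2L),
    acceptor = substr(seq, raw$length - 1L, raw$length),
    terminal = classify_termini(seq),
    burge_flag = raw$burge == "+",
    rule_flag = raw$rule == "+",
    fate = raw$fate,
    ortholog = raw$ortholog
  )
}

#' Synthetic homolog pairs mirroring the candidate set's fate column
#'
#' Loads the packaged synthetic gene-structure pairs: for each candidate
#' whose *C. elegans* fate is resolvable, a constructed pair of homologous
#' gene structures whose intron layout reproduces that fate (same-site
#' U12-to-U2 conversion, conversion via a 3-codon splice-site shift, or
#' complete loss). The proteins and coordinates are synthetic; only the
#' fate relationships are real.
#'
#' @return A tibble from [read_fate_pairs()] with columns `pair_id`,
#'   `expected_fate` and gene-structure list-columns `a`, `b`.
#' @export
fate_pair_fixture <- function() {
  read_fate_pairs(system.file(
    "extdata", "trichinella_celegans_fate_pairs_synthetic.tsv",
    package = "minorintron", mustWork = TRUE
  ))
}
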
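# Evolutionary fate of minor-spliceosome introns between homologous genes:
# intron positions (codon index + phase) are projected through a protein
# alignment and compared with the second species' gene structure.

#' Construct a gene structure
#'
#' A gene structure is a protein sequence plus its intron positions in
#' coding coordinates: `codon_index` (1-based codon carrying the junction)
#' and `phase` (0, 1 or 2 nucleotides into that codon), with the terminal
#' category and a minor-spliceosome flag per intron.
#'
#' @param species Species tag.
#' @param protein Amino-acid sequence (character string).
#' @param introns Tibble with columns `codon_index`, `phase`, `terminal`,
#'   `u12` (logical); may have zero rows.
#' @return A `gene_structure` object.
#' @export
gene_structure <- function(species, protein,
                           introns = tibble::tibble(
                             codon_index = integer(), phase = integer(),
                             terminal = character(), u12 = logical()
                           )) {
  introns <- tibble::as_tibble(introns)
  if (nrow(introns) > 0L) {
    pos <- 3 * introns$codon_index + introns$phase
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("intron positions must be strictly increasing")
    }
    if (any(introns$codon_index > nchar(protein)) || any(introns$codon_index < 1L)) {
      stop("intron codon_index must lie within the protein")
    }
    if (any(!introns$phase %in% 0:2)) stop("phase must be 0, 1 or 2")
  }
  structure(list(species = species, protein = toupper(protein),
                 introns = introns),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("<gene_structure> %s: %d aa, %d introns (%d U12)\n",
              x$species, nchar(x$protein), nrow(x$introns),
              sum(x$introns$u12)))
  invisible(x)
}

#' Globally align two proteins
#'
#' Convenience plumbing around [Biostrings::pairwiseAlignment()]
#' (Needleman-Wunsch, BLOSUM62) returning the two gapped sequences.
#'
#' @param a,b `gene_structure` objects or amino-acid strings.
#' @param gap_opening,gap_extension Gap penalties.
#' @return Character vector of length 2: the gapped sequences of `a` and `b`.
#' @export
align_protein_pair <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  pa <- if (inherits(a, "gene_structure")) a$protein else a
  pb <- if (inherits(b, "gene_structure")) b$protein else b
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

#' Project intron positions through a protein alignment
#'
#' Each intron position of `a` is mapped onto `b`'s codon coordinates via
#' the alignment column holding the corresponding residue of `a`. Introns
#' whose residue aligns to a gap in `b` are marked unmappable.
#'
#' @param a,b `gene_structure` objects.
#' @param alignment Character vector of the two gapped sequences
#'   (a first), e.g. from [align_protein_pair()] or an aligned FASTA read
#'   with [read_fasta()]. Defaults to aligning the two proteins.
#' @return A tibble with `codon_index`, `phase`, `mapped_codon`,
#'   `mapped_phase`, `mappable`.
#' @export
map_intron_positions <- function(a, b, alignment = align_protein_pair(a, b)) {
  ga <- toupper(alignment[[1L]])
  gb <- toupper(alignment[[2L]])
  if (nchar(ga) != nchar(gb)) stop("gapped sequences differ in length")
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  if (paste(ca[ca != "-"], collapse = "") != a$protein ||
      paste(cb[cb != "-"], collapse = "") != b$protein) {
    stop("alignment is inconsistent with the protein sequences")
  }
  a_res <- cumsum(ca != "-") # residue index of a at each column
  b_res <- cumsum(cb != "-")
  cols <- match(a$introns$codon_index, a_res) # first column of that residue
  mappable <- !is.na(cols) & cb[cols] != "-"
  tibble::tibble(
    codon_index = a$introns$codon_index,
    phase = a$introns$phase,
    mapped_codon = ifelse(mappable, b_res[cols], NA_integer_),
    mapped_phase = a$introns$phase,
    mappable = mappable
  )
}

FATES <- c("CONSERVED_U12", "U12_TO_U2_SAME_SITE", "U12_TO_U2_SHIFTED",
           "U12_LOST", "UNKNOWN")

#' Classify the fate of one mapped U12 intron
#'
#' Given a U12 intron position projected into species `b`'s coordinates:
#' a U12 intron of `b` at the same codon and phase is `CONSERVED_U12`; a U2
#' intron there is `U12_TO_U2_SAME_SITE`; an intron within `shift_max`
#' codons (phase ignored) is a shifted conversion (`U12_TO_U2_SHIFTED`, or
#' `CONSERVED_U12` if that intron is itself U12), with the codon distance
#' reported; no intron within `shift_max` codons means `U12_LOST`.
#' An unmappable position yields `UNKNOWN`.
#'
#' @param mapped One row of [map_intron_positions()] output (list or
#'   single-row tibble).
#' @param b `gene_structure` of the second species.
#' @param shift_max Maximum codon shift still counted as the same intron
#'   (default 5).
#' @return A list with `fate` and `shift_codons`.
#' @export
classify_fate <- function(mapped, b, shift_max = 5L) {
  if (!isTRUE(mapped$mappable[[1L]])) {
    return(list(fate = "UNKNOWN", shift_codons = NA_integer_))
  }
  pos <- mapped$mapped_codon[[1L]]
  ph <- mapped$mapped_phase[[1L]]
  bi <- b$introns
  same <- which(bi$codon_index == pos & bi$phase == ph)
  if (length(same) > 0L) {
    fate <- if (any(bi$u12[same])) "CONSERVED_U12" else "U12_TO_U2_SAME_SITE"
    return(list(fate = fate, shift_codons = 0L))
  }
  d <- abs(bi$codon_index - pos)
  near <- which(d <= shift_max)
  if (length(near) > 0L) {
    j <- near[which.min(d[near])]
    fate <- if (bi$u12[j]) "CONSERVED_U12" else "U12_TO_U2_SHIFTED"
    return(list(fate = fate, shift_codons = d[j]))
  }
  list(fate = "U12_LOST", shift_codons = NA_integer_)
}

#' Classify the fates of all U12 introns between two homologous genes
#'
#' Maps every U12-flagged intron of `a` through the protein alignment and
#' classifies its fate in `b`.
#'
#' @inheritParams map_intron_positions
#' @param shift_max Maximum codon shift for [classify_fate()].
#' @return A tibble with one row per U12 intron of `a`: `codon_index`,
#'   `phase`, `mapped_codon`, `fate`, `shift_codons`.
#' @export
classify_intron_fates <- function(a, b, alignment = align_protein_pair(a, b),
                                  shift_max = 5L) {
  u12 <- gene_structure(a$species, a$protein,
                        a$introns[a$introns$u12, , drop = FALSE])
  mapped <- map_intron_positions(u12, b, alignment)
  res <- purrr::map(seq_len(nrow(mapped)), function(i) {
    classify_fate(mapped[i, ], b, shift_max)
  })
  dplyr::mutate(mapped,
    fate = vapply(res, `[[`, character(1), "fate"),
    shift_codons = vapply(res, `[[`, integer(1), "shift_codons")
  )
}

#' Read synthetic homolog gene-structure pairs from TSV
#'
#' Parses the packaged fate-fixture dialect: one row per gene pair with the
#' two proteins and semicolon-separated intron descriptors
#' (`codon:phase:terminal:u12`).
#'
#' @param path TSV path with columns `pair_id`, `a_species`, `a_protein`,
#'   `a_introns`, `b_species`, `b_protein`, `b_introns`, and optionally
#'   `expected_fate`.
#' @return A tibble with list-columns `a` and `b` of `gene_structure`
#'   objects.
#' @export
read_fate_pairs <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "")
  parse_introns <- function(txt) {
    if (is.na(txt) || txt == "") {
      return(tibble::tibble(codon_index = integer(), phase = integer(),
                            terminal = character(), u12 = logical()))
    }
    parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    tibble::tibble(
      codon_index = as.integer(vapply(parts, `[[`, character(1), 1L)),
      phase = as.integer(vapply(parts, `[[`, character(1), 2L)),
      terminal = vapply(parts, `[[`, character(1), 3L),
      u12 = vapply(parts, `[[`, character(1), 4L) == "1"
    )
  }
  tibble::tibble(
    pair_id = raw$pair_id,
    expected_fate = if ("expected_fate" %in% names(raw)) raw$expected_fate else NA,
    a = purrr::map(seq_len(nrow(raw)), function(i) {
      gene_structure(raw$a_species[i], raw$a_protein[i],
                     parse_introns(raw$a_introns[i]))
    }),
    b = purrr::map(seq_len(nrow(raw)), function(i) {
      gene_structure(raw$b_species[i], raw$b_protein[i],
                     parse_introns(raw$b_introns[i]))
    })
  )
}
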
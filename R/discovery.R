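#' Read a 12-column tabular local-alignment file
#'
#' Imports the de facto standard tabular output of local-alignment tools
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore; 1-based inclusive coordinates) and converts it to the
#' package's 0-based half-open convention. Minus-strand hits (subject start
#' greater than end) are remapped onto the reverse-complemented EST, so
#' downstream inference always works on the coding strand; this requires
#' `ests` so the EST lengths are known.
#'
#' @param path Path to the tabular file (no header).
#' @param ests Optional named character vector of EST sequences (required
#'   only when the file contains minus-strand hits).
#' @return A tibble of HSPs: `est_id`, `contig_id`, `est_start`, `est_end`,
#'   `genome_start`, `genome_end`, `strand`, `identity`, `match_len`.
#' @export
read_blast_tab <- function(path, ests = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- utils::read.table(path, sep = "\t", col.names = cols,
                           stringsAsFactors = FALSE)
  minus <- raw$sstart > raw$send
  if (any(minus) && is.null(ests)) {
    stop("minus-strand hits present; supply `ests` so coordinates can be remapped")
  }
  est_start <- raw$qstart - 1L
  est_end <- raw$qend
  if (any(minus)) {
    len <- nchar(ests)[match(raw$qseqid, names(ests))]
    if (anyNA(len[minus])) stop("minus-strand hit for an EST absent from `ests`")
    est_start[minus] <- len[minus] - raw$qend[minus]
    est_end[minus] <- len[minus] - raw$qstart[minus] + 1L
  }
  tibble::tibble(
    est_id = raw$qseqid,
    contig_id = raw$sseqid,
    est_start = est_start,
    est_end = est_end,
    genome_start = ifelse(minus, raw$send, raw$sstart) - 1L,
    genome_end = ifelse(minus, raw$sstart, raw$send),
    strand = ifelse(minus, "-", "+"),
    identity = raw$pident,
    match_len = raw$qend - raw$qstart + 1L
  )
}

#' Filter HSPs on identity and length
#'
#' Keeps alignments with identity and length at least the thresholds
#' (both boundaries inclusive). Defaults mirror the standard EST-mapping
#' stringency: >= 98% identity and >= 35 nt.
#'
#' @param hsps HSP tibble (see [read_blast_tab()]).
#' @param min_identity Minimum percent identity (default 98).
#' @param min_len Minimum alignment length in nt (default 35).
#' @return The filtered tibble.
#' @export
filter_hsps <- function(hsps, min_identity = 98, min_len = 35) {
  dplyr::filter(hsps, .data$identity >= min_identity,
                .data$match_len >= min_len)
}

#' Select the contig with the most extensive EST match
#'
#' Among all contigs hit by one EST, returns the contig whose HSPs cover the
#' largest number of distinct EST bases (overlaps counted once). Ties go to
#' the lexicographically smallest contig id.
#'
#' @param hsps HSP tibble for a single EST.
#' @return The winning `contig_id` (character scalar).
#' @export
select_best_contig <- function(hsps) {
  if (nrow(hsps) == 0L) stop("no HSPs supplied")
  cov <- hsps |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::summarise(
      covered = interval_union_len(.data$est_start, .data$est_end),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$covered), .data$contig_id)
  cov$contig_id[1L]
}

# --- built-in exact-anchor matcher ----------------------------------------

build_kmer_index <- function(genome, k) {
  parts <- purrr::imap(genome, function(seq, id) {
    n <- nchar(seq)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    tibble::tibble(kmer = substring(seq, starts, starts + k - 1L),
                   contig_id = id, gpos = starts)
  })
  dplyr::bind_rows(parts)
}

# Ungapped X-drop extension of seed anchors along one EST/contig diagonal.
# eint/cint are integer base codes; diag = gpos - epos (1-based).
extend_diagonal <- function(eint, cint, diag, anchor_lo, anchor_hi,
                            mismatch_penalty = 3) {
  pmin_v <- max(1L, 1L - diag)
  pmax_v <- min(length(eint), length(cint) - diag)
  m <- eint[pmin_v:pmax_v] == cint[(pmin_v + diag):(pmax_v + diag)]
  m[is.na(m)] <- FALSE
  off <- pmin_v - 1L
  e1 <- anchor_lo; e2 <- anchor_hi
  if (e2 < pmax_v) {
    sc <- cumsum(ifelse(m[(e2 + 1L - off):(pmax_v - off)], 1, -mismatch_penalty))
    j <- which.max(sc)
    if (sc[j] > 0) e2 <- e2 + j
  }
  if (e1 > pmin_v) {
    sc <- cumsum(ifelse(rev(m[(pmin_v - off):(e1 - 1L - off)]), 1, -mismatch_penalty))
    j <- which.max(sc)
    if (sc[j] > 0) e1 <- e1 - j
  }
  span <- m[(e1 - off):(e2 - off)]
  list(e1 = e1, e2 = e2, identity = 100 * mean(span))
}

#' Match ESTs against genomic contigs
#'
#' A light-weight spliced-mapping front end sufficient for high-identity,
#' substitution-only data: exact k-mer anchors locate each exon, anchors on
#' a shared alignment diagonal are merged, and the merged blocks are extended
#' without gaps in both directions under an X-drop rule. Both orientations of
#' each EST are tried; hits from the reverse-complemented orientation carry
#' `strand == "-"` with EST coordinates on the reverse complement, so introns
#' are always inferred on the coding strand.
#'
#' @param genome Named character vector of contigs (or FASTA path /
#'   DNAStringSet).
#' @param ests Named character vector of ESTs (or FASTA path / DNAStringSet).
#' @param k Anchor k-mer length (default 16).
#' @return An HSP tibble (see [read_blast_tab()] for columns).
#' @export
match_ests <- function(genome, ests, k = 16L) {
  genome <- as_named_seqs(genome, "genome")
  ests <- as_named_seqs(ests, "ests")
  index <- build_kmer_index(genome, k)
  cints <- lapply(genome, seq_to_idx)
  oriented <- list(`+` = ests, `-` = stats::setNames(revcomp(ests), names(ests)))
  # one global seed table so the k-mer hash join happens once
  seeds <- purrr::imap(oriented, function(seqs, ori) {
    purrr::imap(seqs, function(est, est_id) {
      n <- nchar(est)
      if (n < k) return(NULL)
      spos <- unique(c(seq.int(1L, n - k + 1L, by = k), n - k + 1L))
      tibble::tibble(est_id = est_id, strand = ori, epos = spos,
                     kmer = substring(est, spos, spos + k - 1L))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  empty <- tibble::tibble(
    est_id = character(), contig_id = character(),
    est_start = integer(), est_end = integer(),
    genome_start = integer(), genome_end = integer(),
    strand = character(), identity = numeric(), match_len = integer()
  )
  if (nrow(seeds) == 0L) return(empty)
  hits <- dplyr::inner_join(seeds, index, by = "kmer",
                            relationship = "many-to-many")
  if (nrow(hits) == 0L) return(empty)
  groups <- hits |>
    dplyr::mutate(diag = .data$gpos - .data$epos) |>
    dplyr::group_by(.data$est_id, .data$strand, .data$contig_id, .data$diag) |>
    dplyr::summarise(lo = min(.data$epos), hi = max(.data$epos) + k - 1L,
                     .groups = "drop")
  eint_cache <- new.env(parent = emptyenv())
  get_eint <- function(est_id, ori) {
    key <- paste0(ori, est_id)
    val <- get0(key, envir = eint_cache)
    if (is.null(val)) {
      val <- seq_to_idx(oriented[[ori]][[est_id]])
      assign(key, val, envir = eint_cache)
    }
    val
  }
  out <- vector("list", nrow(groups))
  for (r in seq_len(nrow(groups))) {
    eint <- get_eint(groups$est_id[r], groups$strand[r])
    ext <- extend_diagonal(eint, cints[[groups$contig_id[r]]], groups$diag[r],
                           groups$lo[r], groups$hi[r])
    out[[r]] <- tibble::tibble(
      est_id = groups$est_id[r], contig_id = groups$contig_id[r],
      est_start = ext$e1 - 1L, est_end = ext$e2,
      genome_start = ext$e1 + groups$diag[r] - 1L,
      genome_end = ext$e2 + groups$diag[r],
      strand = groups$strand[r],
      identity = ext$identity,
      match_len = ext$e2 - ext$e1 + 1L
    )
  }
  dplyr::distinct(dplyr::bind_rows(out))
}

# --- intron placement ------------------------------------------------------

empty_candidates <- function() {
  tibble::tibble(
    contig_id = character(), start = integer(), end = integer(),
    length = integer(), sequence = character(), donor = character(),
    acceptor = character(), exon5 = character(), exon3 = character(),
    est_id = character(), est_junction = integer()
  )
}

intron_candidate_row <- function(genome_seq, contig_id, istart, iend, est_id,
                                 junction = NA_integer_) {
  seq <- substr(genome_seq, istart + 1L, iend)
  len <- iend - istart
  tibble::tibble(
    contig_id = contig_id, start = istart, end = iend, length = len,
    sequence = seq,
    donor = substr(seq, 1L, 2L),
    acceptor = substr(seq, len - 1L, len),
    exon5 = safe_substr(genome_seq, istart - 2L, istart),
    exon3 = safe_substr(genome_seq, iend + 1L, iend + 3L),
    est_id = est_id, est_junction = junction
  )
}

#' Enumerate candidate intron placements between two adjacent HSPs
#'
#' Local alignment cannot always place a splice junction exactly: when the
#' flanking HSPs overlap on the EST by `b` bases, any of the `b + 1` splits
#' of the shared bases is consistent with the alignment. Each split slides
#' the exon/intron junction by one base while conserving every EST base; all
#' placements share the same intron length. Placements whose genomic gap
#' falls outside `[min_intron, max_intron]` are excluded. HSP pairs separated
#' by unaligned EST bases yield no candidates.
#'
#' @param left,right Single-row HSP tibbles (or lists), adjacent on the EST,
#'   same contig and strand.
#' @param genome_seq Sequence of the shared contig (character string).
#' @param min_intron,max_intron Genomic gap bounds in nt (defaults 30 and
#'   20000).
#' @return A tibble of intron candidates (possibly empty), one row per
#'   junction split.
#' @export
enumerate_intron_placements <- function(left, right, genome_seq,
                                        min_intron = 30L, max_intron = 20000L) {
  if (left$contig_id != right$contig_id || left$strand != right$strand) {
    stop("HSPs must be on the same contig and strand")
  }
  b <- left$est_end - right$est_start
  if (b < 0L) return(empty_candidates())
  splits <- seq.int(right$est_start, left$est_end)
  istart <- left$genome_end - (left$est_end - splits)
  iend <- right$genome_start + (splits - right$est_start)
  keep <- (iend - istart) >= min_intron & (iend - istart) <= max_intron &
    istart >= 0L & iend <= nchar(genome_seq)
  if (!any(keep)) return(empty_candidates())
  purrr::map2(istart[keep], iend[keep], function(s, e) {
    intron_candidate_row(genome_seq, left$contig_id, s, e, left$est_id,
                         junction = s - (left$genome_end - left$est_end))
  }) |>
    dplyr::bind_rows()
}

#' Resolve the exact splice sites among candidate placements
#'
#' Scores every candidate's 13-nt 5' window (last 3 exon bases + first 10
#' intron bases) and 17-nt 3' window (last 14 intron bases + first 3 exon
#' bases) under each supplied species matrix set, using mean log probability
#' across sets. If one candidate simultaneously maximizes both the 5' and 3'
#' scores it wins; otherwise the candidate with the greatest 5' + 3' score
#' sum wins. Remaining ties go to the leftmost genomic start.
#'
#' @param cands Candidate tibble from [enumerate_intron_placements()]
#'   (at least one row).
#' @param pwm_sets List of matrix sets, each a list with elements
#'   `five_prime` (13-position PWM) and `three_prime` (17-position PWM) of
#'   kind `"probs"`. Sets from different species are combined by averaging
#'   (`combine = "mean"`); sets for different intron classes by taking each
#'   candidate's best class (`combine = "max"`).
#' @param combine How to combine scores across sets: `"mean"` or `"max"`.
#' @return The single winning candidate row, with `score5` and `score3`
#'   columns appended (combined log2 probabilities).
#' @export
resolve_splice_sites <- function(cands, pwm_sets, combine = c("mean", "max")) {
  if (nrow(cands) == 0L) stop("no candidates to resolve")
  combine <- match.arg(combine)
  comb_fun <- if (combine == "mean") rowMeans else
    function(m) apply(m, 1L, max)
  w5 <- paste0(cands$exon5, substr(cands$sequence, 1L, 10L))
  w3 <- paste0(substr(cands$sequence, cands$length - 13L, cands$length),
               cands$exon3)
  score_set <- function(windows, which) {
    per_set <- vapply(pwm_sets, function(set) {
      vapply(windows, function(w) log2(score_5ss(w, set[[which]])), numeric(1))
    }, numeric(length(windows)))
    comb_fun(matrix(per_set, nrow = length(windows)))
  }
  if (nrow(cands) == 1L) {
    cands$score5 <- score_set(w5, "five_prime")
    cands$score3 <- score_set(w3, "three_prime")
    return(cands)
  }
  s5 <- score_set(w5, "five_prime")
  s3 <- score_set(w3, "three_prime")
  cands$score5 <- s5
  cands$score3 <- s3
  top5 <- which(s5 >= max(s5) - 1e-12)
  top3 <- which(s3 >= max(s3) - 1e-12)
  both <- intersect(top5, top3)
  pick <- if (length(both) > 0L) both else which(s5 + s3 >= max(s5 + s3) - 1e-12)
  pick <- pick[order(cands$start[pick])][1L]
  cands[pick, ]
}

#' Categorize intron terminal dinucleotides
#'
#' @param donor,acceptor 2-nt terminal dinucleotides.
#' @return Character vector over `"GT_AG"`, `"GC_AG"`, `"AT_AC"`, `"OTHER"`.
#' @export
terminal_category <- function(donor, acceptor) {
  dplyr::case_when(
    donor == "GT" & acceptor == "AG" ~ "GT_AG",
    donor == "GC" & acceptor == "AG" ~ "GC_AG",
    donor == "AT" & acceptor == "AC" ~ "AT_AC",
    TRUE ~ "OTHER"
  )
}

#' Classify intron termini
#'
#' Adds a `terminal` column derived solely from the first and last two intron
#' bases. Accepts an intron tibble (with `donor`/`acceptor` or `sequence`
#' columns) or a character vector of intron sequences.
#'
#' @param x Intron tibble or character vector of sequences (>= 4 nt).
#' @return The tibble with a `terminal` column, or a character vector of
#'   categories.
#' @export
classify_termini <- function(x) {
  if (is.character(x)) {
    if (any(nchar(x) < 4L)) stop("sequences must be at least 4 nt")
    return(terminal_category(substr(x, 1L, 2L),
                             substr(x, nchar(x) - 1L, nchar(x))))
  }
  if (!all(c("donor", "acceptor") %in% names(x))) {
    x$donor <- substr(x$sequence, 1L, 2L)
    x$acceptor <- substr(x$sequence, nchar(x$sequence) - 1L, nchar(x$sequence))
  }
  dplyr::mutate(x, terminal = terminal_category(.data$donor, .data$acceptor))
}

#' Intron length summary
#'
#' @param introns Intron tibble with a `length` column, or a numeric vector
#'   of lengths.
#' @return A list with `mode` (most frequent exact length, ties to the
#'   smallest), `mean`, and `histogram` (tibble of `length`, `n`).
#' @export
intron_length_stats <- function(introns) {
  lens <- if (is.data.frame(introns)) introns$length else introns
  if (length(lens) == 0L) stop("no introns supplied")
  hist <- tibble::tibble(length = lens) |>
    dplyr::count(.data$length, name = "n") |>
    dplyr::arrange(.data$length)
  list(
    mode = hist$length[which.max(hist$n)],
    mean = mean(lens),
    histogram = hist
  )
}

# One matrix set per intron class; resolution takes each candidate's best
# class, so both major- and minor-spliceosome junctions are scored sharply.
default_resolution_sets <- function() {
  pwm <- the_fixture_set()$pwm
  lapply(INTRON_CLASSES, function(cl) {
    list(five_prime = pwm$five_prime[[cl]], three_prime = pwm$three_prime[[cl]])
  })
}

# Keep a chain of HSPs that advances on both axes. Adjacent HSPs may
# overlap on the EST (junction ambiguity) and slightly on the genome; they
# only need strictly increasing end coordinates on both axes.
chain_hsps <- function(hsps) {
  hsps <- dplyr::arrange(hsps, .data$est_start, .data$genome_start)
  keep <- integer(0)
  for (i in seq_len(nrow(hsps))) {
    if (length(keep) == 0L) {
      keep <- i
      next
    }
    j <- keep[length(keep)]
    if (hsps$est_end[i] > hsps$est_end[j] &&
        hsps$genome_start[i] >= hsps$genome_start[j] &&
        hsps$genome_end[i] > hsps$genome_end[j]) {
      keep <- c(keep, i)
    }
  }
  hsps[keep, ]
}

#' Discover introns from EST-to-genome matches
#'
#' End-to-end inference: (optionally) match ESTs to contigs with the built-in
#' anchor matcher, filter HSPs on identity and length, pick the best-matching
#' contig per EST, and, for each adjacent HSP pair along the EST, enumerate
#' all junction placements and resolve the exact splice sites by PWM scoring.
#' Multi-intron ESTs are processed gap by gap independently.
#'
#' @param genome Named character vector of contigs (or FASTA path /
#'   DNAStringSet).
#' @param ests Named character vector of ESTs; may be omitted when `hsps`
#'   is supplied.
#' @param hsps Optional precomputed HSP tibble (e.g. from
#'   [read_blast_tab()]); when `NULL`, [match_ests()] is run.
#' @param min_identity,min_len HSP filters (defaults 98 and 35).
#' @param min_intron,max_intron Intron length bounds (defaults 30 and 20000).
#' @param pwm_sets Matrix sets for [resolve_splice_sites()]; default is one
#'   set per intron class built from the packaged PWMs, combined per
#'   candidate by `combine`.
#' @param combine Score combination across sets (see
#'   [resolve_splice_sites()]); defaults to `"max"` for the per-class
#'   default sets and `"mean"` for user-supplied (per-species) sets.
#' @param k Anchor k-mer length for the built-in matcher.
#' @return A tibble of resolved intron candidates, one row per EST gap, with
#'   a `terminal` column.
#' @export
discover_introns <- function(genome, ests = NULL, hsps = NULL,
                             min_identity = 98, min_len = 35,
                             min_intron = 30L, max_intron = 20000L,
                             pwm_sets = NULL, combine = NULL, k = 16L) {
  genome <- as_named_seqs(genome, "genome")
  if (is.null(hsps)) {
    if (is.null(ests)) stop("supply either `ests` or `hsps`")
    hsps <- match_ests(genome, ests, k = k)
  }
  hsps <- filter_hsps(hsps, min_identity, min_len)
  if (is.null(pwm_sets)) {
    pwm_sets <- default_resolution_sets()
    if (is.null(combine)) combine <- "max"
  }
  if (is.null(combine)) combine <- "mean"
  out <- list()
  for (df in split(hsps, hsps$est_id)) {
    if (nrow(df) == 0L) next
    best <- select_best_contig(df)
    df <- df[df$contig_id == best, ]
    strands <- table(df$strand)
    df <- df[df$strand == names(strands)[which.max(strands)], ]
    df <- chain_hsps(df)
    if (nrow(df) < 2L) next
    gseq <- genome[[best]]
    for (i in seq_len(nrow(df) - 1L)) {
      cands <- enumerate_intron_placements(
        df[i, ], df[i + 1L, ], gseq, min_intron, max_intron
      )
      if (nrow(cands) == 0L) next
      out[[length(out) + 1L]] <- resolve_splice_sites(cands, pwm_sets, combine)
    }
  }
  if (length(out) == 0L) {
    return(classify_termini(empty_candidates()))
  }
  classify_termini(dplyr::bind_rows(out))
}
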
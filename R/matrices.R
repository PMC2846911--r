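#' Splice-site matrices
#'
#' A `splice_matrix` is a positions-by-base (A, C, G, T) numeric matrix with
#' metadata describing which splice signal it models. Three kinds exist:
#' `"counts"` (a frequency matrix of observed sites), `"probs"` (a position
#' weight matrix of per-position base probabilities) and `"logodds"`
#' (log2 weights against a background composition). Conventional dimensions
#' follow the SpliceRack layout: 13 positions for the 5' splice site (the
#' first 3 exonic), 17 for the 3' splice site (the last 3 exonic) and 12 for
#' the branch site (all intronic).
#'
#' @param values Numeric matrix with one row per position and columns
#'   A, C, G, T.
#' @param site_type One of `"five_prime"`, `"three_prime"`, `"branch"`.
#' @param intron_class One of `"U2_GTAG"`, `"U2_GCAG"`, `"U12_GTAG"`,
#'   `"U12_ATAC"`.
#' @param kind Matrix kind: `"counts"`, `"probs"` or `"logodds"`.
#' @param exon_offset Number of exonic positions at the exon-proximal edge
#'   (3 for splice sites, 0 for branch matrices).
#' @param species Free-text species tag.
#' @param ... Further metadata stored as attributes (e.g. `prob_floor`,
#'   `pseudocount`, `background`).
#' @return A `splice_matrix` object.
#' @export
splice_matrix <- function(values, site_type, intron_class, kind = "counts",
                          exon_offset = 0L, species = "unspecified", ...) {
  values <- as.matrix(values)
  colnames(values) <- BASES
  x <- structure(values,
    site_type = site_type, intron_class = intron_class, kind = kind,
    exon_offset = as.integer(exon_offset), species = species,
    class = "splice_matrix"
  )
  extra <- list(...)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  validate_splice_matrix(x)
  x
}

SITE_TYPES <- c("five_prime", "three_prime", "branch")
INTRON_CLASSES <- c("U2_GTAG", "U2_GCAG", "U12_GTAG", "U12_ATAC")

validate_splice_matrix <- function(x) {
  if (!is.matrix(x) || ncol(x) != 4L) {
    stop("splice_matrix values must have 4 columns (A, C, G, T)")
  }
  if (!attr(x, "site_type") %in% SITE_TYPES) {
    stop("site_type must be one of: ", paste(SITE_TYPES, collapse = ", "))
  }
  if (!attr(x, "intron_class") %in% INTRON_CLASSES) {
    stop("intron_class must be one of: ", paste(INTRON_CLASSES, collapse = ", "))
  }
  kind <- attr(x, "kind")
  if (!kind %in% c("counts", "probs", "logodds")) {
    stop("kind must be counts, probs or logodds")
  }
  if (kind == "counts" && any(x < 0)) stop("counts must be non-negative")
  if (kind == "probs") {
    sums <- rowSums(x)
    if (any(abs(sums - 1) > 1e-9)) {
      stop("probability rows must sum to 1 within 1e-9")
    }
  }
  invisible(x)
}

sm_kind <- function(x) attr(x, "kind")
sm_site_type <- function(x) attr(x, "site_type")
sm_class <- function(x) attr(x, "intron_class")
sm_exon_offset <- function(x) attr(x, "exon_offset")

#' @export
print.splice_matrix <- function(x, ...) {
  cat(sprintf(
    "<splice_matrix> %s %s [%s], %d positions (%d exonic), species %s\n",
    sm_site_type(x), sm_class(x), sm_kind(x), nrow(x),
    sm_exon_offset(x), attr(x, "species")
  ))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Tidy a splice matrix into long format
#'
#' @param x A `splice_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `value`.
#' @method tidy splice_matrix
#' @export
tidy.splice_matrix <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(nrow(x)), each = 4L),
    base = rep(BASES, nrow(x)),
    value = as.numeric(t(unclass(x)))
  )
}

#' Read a splice matrix from a flat file
#'
#' The file dialect is self-describing plain text: `#key value` header lines
#' (at least `site_type`, `intron_class` and `exon_offset`; `species` and
#' `kind` optional), followed by one whitespace-separated `A C G T` row per
#' position.
#'
#' @param path Path to a matrix file.
#' @return A `splice_matrix`.
#' @export
#' @examples
#' p <- tempfile()
#' writeLines(c("#site_type branch", "#intron_class U12_GTAG",
#'              "#exon_offset 0", "1 2 3 4"), p)
#' read_splice_matrix(p)
read_splice_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  meta <- list(species = "unspecified", kind = "counts")
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
      if (length(kv) < 2L) {
        stop(sprintf("%s:%d: malformed header line '%s'", path, i, ln))
      }
      meta[[kv[1L]]] <- paste(kv[-1L], collapse = " ")
    } else {
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals)) {
        stop(sprintf("%s:%d: expected 4 numeric values, got '%s'", path, i, ln))
      }
      if (meta$kind == "counts" && any(vals < 0)) {
        stop(sprintf("%s:%d: negative count", path, i))
      }
      rows[[length(rows) + 1L]] <- vals
    }
  }
  for (req in c("site_type", "intron_class", "exon_offset")) {
    if (is.null(meta[[req]])) stop(path, ": missing required header #", req)
  }
  if (length(rows) == 0L) stop(path, ": no matrix rows")
  splice_matrix(do.call(rbind, rows),
    site_type = meta$site_type, intron_class = meta$intron_class,
    kind = meta$kind, exon_offset = as.integer(meta$exon_offset),
    species = meta$species
  )
}

#' Write a splice matrix to the flat-file format
#'
#' Inverse of [read_splice_matrix()]: the round trip is loss-free modulo
#' whitespace normalization.
#'
#' @param x A `splice_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_splice_matrix <- function(x, path) {
  validate_splice_matrix(x)
  hdr <- c(
    paste("#site_type", sm_site_type(x)),
    paste("#intron_class", sm_class(x)),
    paste("#species", attr(x, "species")),
    paste("#exon_offset", sm_exon_offset(x)),
    paste("#kind", sm_kind(x))
  )
  body <- apply(unclass(x), 1L, function(r) paste(sprintf("%.10g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Convert a frequency matrix to a position weight matrix
#'
#' Rows are normalized to probabilities. Probabilities below `prob_floor` are
#' raised to the floor and the row renormalized, so a single unobserved base
#' cannot veto a whole sequence in product scoring.
#'
#' @param m A `splice_matrix` of kind `"counts"`.
#' @param prob_floor Smallest allowed probability before renormalization
#'   (default 1e-4); use 0 for no floor.
#' @return A `splice_matrix` of kind `"probs"`.
#' @export
to_pwm <- function(m, prob_floor = 1e-4) {
  stopifnot(inherits(m, "splice_matrix"))
  totals <- rowSums(unclass(m))
  if (any(totals <= 0)) {
    stop("position ", which(totals <= 0)[1L], " has zero total count")
  }
  p <- unclass(m) / totals
  if (prob_floor > 0) {
    p[p < prob_floor] <- prob_floor
    p <- p / rowSums(p)
  }
  splice_matrix(p,
    site_type = sm_site_type(m), intron_class = sm_class(m), kind = "probs",
    exon_offset = sm_exon_offset(m), species = attr(m, "species"),
    prob_floor = prob_floor
  )
}

#' Convert a frequency matrix to a log-odds matrix
#'
#' Weights are `log2(((count + pseudocount) / (total + 4 * pseudocount)) /
#' background)`, with a small pseudocount (default 0.001) guarding against
#' unobserved bases.
#'
#' @param m A `splice_matrix` of kind `"counts"`.
#' @param pseudocount Count added to every cell (default 0.001).
#' @param background Per-base background probabilities summing to 1
#'   (default uniform 0.25).
#' @return A `splice_matrix` of kind `"logodds"`.
#' @export
to_log_odds <- function(m, pseudocount = 0.001, background = rep(0.25, 4)) {
  stopifnot(inherits(m, "splice_matrix"))
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 positive probabilities")
  }
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  counts <- unclass(m)
  totals <- rowSums(counts)
  p <- (counts + pseudocount) / (totals + 4 * pseudocount)
  w <- log2(sweep(p, 2L, background, "/"))
  splice_matrix(w,
    site_type = sm_site_type(m), intron_class = sm_class(m), kind = "logodds",
    exon_offset = sm_exon_offset(m), species = attr(m, "species"),
    pseudocount = pseudocount, background = background
  )
}

#' Consensus sequence of a splice matrix
#'
#' The per-position argmax base (ties broken alphabetically).
#'
#' @param x A `splice_matrix`.
#' @return A character string of length `nrow(x)`.
#' @export
consensus_window <- function(x) {
  paste(BASES[apply(unclass(x), 1L, which.max)], collapse = "")
}

# Score one window (integer base codes) against a matrix.
# Ambiguous bases (NA codes) contribute the background probability under a
# probability matrix and weight 0 under a log-odds matrix.
window_score_idx <- function(mat, idx, ambig_prob = 0.25) {
  v <- unclass(mat)[cbind(seq_len(nrow(mat)), idx)]
  if (sm_kind(mat) == "logodds") {
    v[is.na(idx)] <- 0
    sum(v)
  } else {
    v[is.na(idx)] <- ambig_prob
    prod(v)
  }
}

#' Score a fixed splice-site window
#'
#' Under a probability matrix the score is the product over positions of the
#' per-base probabilities; under a log-odds matrix it is the sum of weights.
#' The window must already include the matrix's exonic positions (e.g. the
#' 13-nt 5' window is the last 3 exon bases plus the first 10 intron bases).
#'
#' @param window Character string whose length equals `nrow(pwm)`.
#' @param pwm A `splice_matrix` of kind `"probs"` or `"logodds"`.
#' @return A single numeric score.
#' @export
score_5ss <- function(window, pwm) {
  stopifnot(inherits(pwm, "splice_matrix"))
  if (nchar(window) != nrow(pwm)) {
    stop(sprintf(
      "window length %d does not match matrix length %d",
      nchar(window), nrow(pwm)
    ))
  }
  window_score_idx(pwm, seq_to_idx(window))
}

# Admissible branch window start offsets for an intron of length n.
# Offsets are relative to the intron 3' end (-1 = last base); windows must
# fall entirely inside `search_range` and must not overlap intron positions
# +1..+10 reserved for the 5' splice site.
branch_offsets <- function(n, window_len, search_range = c(-40, -5)) {
  lo <- max(search_range[1L], 10L - n)
  hi <- search_range[2L] - window_len + 1L
  if (lo > hi) return(integer(0))
  seq.int(lo, hi)
}

#' Best-scoring branch window in an intron
#'
#' Slides a window of `window_len` positions over all fully-contained
#' placements within `search_range` (offsets relative to the intron 3' end)
#' and returns the maximum score; ties go to the leftmost (5'-most) window.
#' Windows overlapping intron positions +1..+10 are excluded so the scan
#' never reads into the 5' splice site of short introns.
#'
#' @param intron Intron sequence (character string).
#' @param mat Branch `splice_matrix` of kind `"probs"` or `"logodds"`.
#' @param window_len Window length in positions; defaults to `nrow(mat)`.
#' @param search_range Scan interval relative to the 3' splice site,
#'   default `c(-40, -5)`.
#' @return A list with elements `score` (window probability or log-odds sum),
#'   `offset` (window start offset, e.g. -20) and `window` (the sequence).
#' @export
score_branch_max <- function(intron, mat, window_len = nrow(mat),
                             search_range = c(-40, -5)) {
  stopifnot(inherits(mat, "splice_matrix"))
  if (window_len != nrow(mat)) {
    stop("window_len must equal the matrix length")
  }
  n <- nchar(intron)
  offs <- branch_offsets(n, window_len, search_range)
  if (length(offs) == 0L) {
    stop(sprintf("intron too short for branch scan (%d nt, window %d)", n, window_len))
  }
  idx <- seq_to_idx(intron)
  scores <- vapply(offs, function(o) {
    s <- n + o + 1L
    window_score_idx(mat, idx[s:(s + window_len - 1L)])
  }, numeric(1))
  best <- which.max(scores)
  s <- n + offs[best] + 1L
  list(
    score = scores[best], offset = offs[best],
    window = substr(intron, s, s + window_len - 1L)
  )
}

#' Build a U2 branch-site frequency matrix from best-scoring windows
#'
#' For every U2 intron, the branch window achieving the best probability
#' under a U12 branch PWM is located (ties to the leftmost window); the
#' per-intron best windows are tallied into a frequency matrix. This mirrors
#' the construction of a major-spliceosome branch matrix when no curated one
#' exists: each contributing intron adds exactly 1 to every position's
#' column sum.
#'
#' @param u2_introns A tibble with a `sequence` column, or a character vector
#'   of intron sequences.
#' @param u12_branch_pwm Branch `splice_matrix` of kind `"probs"` used to
#'   locate the windows.
#' @param window_len Window length (default 12).
#' @param search_range Scan interval relative to the 3' end, default
#'   `c(-40, -5)`.
#' @return A `splice_matrix` of kind `"counts"` with `window_len` positions.
#' @export
build_u2_branch_matrix <- function(u2_introns, u12_branch_pwm,
                                   window_len = 12L,
                                   search_range = c(-40, -5)) {
  seqs <- if (is.data.frame(u2_introns)) u2_introns$sequence else u2_introns
  if (length(seqs) == 0L) stop("no introns supplied")
  if (window_len != nrow(u12_branch_pwm)) {
    stop("window_len must equal the branch PWM length")
  }
  counts <- matrix(0, nrow = window_len, ncol = 4L, dimnames = list(NULL, BASES))
  skipped <- 0L
  for (s in seqs) {
    if (length(branch_offsets(nchar(s), window_len, search_range)) == 0L) {
      skipped <- skipped + 1L
      next
    }
    win <- score_branch_max(s, u12_branch_pwm, window_len, search_range)$window
    idx <- seq_to_idx(win)
    for (i in seq_len(window_len)) {
      if (!is.na(idx[i])) counts[i, idx[i]] <- counts[i, idx[i]] + 1
    }
  }
  if (skipped > 0L) {
    warning(skipped, " intron(s) too short for the branch scan were skipped")
  }
  if (sum(counts) == 0) stop("no intron admitted a branch window")
  splice_matrix(counts,
    site_type = "branch", intron_class = "U2_GTAG", kind = "counts",
    exon_offset = 0L, species = attr(u12_branch_pwm, "species")
  )
}
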
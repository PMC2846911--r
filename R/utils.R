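# Internal sequence utilities. Sequences are plain upper-case character
# strings externally and integer base codes (A=1, C=2, G=3, T=4, NA for
# ambiguity codes) internally.

BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  N = c("A", "C", "G", "T")
)

seq_to_idx <- function(x) {
  match(utf8ToInt(toupper(x)), c(65L, 67L, 71L, 84L))
}

idx_to_seq <- function(idx) {
  chars <- c(BASES, "N")
  idx[is.na(idx)] <- 5L
  paste(chars[idx], collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substr() that never walks off the sequence: out-of-range positions pad "N"
safe_substr <- function(x, start, end) {
  n <- nchar(x)
  lead <- max(0L, 1L - start)
  trail <- max(0L, end - n)
  core <- substr(x, max(1L, start), min(n, end))
  paste0(strrep("N", lead), core, strrep("N", trail))
}

# total length of the union of 0-based half-open intervals
interval_union_len <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0L
  cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' character sequences named by the first whitespace-delimited token of each
#' record header.
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

as_named_seqs <- function(x, arg = "x") {
  if (is.character(x) && length(x) == 1L && file.exists(x) && is.null(names(x))) {
    return(read_fasta(x))
  }
  if (methods::is(x, "DNAStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (!is.character(x) || is.null(names(x))) {
    stop(sprintf("`%s` must be a named character vector, DNAStringSet or FASTA path", arg))
  }
  toupper(x)
}
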
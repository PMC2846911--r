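# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately avoid the package's scoring internals:
# they work on character vectors with explicit loops.

oracle_window_score <- function(mat, window) {
  chars <- strsplit(window, "")[[1]]
  vals <- numeric(length(chars))
  for (i in seq_along(chars)) {
    j <- match(chars[i], c("A", "C", "G", "T"))
    vals[i] <- if (is.na(j)) {
      if (attr(mat, "kind") == "logodds") 0 else 0.25
    } else {
      unclass(mat)[i, j]
    }
  }
  if (attr(mat, "kind") == "logodds") sum(vals) else prod(vals)
}

# exhaustive branch-window scan: every offset in [range] with the window
# fully inside the range and clear of intron positions 1..10
oracle_branch_max <- function(intron, mat, window_len = nrow(mat),
                              range = c(-40, -5)) {
  n <- nchar(intron)
  best <- NULL
  for (o in seq(range[1], range[2])) {
    s <- n + o + 1
    if (o < range[1] || o + window_len - 1 > range[2]) next
    if (s < 11 || s + window_len - 1 > n) next
    sc <- oracle_window_score(mat, substr(intron, s, s + window_len - 1))
    if (is.null(best) || sc > best$score) best <- list(score = sc, offset = o)
  }
  best
}

oracle_u2_branch_matrix <- function(seqs, pwm, window_len = 12) {
  counts <- matrix(0, window_len, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (s in seqs) {
    b <- oracle_branch_max(s, pwm, window_len)
    if (is.null(b)) next
    w <- strsplit(substr(s, nchar(s) + b$offset + 1,
                         nchar(s) + b$offset + window_len), "")[[1]]
    for (i in seq_along(w)) {
      counts[i, match(w[i], c("A", "C", "G", "T"))] <-
        counts[i, match(w[i], c("A", "C", "G", "T"))] + 1
    }
  }
  counts
}

# every consistent split of the EST overlap between two adjacent HSPs
oracle_junction_splits <- function(left, right) {
  b <- left$est_end - right$est_start
  if (b < 0) return(NULL)
  splits <- right$est_start:left$est_end
  data.frame(
    start = left$genome_end - (left$est_end - splits),
    end = right$genome_start + (splits - right$est_start)
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_count_matrix <- function(len, site_type = "branch",
                                intron_class = "U12_GTAG") {
  splice_matrix(matrix(sample(0:20, len * 4, replace = TRUE), len, 4),
                site_type, intron_class, "counts",
                exon_offset = if (site_type == "branch") 0L else 3L)
}

one_hot_matrix <- function(window, site_type = "branch",
                           intron_class = "U12_GTAG", kind = "probs") {
  chars <- strsplit(window, "")[[1]]
  m <- matrix(0, length(chars), 4)
  for (i in seq_along(chars)) m[i, match(chars[i], c("A", "C", "G", "T"))] <- 1
  splice_matrix(m, site_type, intron_class, kind,
                exon_offset = if (site_type == "branch") 0L else 3L)
}

# single small simulated dataset reused across test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(seed = 11, n_genes = 12,
                                            est_error_rate = 0))
    }
    cache
  }
})
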
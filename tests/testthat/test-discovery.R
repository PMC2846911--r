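hsp_row <- function(est_id = "e1", contig_id = "c1", est_start = 0L,
                    est_end = 100L, genome_start = 0L, genome_end = 100L,
                    strand = "+", identity = 100, match_len = NULL) {
  tibble::tibble(
    est_id = est_id, contig_id = contig_id,
    est_start = est_start, est_end = est_end,
    genome_start = genome_start, genome_end = genome_end,
    strand = strand, identity = identity,
    match_len = if (is.null(match_len)) est_end - est_start else match_len
  )
}

test_that("HSP filter thresholds are inclusive on both boundaries", {
  h <- dplyr::bind_rows(
    hsp_row(identity = 98.0, est_end = 35L, genome_end = 35L),
    hsp_row(identity = 97.9, est_end = 500L, genome_end = 500L),
    hsp_row(identity = 100, est_end = 34L, genome_end = 34L)
  )
  kept <- filter_hsps(h)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$identity, 98.0)
  expect_equal(nrow(filter_hsps(h[0, ])), 0L)
})

test_that("best contig maximizes distinct EST bases covered, ties lexicographic", {
  h <- dplyr::bind_rows(
    hsp_row(contig_id = "c2", est_start = 0L, est_end = 300L),
    hsp_row(contig_id = "c1", est_start = 0L, est_end = 300L),
    hsp_row(contig_id = "c1", est_start = 250L, est_end = 500L)
  )
  expect_equal(select_best_contig(h), "c1")
  # overlapping HSPs on one contig count bases once: c1 covers 500, not 550
  h2 <- dplyr::bind_rows(
    hsp_row(contig_id = "c1", est_start = 0L, est_end = 300L),
    hsp_row(contig_id = "c1", est_start = 200L, est_end = 500L),
    hsp_row(contig_id = "c3", est_start = 0L, est_end = 510L)
  )
  expect_equal(select_best_contig(h2), "c3")
  # exact tie -> lexicographically first
  h3 <- dplyr::bind_rows(
    hsp_row(contig_id = "cb", est_start = 0L, est_end = 100L),
    hsp_row(contig_id = "ca", est_start = 0L, est_end = 100L)
  )
  expect_equal(select_best_contig(h3), "ca")
  expect_error(select_best_contig(h3[0, ]), "no HSPs")
})

test_that("junction enumeration matches the brute-force split oracle", {
  set.seed(21)
  genome <- random_dna(2000)
  for (b in 0:10) {
    left <- hsp_row(est_start = 0L, est_end = 200L,
                    genome_start = 100L, genome_end = 300L)
    right <- hsp_row(est_start = 200L - b, est_end = 400L - b,
                     genome_start = 800L, genome_end = 1000L)
    cands <- enumerate_intron_placements(left, right, genome,
                                         min_intron = 30L)
    oracle <- oracle_junction_splits(left, right)
    expect_equal(nrow(cands), b + 1L)
    expect_equal(cands$start, oracle$start)
    expect_equal(cands$end, oracle$end)
    expect_true(all(cands$sequence ==
                      substring(genome, cands$start + 1, cands$end)))
  }
})

test_that("junction enumeration rejects out-of-range gaps and bad pairs", {
  genome <- strrep("ACGT", 100)
  left <- hsp_row(est_end = 100L, genome_end = 100L)
  right <- hsp_row(est_start = 100L, est_end = 200L,
                   genome_start = 120L, genome_end = 220L)
  expect_equal(nrow(enumerate_intron_placements(left, right, genome,
                                                min_intron = 30L)), 0L)
  right$genome_start <- 150L
  expect_equal(nrow(enumerate_intron_placements(left, right, genome,
                                                min_intron = 30L)), 1L)
  right$contig_id <- "c9"
  expect_error(enumerate_intron_placements(left, right, genome),
               "same contig")
  # HSPs separated on the EST axis cannot form a clean junction
  right <- hsp_row(est_start = 120L, est_end = 200L,
                   genome_start = 400L, genome_end = 480L)
  expect_equal(nrow(enumerate_intron_placements(left, right, genome)), 0L)
})

test_that("splice-site resolution picks the planted junction and applies the sum rule", {
  set.seed(33)
  pwm <- the_fixture_set()$pwm
  sets <- list(list(five_prime = pwm$five_prime$U2_GTAG,
                    three_prime = pwm$three_prime$U2_GTAG))
  # a genome with one consensus U2 junction; candidates shift it by -2..+2
  exon1 <- paste0(random_dna(57), "CAG")
  intron <- paste0("GTAAGT", random_dna(48), "TTTTTTTTTTTCAG")
  exon2 <- paste0("G", random_dna(59))
  genome <- paste0(exon1, intron, exon2)
  true_start <- 60L
  true_end <- true_start + nchar(intron)
  cands <- dplyr::bind_rows(lapply(-2:2, function(d) {
    minorintron:::intron_candidate_row(genome, "c1", true_start + d,
                                       true_end + d, "e1")
  }))
  best <- resolve_splice_sites(cands, sets)
  expect_equal(best$start, true_start)
  expect_equal(best$end, true_end)

  # single candidate comes back unchanged
  one <- resolve_splice_sites(cands[2, ], sets)
  expect_equal(one$start, cands$start[2])

  # when no candidate dominates both windows the larger score sum wins
  mk_cand <- function(sequence, exon5, exon3, start) {
    tibble::tibble(
      contig_id = "c1", start = start, end = start + nchar(sequence),
      length = nchar(sequence), sequence = sequence,
      donor = substr(sequence, 1, 2),
      acceptor = substr(sequence, nchar(sequence) - 1, nchar(sequence)),
      exon5 = exon5, exon3 = exon3, est_id = "e1", est_junction = NA_integer_
    )
  }
  a <- mk_cand(paste0("GTAAGT", strrep("C", 30), strrep("A", 14)),
               exon5 = "CAG", exon3 = "AAA", start = 10L)   # best 5', poor 3'
  b <- mk_cand(paste0("GTAAGT", strrep("C", 30), strrep("T", 12), "AG"),
               exon5 = "CTT", exon3 = "GAA", start = 20L)   # poor 5', best 3'
  res <- resolve_splice_sites(dplyr::bind_rows(a, b), sets)
  expect_gt(res$score3, -40) # b scored, not defaulted
  expect_equal(res$start, 20L) # b: lower 5' score but much larger 5'+3' sum
})

test_that("terminal dinucleotide categories follow the donor/acceptor pair", {
  expect_equal(classify_termini("GTATCCTTTAG"), "GT_AG")
  expect_equal(classify_termini("GCAAGTTTTAG"), "GC_AG")
  expect_equal(classify_termini(paste0("ATATCCTTTC", strrep("N", 20), "TTTTAC")),
               "AT_AC")
  expect_equal(classify_termini("CTAAGTTAAAG"), "OTHER")
  expect_error(classify_termini("GT"), "at least 4")
  df <- tibble::tibble(sequence = c("GTXXAG", "ATXXAC"))
  expect_equal(classify_termini(df)$terminal, c("GT_AG", "AT_AC"))
})

test_that("length statistics report mode (smallest on ties), mean and histogram", {
  s <- intron_length_stats(c(60, 60, 70))
  expect_equal(s$mode, 60)
  expect_equal(s$mean, 63.33, tolerance = 1e-3)
  expect_equal(intron_length_stats(c(50, 50, 80, 80))$mode, 50)
  expect_equal(sum(s$histogram$n), 3)
  expect_error(intron_length_stats(numeric(0)), "no introns")
})

test_that("tabular alignment import converts coordinates and strands", {
  path <- withr::local_tempfile()
  writeLines(paste(c("e1", "c1", 99.5, 50, 0, 0, 11, 60, 101, 150, 1e-20, 90),
                   collapse = "\t"), path)
  h <- read_blast_tab(path)
  expect_equal(h$est_start, 10L)
  expect_equal(h$est_end, 60L)
  expect_equal(h$genome_start, 100L)
  expect_equal(h$genome_end, 150L)
  expect_equal(h$strand, "+")
  expect_equal(h$match_len, 50L)
  # minus strand requires ests and flips the EST axis
  writeLines(paste(c("e1", "c1", 100, 40, 0, 0, 1, 40, 240, 201, 1e-20, 80),
                   collapse = "\t"), path)
  expect_error(read_blast_tab(path), "minus-strand")
  h2 <- read_blast_tab(path, ests = c(e1 = strrep("A", 100)))
  expect_equal(h2$strand, "-")
  expect_equal(h2$est_start, 60L)
  expect_equal(h2$est_end, 100L)
  expect_equal(h2$genome_start, 200L)
  expect_equal(h2$genome_end, 240L)
})

test_that("the anchor matcher recovers exact exon blocks with full identity", {
  ds <- small_sim()
  gid <- ds$truth$contig_id[1]
  est <- ds$ests[grep(paste0(gid, "_est1"), names(ds$ests))]
  h <- match_ests(ds$genome[gid], est)
  h <- filter_hsps(h[h$strand == "+", ])
  n_introns <- sum(ds$truth$contig_id == gid)
  expect_gte(nrow(h), n_introns + 1L)
  expect_true(all(h$identity == 100))
})

test_that("reverse-complemented ESTs are matched and reported on the coding strand", {
  ds <- small_sim()
  gid <- ds$truth$contig_id[1]
  est_id <- paste0(gid, "_est1")
  fwd <- discover_introns(ds$genome[gid], ds$ests[est_id])
  rc <- ds$ests[est_id]
  rc[] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(rc)))
  rev <- discover_introns(ds$genome[gid], rc)
  expect_equal(dplyr::arrange(rev[, c("start", "end")], start),
               dplyr::arrange(fwd[, c("start", "end")], start))
})

test_that("discovered introns are faithful genome substrings and splice back to the EST", {
  ds <- small_sim()
  introns <- discover_introns(ds$genome, ds$ests)
  expect_gt(nrow(introns), 0)
  ok <- vapply(seq_len(nrow(introns)), function(i) {
    g <- ds$genome[[introns$contig_id[i]]]
    identical(substr(g, introns$start[i] + 1, introns$end[i]),
              introns$sequence[i])
  }, logical(1))
  expect_true(all(ok))
  # zero-error data: splicing the intron out reconstructs the EST exactly
  # around every junction
  for (i in sample(nrow(introns), min(10, nrow(introns)))) {
    g <- ds$genome[[introns$contig_id[i]]]
    est <- ds$ests[[introns$est_id[i]]]
    j <- introns$est_junction[i]
    left_est <- substr(est, j - 19, j)
    right_est <- substr(est, j + 1, j + 20)
    expect_identical(substr(g, introns$start[i] - 19, introns$start[i]),
                     left_est)
    expect_identical(substr(g, introns$end[i] + 1, introns$end[i] + 20),
                     right_est)
  }
})
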
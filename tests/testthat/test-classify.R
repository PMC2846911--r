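test_that("5' window scoring is the per-position probability product", {
  uni <- to_pwm(splice_matrix(matrix(1, 13, 4), "five_prime", "U2_GTAG",
                              exon_offset = 3L))
  expect_equal(score_5ss(strrep("A", 13), uni), 0.25^13)

  hot <- one_hot_matrix("CAGGTAAGTTTTT", "five_prime", "U2_GTAG")
  expect_equal(score_5ss("CAGGTAAGTTTTT", hot), 1)
  expect_equal(score_5ss("AAGGTAAGTTTTT", hot), 0)

  toy <- splice_matrix(
    matrix(c(0.5, 0.2, 0.2, 0.1,
             0.1, 0.3, 0.4, 0.2,
             0.2, 0.3, 0.2, 0.3), 3, 4, byrow = TRUE),
    "branch", "U2_GTAG", kind = "probs"
  )
  expect_equal(score_5ss("ACG", toy), 0.5 * 0.3 * 0.2) # 0.03
  expect_error(score_5ss("ACGT", toy), "length")
})

test_that("ambiguous bases contribute background probability or zero weight", {
  uni <- to_pwm(splice_matrix(matrix(c(8, 0, 0, 0), 4, 4, byrow = TRUE),
                              "branch", "U2_GTAG"), prob_floor = 0)
  expect_equal(score_5ss("ANAA", uni), 0.25)
  lo <- to_log_odds(splice_matrix(matrix(c(8, 0, 0, 0), 4, 4, byrow = TRUE),
                                  "branch", "U2_GTAG"))
  expect_equal(score_5ss("ANAA", lo), unname(3 * unclass(lo)[1, 1]))
})

test_that("branch window maximum equals the brute-force scan", {
  set.seed(77)
  for (rep in 1:30) {
    len <- sample(c(12, 13), 1)
    mat <- to_pwm(random_count_matrix(len) |>
                    (\(m) splice_matrix(unclass(m) + 1, "branch", "U12_GTAG"))())
    intron <- random_dna(sample(30:200, 1))
    oracle <- oracle_branch_max(intron, mat, len)
    if (is.null(oracle)) {
      expect_error(score_branch_max(intron, mat), "too short")
    } else {
      got <- score_branch_max(intron, mat)
      expect_equal(got$score, oracle$score)
      expect_equal(got$offset, oracle$offset)
    }
  }
})

test_that("planted one-hot branch windows are found exactly", {
  set.seed(5)
  win <- "TTCCTTAACTAG"
  hot <- one_hot_matrix(win)
  intron <- random_dna(120)
  s <- 120 - 20 + 1
  intron <- paste0(substr(intron, 1, s - 1), win, substr(intron, s + 12, 120))
  res <- score_branch_max(intron, hot)
  expect_equal(res$score, 1)
  expect_equal(res$offset, -20)
})

test_that("z-normalization yields mean 0 and SD 1 on every scored sample", {
  set.seed(101)
  pwm <- the_fixture_set()$pwm
  for (rep in 1:3) {
    introns <- tibble::tibble(
      sequence = vapply(seq_len(sample(20:60, 1)),
                        function(i) random_dna(sample(60:150, 1)),
                        character(1)),
      exon5 = vapply(seq_len(length(sequence)), function(i) random_dna(3),
                     character(1))
    )
    sc <- burge_scores(introns, pwm)
    expect_equal(mean(sc$z5), 0, tolerance = 1e-9)
    expect_equal(stats::sd(sc$z5), 1, tolerance = 1e-9)
    expect_equal(mean(sc$zb), 0, tolerance = 1e-9)
    expect_equal(stats::sd(sc$zb), 1, tolerance = 1e-9)
  }
})

test_that("equal U12/U2 probabilities give zero log ratio", {
  pwm <- the_fixture_set()$pwm
  same <- list(
    five_prime = list(U12_GTAG = pwm$five_prime$U2_GTAG,
                      U12_ATAC = pwm$five_prime$U2_GTAG,
                      U2_GTAG = pwm$five_prime$U2_GTAG),
    branch = list(U12_GTAG = pwm$branch$U2_GTAG,
                  U12_ATAC = pwm$branch$U2_GTAG,
                  U2_GTAG = pwm$branch$U2_GTAG)
  )
  introns <- tibble::tibble(sequence = c(random_dna(80), random_dna(90)),
                            exon5 = c("AAA", "CCC"))
  sc <- minorintron:::burge_raw_scores(introns, same)
  expect_equal(sc$s5, c(0, 0))
  expect_equal(sc$sb, c(0, 0))
})

test_that("planted minor introns rise to the top of the z-score ranking", {
  set.seed(202)
  pwms <- the_fixture_set()$pwm
  u2 <- purrr::map(1:200, function(i) {
    minorintron:::sample_intron("U2_GTAG", sample(60:150, 1), pwms)$sequence
  })
  u12 <- purrr::map(1:5, function(i) {
    minorintron:::sample_intron("U12_GTAG", sample(60:150, 1), pwms,
                                consensus_sites = TRUE)$sequence
  })
  introns <- tibble::tibble(sequence = c(unlist(u2), unlist(u12)))
  sc <- burge_scores(introns, pwms)
  top5 <- order(sc$z5 + sc$zb, decreasing = TRUE)[1:5]
  expect_setequal(top5, 201:205)
})

test_that("the reference rectangle rule is inclusive at the boundary", {
  sc <- tibble::tibble(z5 = c(1.0, 1.5, 2.0), zb = c(2.0, 1.9, 0.5))
  th <- list(min_z5 = 1.0, min_zb = 2.0)
  out <- burge_classify(sc, th)
  expect_equal(out$burge_flag, c(TRUE, FALSE, FALSE))
  expect_error(burge_classify(sc, list(min_z5 = 1)), "thresholds")
})

test_that("consensus-sited introns always pass against a sampled reference set", {
  set.seed(303)
  pwms <- the_fixture_set()$pwm
  seqs <- c(
    purrr::map_chr(1:80, function(i) {
      minorintron:::sample_intron("U2_GTAG", sample(60:150, 1), pwms)$sequence
    }),
    purrr::map_chr(1:10, function(i) {
      minorintron:::sample_intron("U12_GTAG", sample(60:150, 1), pwms,
                                  consensus_sites = TRUE)$sequence
    })
  )
  sc <- burge_scores(tibble::tibble(sequence = seqs), pwms)
  th <- reference_thresholds(sc, reference_introns(), pwms)
  out <- burge_classify(sc, th)
  expect_true(all(out$burge_flag[81:90]))
})

test_that("log-odds classification separates planted classes", {
  set.seed(404)
  ms <- the_fixture_set()
  pwms <- ms$pwm
  cons <- purrr::map_chr(1:5, function(i) {
    minorintron:::sample_intron("U12_GTAG", 100, pwms,
                                consensus_sites = TRUE)$sequence
  })
  out <- sheth_classify(tibble::tibble(sequence = cons), ms$logodds)
  expect_true(all(out$sheth_flag))
  expect_true(all(out$category == "U12_GTAG"))

  u2 <- purrr::map_chr(1:200, function(i) {
    minorintron:::sample_intron("U2_GTAG", sample(60:150, 1), pwms)$sequence
  })
  out2 <- sheth_classify(tibble::tibble(sequence = u2), ms$logodds)
  expect_lte(sum(out2$sheth_flag), 4) # false-positive rate well under 2%

  odd <- sheth_classify(tibble::tibble(sequence = paste0("CT", random_dna(60), "GG")),
                        ms$logodds)
  expect_true(is.na(odd$sheth_flag))
  expect_equal(odd$category, "OTHER")
})

test_that("the RTATCCTT rule matches the curated candidate set exactly", {
  fx <- u12_candidate_fixture()
  expect_equal(nrow(fx), 16L)
  expect_true(five_prime_rule("ATATCCTTTC"))
  expect_false(five_prime_rule("GTATTGTTTT"))
  expect_true(five_prime_rule("GTATCTTTTC"))
  r <- five_prime_rule(fx$sequence)
  expect_identical(r, fx$rule_flag)
  expect_equal(sum(!r), 5L)
  expect_equal(sum(r), 11L)
  # both Cs replaced is too divergent; single replacements pass
  expect_false(five_prime_rule("GTATTTTTTT"))
  expect_error(five_prime_rule("GTATCCT"), "at least 8")
})

test_that("category summaries tally per method with 5'-rule parentheticals", {
  cl <- tibble::tibble(
    terminal = c("AT_AC", "AT_AC", "GT_AG", "GT_AG", "GC_AG", "OTHER"),
    burge_flag = c(TRUE, FALSE, TRUE, FALSE, FALSE, NA),
    sheth_flag = c(TRUE, TRUE, FALSE, FALSE, FALSE, NA),
    rule_flag = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
  s <- summarize_counts(cl)
  get <- function(cat, col) s[[col]][s$category == cat]
  expect_equal(get("U12_ATAC", "burge_n"), 1L)
  expect_equal(get("U12_ATAC", "sheth_n"), 2L)
  expect_equal(get("U12_ATAC", "sheth_rule_n"), 1L)
  expect_equal(get("U12_GTAG", "burge_n"), 1L)
  expect_equal(get("U2_GTAG", "sheth_n"), 2L)
  expect_equal(get("U2_GCAG", "sheth_n"), 1L)
  expect_equal(get("OTHER_ATAC", "burge_n"), 1L)
  expect_equal(get("OTHER", "burge_n"), 1L)

  z <- summarize_counts(cl[0, ])
  expect_true(all(z$sheth_n == 0L))

  # the 16 curated records, all identified by the log-odds method, split
  # 3 AT-AC + 13 GT-AG by termini
  fx <- u12_candidate_fixture()
  s2 <- summarize_counts(tibble::tibble(
    terminal = fx$terminal, sheth_flag = TRUE, rule_flag = fx$rule_flag
  ))
  expect_equal(s2$sheth_n[s2$category == "U12_ATAC"], 3L)
  expect_equal(s2$sheth_n[s2$category == "U12_GTAG"], 13L)
})

test_that("raising a U12 matrix probability never lowers the log ratios", {
  set.seed(55)
  pwms <- the_fixture_set()$pwm
  intron <- tibble::tibble(sequence = random_dna(100), exon5 = "AAA")
  base <- minorintron:::burge_raw_scores(intron, pwms)
  # bump the probability of the observed base at 5' position +1 (row 4)
  obs <- match(substr(intron$sequence, 1, 1), c("A", "C", "G", "T"))
  bumped <- pwms
  v <- unclass(bumped$five_prime$U12_GTAG)
  v[4, obs] <- v[4, obs] + 0.1
  v[4, ] <- v[4, ] / sum(v[4, ])
  bumped$five_prime$U12_GTAG <- splice_matrix(
    v, "five_prime", "U12_GTAG", "probs", 3L
  )
  after <- minorintron:::burge_raw_scores(intron, bumped)
  expect_gte(after$s5, base$s5)
})

test_that("classification pipeline produces a coherent result object", {
  ds <- small_sim()
  introns <- discover_introns(ds$genome, ds$ests)
  cl <- classify_introns(introns)
  expect_s3_class(cl, "u12_classification")
  td <- tidy(cl)
  expect_true(all(c("z5", "zb", "burge_flag", "sheth_flag", "rule_flag",
                    "category") %in% names(td)))
  g <- glance(cl)
  expect_equal(g$n_introns, nrow(td))
  p <- autoplot(cl)
  expect_s3_class(p, "ggplot")
  out <- withr::local_tempdir()
  write_classification(cl, out)
  expect_true(file.exists(file.path(out, "intron_scores.tsv")))
  expect_true(file.exists(file.path(out, "summary.tsv")))
})
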
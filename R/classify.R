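# U12/U2 intron classification: probability-product scoring with z-score
# normalization against a reference U12 set ("B" flag), per-class log-odds
# scoring ("S" flag), and the relaxed RTATCCTT 5'-terminal rule ("R" flag).

u12_class_for <- function(terminal) {
  ifelse(terminal == "AT_AC", "U12_ATAC", "U12_GTAG")
}

u2_class_for <- function(terminal) {
  ifelse(terminal == "GC_AG", "U2_GCAG", "U2_GTAG")
}

five_prime_window <- function(introns) {
  exon5 <- if ("exon5" %in% names(introns)) introns$exon5 else
    rep("NNN", nrow(introns))
  paste0(exon5, substr(introns$sequence, 1L, 10L))
}

three_prime_window <- function(introns) {
  exon3 <- if ("exon3" %in% names(introns)) introns$exon3 else
    rep("NNN", nrow(introns))
  n <- nchar(introns$sequence)
  paste0(substr(introns$sequence, n - 13L, n), exon3)
}

# raw probability-product scores without the sample normalization
burge_raw_scores <- function(introns, pwm) {
  terminal <- if ("terminal" %in% names(introns)) introns$terminal else
    classify_termini(introns$sequence)
  w5 <- five_prime_window(introns)
  n <- nrow(introns)
  res <- tibble::tibble(
    p5_u12 = numeric(n), p5_u2 = numeric(n),
    pb_u12 = numeric(n), pb_u2 = numeric(n),
    branch_offset = integer(n)
  )
  for (i in seq_len(n)) {
    ucl <- u12_class_for(terminal[i])
    res$p5_u12[i] <- score_5ss(w5[i], pwm$five_prime[[ucl]])
    res$p5_u2[i] <- score_5ss(w5[i], pwm$five_prime$U2_GTAG)
    b12 <- score_branch_max(introns$sequence[i], pwm$branch[[ucl]])
    b2 <- score_branch_max(introns$sequence[i], pwm$branch$U2_GTAG)
    res$pb_u12[i] <- b12$score
    res$pb_u2[i] <- b2$score
    res$branch_offset[i] <- b12$offset
  }
  res$s5 <- log2(res$p5_u12 / res$p5_u2)
  res$sb <- log2(res$pb_u12 / res$pb_u2)
  res
}

#' Probability-product splice scores with z-score normalization
#'
#' For each intron, the 13-nt 5' window and the best branch window are scored
#' as probability products under the U12 matrices matching the intron's
#' termini (AT-AC introns use the AT-AC U12 matrices, all others the GT-AG
#' U12 matrices) and under the GT-AG U2 matrices. The log2 ratios
#' `s5 = log2(P5(U12)/P5(U2))` and `sb = log2(Pb(U12)/Pb(U2))` are then
#' normalized to z-scores `z5`, `zb` by subtracting the sample mean and
#' dividing by the sample standard deviation of the scored set, making
#' scores comparable across species and matrix sets.
#'
#' @param introns Intron tibble with `sequence` (and ideally `exon5`)
#'   columns; a `terminal` column is derived if absent.
#' @param pwm Matrix set: `pwm$five_prime` and `pwm$branch`, each holding
#'   `U12_GTAG`, `U12_ATAC` and `U2_GTAG` matrices of kind `"probs"`.
#' @return The input tibble with score columns `p5_u12`, `p5_u2`, `pb_u12`,
#'   `pb_u2`, `s5`, `sb`, `z5`, `zb` appended.
#' @export
burge_scores <- function(introns, pwm = the_fixture_set()$pwm) {
  if (nrow(introns) < 2L) stop("need at least 2 introns for normalization")
  raw <- burge_raw_scores(introns, pwm)
  if (stats::sd(raw$s5) == 0 || stats::sd(raw$sb) == 0) {
    stop("sample standard deviation is zero; z-scores undefined")
  }
  raw$z5 <- (raw$s5 - mean(raw$s5)) / stats::sd(raw$s5)
  raw$zb <- (raw$sb - mean(raw$sb)) / stats::sd(raw$sb)
  dplyr::bind_cols(introns, raw)
}

#' Classification thresholds from a reference U12 set
#'
#' Scores the reference introns with the same matrices as the query sample
#' and places them in the query sample's z-space (normalizing with the query
#' mean and standard deviation). The thresholds are the minima of the
#' reference set on each axis: an intron qualifies as U12 only if both its
#' 5' and branch z-scores are at least these minima.
#'
#' @param scores Query score tibble from [burge_scores()].
#' @param reference Reference intron tibble (columns `sequence`, optionally
#'   `exon5`); defaults to [reference_introns()].
#' @param pwm Matrix set used for the query scores.
#' @return A list with `min_z5` and `min_zb`.
#' @export
reference_thresholds <- function(scores, reference = reference_introns(),
                                 pwm = the_fixture_set()$pwm) {
  if (nrow(reference) < 2L) stop("reference set needs at least 2 introns")
  ref <- burge_raw_scores(reference, pwm)
  list(
    min_z5 = min((ref$s5 - mean(scores$s5)) / stats::sd(scores$s5)),
    min_zb = min((ref$sb - mean(scores$sb)) / stats::sd(scores$sb))
  )
}

#' Flag U12 introns by the inclusive rectangle rule
#'
#' `B` is true when both z-scores are at least the reference-set minima
#' ("at least" is inclusive, so an intron exactly on the boundary passes).
#'
#' @param scores Score tibble from [burge_scores()].
#' @param thresholds List with `min_z5`, `min_zb` from
#'   [reference_thresholds()].
#' @return `scores` with a logical `burge_flag` column appended.
#' @export
burge_classify <- function(scores, thresholds) {
  if (is.null(thresholds$min_z5) || is.null(thresholds$min_zb)) {
    stop("thresholds must provide min_z5 and min_zb")
  }
  dplyr::mutate(scores,
    burge_flag = .data$z5 >= thresholds$min_z5 & .data$zb >= thresholds$min_zb
  )
}

#' Log-odds classification of U12 introns
#'
#' Scores each intron's 5' window under all four class log-odds matrices and
#' its best 12-nt branch window under the U12 branch matrix matching its
#' termini. `S` is true when the U12-class 5' score exceeds the
#' corresponding U2-class score (GT-AG vs GT-AG U2, GC-AG vs GC-AG U2,
#' AT-AC vs GT-AG U2) and both the U12 5' and branch scores meet their
#' configured minima. The category follows the termini and the flag;
#' introns with non-canonical termini are reported `OTHER` and not scored.
#'
#' @param introns Intron tibble with `sequence` (and ideally `exon5`,
#'   `exon3`) columns.
#' @param lom Log-odds matrix set: `lom$five_prime` (all four classes),
#'   `lom$three_prime`, and `lom$branch` with `U12_GTAG`, `U12_ATAC`.
#' @param min_scores Named numeric minima `c(five = 0, branch = 0)`: the
#'   U12 5' and branch log-odds scores must be at least these values.
#' @return `introns` with columns `sheth_5`, `sheth_5_u2`, `sheth_branch`,
#'   `sheth_3`, `sheth_flag`, `category` appended.
#' @export
sheth_classify <- function(introns, lom = the_fixture_set()$logodds,
                           min_scores = c(five = 0, branch = 0)) {
  introns <- classify_termini(introns)
  w5 <- five_prime_window(introns)
  w3 <- three_prime_window(introns)
  n <- nrow(introns)
  s5 <- s5u2 <- sbr <- s3 <- rep(NA_real_, n)
  flag <- rep(NA, n)
  category <- character(n)
  for (i in seq_len(n)) {
    term <- introns$terminal[i]
    if (term == "OTHER") {
      category[i] <- "OTHER"
      next
    }
    ucl <- u12_class_for(term)
    u2cl <- u2_class_for(term)
    if (is.null(lom$five_prime[[ucl]]) || is.null(lom$branch[[ucl]])) {
      category[i] <- "OTHER"
      next
    }
    s5[i] <- score_5ss(w5[i], lom$five_prime[[ucl]])
    s5u2[i] <- score_5ss(w5[i], lom$five_prime[[u2cl]])
    sbr[i] <- score_branch_max(introns$sequence[i], lom$branch[[ucl]])$score
    s3[i] <- score_5ss(w3[i], lom$three_prime[[ucl]])
    flag[i] <- s5[i] > s5u2[i] &&
      s5[i] >= min_scores[["five"]] && sbr[i] >= min_scores[["branch"]]
    category[i] <- if (flag[i]) {
      ucl
    } else if (term == "AT_AC") {
      "OTHER"
    } else {
      u2cl
    }
  }
  dplyr::bind_cols(introns, tibble::tibble(
    sheth_5 = s5, sheth_5_u2 = s5u2, sheth_branch = sbr, sheth_3 = s3,
    sheth_flag = flag, category = category
  ))
}

#' The relaxed RTATCCTT 5'-terminal rule
#'
#' Effective splicing at a minor-spliceosome 5' splice site requires the
#' intron to begin `RTATCCTT`, where one of the Cs at positions +5 and +6
#' may be replaced by a T. Concretely, positions +1..+8 must satisfy:
#' +1 in {A, G}, +2 = T, +3 = A, +4 = T, (+5, +6) in {CC, CT, TC},
#' +7 = T, +8 = T.
#'
#' @param intron Character vector of intron sequences (each >= 8 nt).
#' @return Logical vector: does each intron conform to the rule?
#' @export
#' @examples
#' five_prime_rule(c("ATATCCTTTC", "GTATTGTTTT", "GTATCTTTTC"))
five_prime_rule <- function(intron) {
  if (any(nchar(intron) < 8L)) stop("introns must be at least 8 nt")
  x <- toupper(intron)
  p <- function(i) substr(x, i, i)
  p(1) %in% c("A", "G") & p(2) == "T" & p(3) == "A" & p(4) == "T" &
    paste0(p(5), p(6)) %in% c("CC", "CT", "TC") &
    p(7) == "T" & p(8) == "T"
}

method_category <- function(terminal, u12_flag) {
  dplyr::case_when(
    is.na(u12_flag) & terminal == "AT_AC" ~ "OTHER_ATAC",
    is.na(u12_flag) ~ "OTHER",
    u12_flag & terminal == "AT_AC" ~ "U12_ATAC",
    u12_flag ~ "U12_GTAG",
    terminal == "AT_AC" ~ "OTHER_ATAC",
    terminal == "GC_AG" ~ "U2_GCAG",
    terminal == "GT_AG" ~ "U2_GTAG",
    TRUE ~ "OTHER"
  )
}

#' Per-category classification summary
#'
#' Tallies introns per category for each method, with the count of U12
#' introns additionally passing the 5' rule (the parenthetical count of the
#' usual per-species summary tables). AT-AC introns failing the U12 test are
#' reported as `OTHER_ATAC` ("other AT-AC introns").
#'
#' @param classified Tibble with columns `terminal`, `rule_flag`, and
#'   method flags `burge_flag` and/or `sheth_flag`.
#' @return A tibble with one row per category and columns `<method>_n`,
#'   `<method>_rule_n` per available method.
#' @export
summarize_counts <- function(classified) {
  cats <- c("U12_ATAC", "U12_GTAG", "U2_GCAG", "U2_GTAG", "OTHER_ATAC", "OTHER")
  out <- tibble::tibble(category = cats)
  rule <- if ("rule_flag" %in% names(classified)) classified$rule_flag else
    rep(NA, nrow(classified))
  for (method in c("burge", "sheth")) {
    col <- paste0(method, "_flag")
    if (!col %in% names(classified)) next
    cat_m <- method_category(classified$terminal, classified[[col]])
    n <- vapply(cats, function(cc) sum(cat_m == cc), integer(1),
                USE.NAMES = FALSE)
    n_rule <- vapply(cats, function(cc) {
      if (!startsWith(cc, "U12")) return(NA_integer_)
      sum(cat_m == cc & rule %in% TRUE)
    }, integer(1), USE.NAMES = FALSE)
    out[[paste0(method, "_n")]] <- n
    out[[paste0(method, "_rule_n")]] <- n_rule
  }
  out
}

#' Classify introns with both scoring schemes and the 5' rule
#'
#' Pipeline wrapper: terminal categorization, probability-product scoring
#' with z-normalization and reference thresholds (`B` flag), per-class
#' log-odds scoring (`S` flag), the RTATCCTT rule (`R` flag), and the
#' per-category summary table.
#'
#' @param introns Intron tibble from [discover_introns()] (needs `sequence`;
#'   `exon5`/`exon3` improve the exonic window positions).
#' @param matrix_set Matrix set with `pwm` and `logodds` components, as from
#'   [build_matrix_set()].
#' @param reference Reference U12 intron tibble for the z-score thresholds;
#'   default [reference_introns()].
#' @param min_scores Log-odds minima passed to [sheth_classify()].
#' @return A `u12_classification` object: list with `introns` (scored,
#'   flagged tibble), `thresholds`, and `summary`.
#' @export
classify_introns <- function(introns, matrix_set = the_fixture_set(),
                             reference = reference_introns(),
                             min_scores = c(five = 0, branch = 0)) {
  res <- classify_termini(introns)
  res <- sheth_classify(res, matrix_set$logodds, min_scores)
  res <- burge_scores(res, matrix_set$pwm)
  thresholds <- reference_thresholds(res, reference, matrix_set$pwm)
  res <- burge_classify(res, thresholds)
  res$rule_flag <- five_prime_rule(res$sequence)
  structure(
    list(
      introns = res,
      thresholds = thresholds,
      summary = summarize_counts(res)
    ),
    class = "u12_classification"
  )
}

#' @export
print.u12_classification <- function(x, ...) {
  cat(sprintf("<u12_classification> %d introns\n", nrow(x$introns)))
  cat(sprintf(
    "thresholds: z5 >= %.3f, zb >= %.3f\n",
    x$thresholds$min_z5, x$thresholds$min_zb
  ))
  print(x$summary)
  invisible(x)
}

#' Write classification results to TSV files
#'
#' Writes `intron_scores.tsv` (one row per intron with all scores and the
#' B/S/R flags), `summary.tsv` (the per-category table) and
#' `scores_scatter.tsv` (the `(z5, zb)` pairs with categories, for a
#' score-space scatter plot).
#'
#' @param x A `u12_classification`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_classification <- function(x, dir) {
  stopifnot(inherits(x, "u12_classification"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(x$introns, "intron_scores.tsv")
  tsv(x$summary, "summary.tsv")
  tsv(dplyr::select(x$introns, dplyr::any_of(c("est_id", "z5", "zb", "category"))),
      "scores_scatter.tsv")
  invisible(dir)
}
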
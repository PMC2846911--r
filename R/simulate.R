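#' Configuration for the synthetic genome/EST generator
#'
#' Bundles every knob of the simulator with defaults that emulate the data
#' regime of small invertebrate/protist EST studies: multi-exon genes, intron
#' lengths with a mode near 62 nt (log-normal, capped), a class mix dominated
#' by major-spliceosome GT-AG introns with a small admixture of U12 introns,
#' and single-pass cDNA reads (ESTs) with a per-base substitution error rate
#' at most 2% so a 98%-identity alignment filter remains meaningful.
#'
#' @param seed Integer seed; identical configs generate identical output.
#' @param n_genes Number of genes (one contig per gene).
#' @param exons_per_gene Inclusive range of exon counts per gene.
#' @param exon_len Inclusive range of exon lengths (nt).
#' @param intron_modal_length Modal intron length of the log-normal (nt).
#' @param intron_sdlog Log-scale standard deviation of intron lengths.
#' @param intron_min,intron_max Intron length truncation bounds (nt). The
#'   minimum is held at >= 50 so every intron admits a branch scan window
#'   and a planted branch site.
#' @param class_mix Named proportions over `U2_GTAG`, `U2_GCAG`, `U12_GTAG`,
#'   `U12_ATAC`, `OTHER`; must sum to 1.
#' @param u12_consensus_mass Probability mass placed on the consensus base at
#'   U12 site positions (default 0.85; U12 signals are strongly conserved).
#' @param u2_consensus_mass Same for U2 sites (default 0.55; weaker signals).
#' @param u12_consensus_frac Fraction of U12 introns whose 5' and branch
#'   windows are planted as the exact matrix consensus rather than sampled,
#'   emulating textbook-strength minor introns (default 0.2).
#' @param est_error_rate Per-base substitution probability in ESTs
#'   (default 0.01, i.e. expected identity 99%).
#' @param est_truncation Length range (nt) of the truncated-fragment EST
#'   emitted per gene in addition to one full-length transcript read.
#' @param flank_len Intergenic flank length on each side of a gene (nt).
#' @param ests_per_gene ESTs per gene: the first is the full spliced
#'   transcript, the rest are random fragments.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 145L,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(80L, 300L),
                       intron_modal_length = 62,
                       intron_sdlog = 0.6,
                       intron_min = 50L,
                       intron_max = 2000L,
                       class_mix = c(U2_GTAG = 0.90, U2_GCAG = 0.02,
                                     U12_GTAG = 0.05, U12_ATAC = 0.02,
                                     OTHER = 0.01),
                       u12_consensus_mass = 0.85,
                       u2_consensus_mass = 0.55,
                       u12_consensus_frac = 0.2,
                       est_error_rate = 0.01,
                       est_truncation = c(300L, 900L),
                       flank_len = 100L,
                       ests_per_gene = 2L) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  need <- c("U2_GTAG", "U2_GCAG", "U12_GTAG", "U12_ATAC", "OTHER")
  if (!setequal(names(class_mix), need)) {
    stop("class_mix must name exactly: ", paste(need, collapse = ", "))
  }
  if (est_error_rate > 0.02) {
    stop("est_error_rate must be <= 0.02 so expected identity stays >= 98%")
  }
  if (intron_min < 50L) stop("intron_min must be >= 50 nt")
  structure(
    list(
      seed = as.integer(seed), n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      exon_len = as.integer(exon_len),
      intron_modal_length = intron_modal_length,
      intron_sdlog = intron_sdlog,
      intron_min = as.integer(intron_min),
      intron_max = as.integer(intron_max),
      class_mix = class_mix[need],
      u12_consensus_mass = u12_consensus_mass,
      u2_consensus_mass = u2_consensus_mass,
      u12_consensus_frac = u12_consensus_frac,
      est_error_rate = est_error_rate,
      est_truncation = as.integer(est_truncation),
      flank_len = as.integer(flank_len),
      ests_per_gene = as.integer(ests_per_gene)
    ),
    class = "sim_config"
  )
}

# Per-position probabilities for a consensus string with IUPAC codes:
# `mass` is split equally over the consensus bases, the remainder equally
# over the others. N positions are uniform.
consensus_to_probs <- function(consensus, mass) {
  if (mass <= 0.25 || mass > 1) stop("consensus mass must be in (0.25, 1]")
  chars <- strsplit(toupper(consensus), "")[[1]]
  t(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (is.null(set)) stop("unsupported consensus code: ", ch)
    k <- length(set)
    if (k == 4L) return(rep(0.25, 4))
    p <- rep((1 - mass) / (4 - k), 4)
    p[match(set, BASES)] <- mass / k
    p
  }, numeric(4)))
}

SITE_CONSENSUS <- list(
  five_prime = list( # 3 exon + 10 intron
    U2_GTAG  = c("NAG", "GTRAGTNNNN"),
    U2_GCAG  = c("NAG", "GCRAGTNNNN"),
    U12_GTAG = c("NNN", "GTATCCTTTN"),
    U12_ATAC = c("NNN", "ATATCCTTTN")
  ),
  three_prime = list( # 14 intron + 3 exon
    U2_GTAG  = c("YYYYYYYYYYYYAG", "GNN"),
    U2_GCAG  = c("YYYYYYYYYYYYAG", "GNN"),
    U12_GTAG = c("NNNNNNNNNNNYAG", "NNN"),
    U12_ATAC = c("NNNNNNNNNNNYAC", "NNN")
  ),
  branch = list( # 12 intronic positions
    U2_GTAG  = "NNNCTRACTNNN",
    U2_GCAG  = "NNNCTRACTNNN",
    U12_GTAG = "NTCCTTAACTNN",
    U12_ATAC = "NTCCTTAACTNN"
  )
)

TERMINI <- list(
  U2_GTAG = c("GT", "AG"), U2_GCAG = c("GC", "AG"),
  U12_GTAG = c("GT", "AG"), U12_ATAC = c("AT", "AC")
)

#' Build consensus-derived splice-site frequency matrices
#'
#' Constructs the full grid of (site type, intron class) frequency matrices
#' from the canonical splice consensus sequences: U2 5'ss `AG/GTRAGT`,
#' U12 5'ss `/RTATCCTTT` (with the class's terminal dinucleotide fixed),
#' U2 branch `CTRACT`, U12 branch `TCCTTAACT`, U2 3'ss pyrimidine tract plus
#' `YAG/G`, and a weak U12 3' site. Each position places `mass` on the
#' consensus base (degenerate codes split it equally) and the remainder
#' uniformly on the other bases. Dimensions follow the SpliceRack layout
#' (13 / 17 / 12 positions).
#'
#' @param u12_mass Consensus mass for U12-class matrices (default 0.85).
#' @param u2_mass Consensus mass for U2-class matrices (default 0.55).
#' @param n_sites Nominal site count each matrix represents; counts are
#'   `probability * n_sites`, so every position's column sum equals
#'   `n_sites` (default 1000).
#' @return Nested list `freq[[site_type]][[intron_class]]` of
#'   `splice_matrix` objects of kind `"counts"`.
#' @export
build_fixture_pwms <- function(u12_mass = 0.85, u2_mass = 0.55,
                               n_sites = 1000) {
  out <- list()
  for (st in names(SITE_CONSENSUS)) {
    out[[st]] <- list()
    for (cl in names(SITE_CONSENSUS[[st]])) {
      mass <- if (startsWith(cl, "U12")) u12_mass else u2_mass
      cons <- paste(SITE_CONSENSUS[[st]][[cl]], collapse = "")
      probs <- consensus_to_probs(cons, mass)
      out[[st]][[cl]] <- splice_matrix(probs * n_sites,
        site_type = st, intron_class = cl, kind = "counts",
        exon_offset = if (st == "branch") 0L else 3L,
        species = "synthetic"
      )
    }
  }
  out
}

#' Derive probability and log-odds matrix sets from frequency matrices
#'
#' @param freq Nested frequency-matrix list as returned by
#'   [build_fixture_pwms()].
#' @param prob_floor Probability floor for the PWMs (default 1e-4).
#' @param pseudocount Pseudocount for the log-odds matrices (default 0.001).
#' @param background Background base composition for log-odds
#'   (default uniform).
#' @return A list with elements `freq`, `pwm` and `logodds`, each nested as
#'   `[[site_type]][[intron_class]]`.
#' @export
build_matrix_set <- function(freq = build_fixture_pwms(), prob_floor = 1e-4,
                             pseudocount = 0.001,
                             background = rep(0.25, 4)) {
  list(
    freq = freq,
    pwm = purrr::map(freq, function(site) purrr::map(site, to_pwm, prob_floor = prob_floor)),
    logodds = purrr::map(freq, function(site) {
      purrr::map(site, to_log_odds, pseudocount = pseudocount, background = background)
    })
  )
}

the_fixture_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_matrix_set()
    cache
  }
})

sample_from_probs <- function(probs) {
  apply(probs, 1L, function(p) sample(4L, 1L, prob = p))
}

random_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# One intron sequence of length n for a given class; returns the sequence
# and the planted branch window offset (NA for class OTHER).
sample_intron <- function(class, n, pwms, consensus_sites = FALSE) {
  chars <- sample(BASES, n, replace = TRUE)
  if (class == "OTHER") {
    repeat {
      d <- sample(BASES, 2L, replace = TRUE)
      a <- sample(BASES, 2L, replace = TRUE)
      key <- paste0(paste(d, collapse = ""), "-", paste(a, collapse = ""))
      if (!key %in% c("GT-AG", "GC-AG", "AT-AC")) break
    }
    chars[1:2] <- d
    chars[(n - 1L):n] <- a
    return(list(sequence = paste(chars, collapse = ""), branch_offset = NA_integer_))
  }
  p5 <- unclass(pwms$five_prime[[class]])[4:13, , drop = FALSE]
  p3 <- unclass(pwms$three_prime[[class]])[1:14, , drop = FALSE]
  pb <- unclass(pwms$branch[[class]])
  pick <- function(pr) {
    if (consensus_sites) apply(pr, 1L, which.max) else sample_from_probs(pr)
  }
  chars[1:10] <- BASES[pick(p5)]
  chars[(n - 13L):n] <- BASES[sample_from_probs(p3)]
  off <- sample(seq.int(-40L, -26L), 1L)
  s <- n + off + 1L
  chars[s:(s + nrow(pb) - 1L)] <- BASES[pick(pb)]
  term <- TERMINI[[class]]
  chars[1:2] <- strsplit(term[1L], "")[[1]]
  chars[(n - 1L):n] <- strsplit(term[2L], "")[[1]]
  list(sequence = paste(chars, collapse = ""), branch_offset = off)
}

sample_intron_length <- function(cfg) {
  mu <- log(cfg$intron_modal_length) + cfg$intron_sdlog^2
  repeat {
    l <- round(stats::rlnorm(1L, mu, cfg$intron_sdlog))
    if (l >= cfg$intron_min && l <= cfg$intron_max) return(as.integer(l))
  }
}

apply_est_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome, ESTs and ground-truth table
#'
#' Emits one contig per gene (uniform-random intergenic and exonic background
#' with splice-signal windows written in from the class PWMs), spliced
#' transcripts sampled as ESTs with substitution errors, and a truth table
#' recording every planted intron: coordinates, class, branch window offset,
#' whether its 5'/branch windows are exact consensus, and which ESTs cover
#' its junction with at least 35 exonic nt on both sides.
#'
#' Identical configurations (including the seed) generate byte-identical
#' output.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_dataset` list with elements `genome` (named character),
#'   `ests` (named character), `truth` (tibble) and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pwms <- build_matrix_set(build_fixture_pwms(
    u12_mass = cfg$u12_consensus_mass, u2_mass = cfg$u2_consensus_mass
  ))$pwm
  genome <- character(0)
  ests <- character(0)
  truth <- list()
  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%04d", g)
    n_ex <- sample(seq.int(cfg$exons_per_gene[1L], cfg$exons_per_gene[2L]), 1L)
    exon_lens <- sample(seq.int(cfg$exon_len[1L], cfg$exon_len[2L]),
                        n_ex, replace = TRUE)
    exons <- lapply(exon_lens, function(n) sample(BASES, n, replace = TRUE))
    n_in <- n_ex - 1L
    classes <- sample(names(cfg$class_mix), n_in, replace = TRUE,
                      prob = cfg$class_mix)
    introns <- vector("list", n_in)
    consensus <- logical(n_in)
    for (i in seq_len(n_in)) {
      cl <- classes[i]
      consensus[i] <- startsWith(cl, "U12") &&
        stats::runif(1L) < cfg$u12_consensus_frac
      len <- sample_intron_length(cfg)
      introns[[i]] <- sample_intron(cl, len, pwms, consensus[i])
      if (cl != "OTHER") {
        # splice-proximal exon bases carry the exonic part of the signals
        p5e <- unclass(pwms$five_prime[[cl]])[1:3, , drop = FALSE]
        p3e <- unclass(pwms$three_prime[[cl]])[15:17, , drop = FALSE]
        le <- length(exons[[i]])
        exons[[i]][(le - 2L):le] <- BASES[sample_from_probs(p5e)]
        exons[[i + 1L]][1:3] <- BASES[sample_from_probs(p3e)]
      }
    }
    contig <- paste0(
      random_seq(cfg$flank_len),
      paste(vapply(seq_len(n_ex), function(i) {
        paste0(
          paste(exons[[i]], collapse = ""),
          if (i <= n_in) introns[[i]]$sequence else ""
        )
      }, character(1)), collapse = ""),
      random_seq(cfg$flank_len)
    )
    genome[[gene_id]] <- contig
    # 0-based intron coordinates on the contig
    exon_lens2 <- vapply(exons, length, integer(1))
    intron_lens <- vapply(introns, function(x) nchar(x$sequence), integer(1))
    pos <- cfg$flank_len
    istart <- integer(n_in); iend <- integer(n_in)
    for (i in seq_len(n_ex)) {
      pos <- pos + exon_lens2[i]
      if (i <= n_in) {
        istart[i] <- pos
        iend[i] <- pos + intron_lens[i]
        pos <- iend[i]
      }
    }
    transcript <- paste(vapply(exons, paste, character(1), collapse = ""),
                        collapse = "")
    tlen <- nchar(transcript)
    junctions <- cumsum(exon_lens2)[seq_len(n_in)] # transcript coords
    est_spans <- list()
    for (e in seq_len(cfg$ests_per_gene)) {
      est_id <- sprintf("%s_est%d", gene_id, e)
      if (e == 1L) {
        s <- 1L; l <- tlen
      } else {
        l <- min(tlen, sample(seq.int(cfg$est_truncation[1L],
                                      cfg$est_truncation[2L]), 1L))
        s <- sample.int(tlen - l + 1L, 1L)
      }
      ests[[est_id]] <- apply_est_errors(substr(transcript, s, s + l - 1L),
                                         cfg$est_error_rate)
      est_spans[[est_id]] <- c(s, s + l - 1L)
    }
    for (i in seq_len(n_in)) {
      cov <- names(Filter(function(sp) {
        sp[1L] + 35L <= junctions[i] && junctions[i] + 35L <= sp[2L] + 1L
      }, est_spans))
      truth[[length(truth) + 1L]] <- tibble::tibble(
        gene_id = gene_id, contig_id = gene_id,
        intron_id = sprintf("%s_i%d", gene_id, i),
        start = istart[i], end = iend[i],
        length = intron_lens[i], class = classes[i],
        branch_offset = introns[[i]]$branch_offset,
        consensus_sites = consensus[i],
        est_ids = paste(cov, collapse = ",")
      )
    }
  }
  structure(
    list(genome = genome, ests = ests,
         truth = dplyr::bind_rows(truth), config = cfg),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d contigs (%d nt), %d ESTs, %d planted introns\n",
    length(x$genome), sum(nchar(x$genome)), length(x$ests), nrow(x$truth)
  ))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `genome.fasta`, `ests.fasta` and `truth.tsv` into `dir`.
#'
#' @param x A `sim_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(x$genome, file.path(dir, "genome.fasta"))
  write_fasta(x$ests, file.path(dir, "ests.fasta"))
  utils::write.table(x$truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Reference set of minor-spliceosome introns
#'
#' Samples U12 GT-AG introns from the consensus-derived U12 matrices with a
#' fixed seed, for use as the reference set anchoring the z-score
#' classification thresholds when no curated reference is supplied.
#'
#' @param n Number of reference introns (default 20).
#' @param seed RNG seed (fixed default so thresholds are reproducible).
#' @param u12_mass Consensus mass of the generating matrices.
#' @param length Intron length (nt).
#' @return A tibble with columns `sequence`, `exon5`, `exon3`.
#' @export
reference_introns <- function(n = 20L, seed = 106L, u12_mass = 0.85,
                              length = 120L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pwms <- build_matrix_set(build_fixture_pwms(u12_mass = u12_mass))$pwm
  rows <- purrr::map(seq_len(n), function(i) {
    s <- sample_intron("U12_GTAG", length, pwms)
    tibble::tibble(
      sequence = s$sequence,
      exon5 = BASES[sample_from_probs(unclass(pwms$five_prime$U12_GTAG)[1:3, ])] |>
        paste(collapse = ""),
      exon3 = BASES[sample_from_probs(unclass(pwms$three_prime$U12_GTAG)[15:17, ])] |>
        paste(collapse = "")
    )
  })
  dplyr::bind_rows(rows)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Compare discovered/classified introns with the generator truth
#'
#' @param introns Tibble of discovered introns (from [discover_introns()]),
#'   optionally carrying a `category` column from classification.
#' @param truth Truth tibble from [simulate_dataset()].
#' @return A list with `boundary_rate` (fraction of EST-covered planted
#'   introns recovered with exact coordinates), `boundary_rate_canonical`
#'   (the same restricted to introns with canonical termini — non-canonical
#'   junctions carry no splice-site signal, so no PWM scorer can place them
#'   among equally consistent alignments), `class_rate` (fraction of
#'   recovered introns assigned their true category; `NA` without a
#'   `category` column), and the joined tibble `detail`.
#' @export
evaluate_recovery <- function(introns, truth) {
  covered <- dplyr::filter(truth, .data$est_ids != "")
  hits <- dplyr::semi_join(covered, introns,
    by = c("contig_id", "start", "end")
  )
  boundary_rate <- nrow(hits) / nrow(covered)
  canon <- dplyr::filter(covered, .data$class != "OTHER")
  canon_hits <- dplyr::semi_join(canon, introns,
    by = c("contig_id", "start", "end")
  )
  boundary_rate_canonical <- nrow(canon_hits) / nrow(canon)
  detail <- dplyr::inner_join(
    covered, introns,
    by = c("contig_id", "start", "end"), suffix = c(".true", "")
  )
  class_rate <- NA_real_
  if ("category" %in% names(detail) && nrow(detail) > 0L) {
    expected <- dplyr::case_match(detail$class,
      "U2_GTAG" ~ "U2_GTAG", "U2_GCAG" ~ "U2_GCAG",
      "U12_GTAG" ~ "U12_GTAG", "U12_ATAC" ~ "U12_ATAC",
      "OTHER" ~ "OTHER"
    )
    class_rate <- mean(detail$category == expected)
  }
  list(boundary_rate = boundary_rate,
       boundary_rate_canonical = boundary_rate_canonical,
       class_rate = class_rate, detail = detail)
}
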
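NON_STOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste0, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Configuration for the synthetic fixture generator
#'
#' Defines the two synthetic sequence classes and the signal planted
#' between them, in exactly the three feature families the classifier
#' uses:
#'
#' * **ORF signal** — positives are resampled until their optimal ORF
#'   is at most `pos_orf_max` nt; negatives get an embedded stop-free
#'   reading frame of at least `neg_orf_min` nt. `pos_orf_max = Inf`
#'   and `neg_orf_min = 0` switch the ORF signal off.
#' * **Composition signal** — positives are drawn i.i.d. at GC
#'   `0.5 - gc_shift/2`, negatives at `0.5 + gc_shift/2`;
#'   `gc_shift = 0` switches it off.
#' * **Junction signal** — positives get `junction_motif[1]` (acceptor
#'   dinucleotide, default `"AG"`) planted immediately upstream of the
#'   5' site and `junction_motif[2]` (donor, default `"GT"`)
#'   immediately downstream of the 3' site on the toy genome, i.e. at
#'   positions 48-49 of the site5 window and 50-51 of the site3 window
#'   after extraction; `NULL` switches it off. Negatives use their
#'   transcript's genomic start/end as the two sites (the lncRNA
#'   convention) with unmodified flanks.
#'
#' `noise` is the fraction of records generated with the opposite
#' class's signal profile while keeping their label — controlled label
#' noise for robustness checks.
#'
#' @param n_pos,n_neg Records per class.
#' @param length_range Transcript length range in nt (both > 200 so
#'   that +/-50 bp junction windows fit inside a locus).
#' @param pos_orf_max Maximum optimal-ORF length in positives (nt).
#' @param neg_orf_min Minimum planted-ORF length in negatives (nt;
#'   0 disables planting).
#' @param gc_shift GC composition offset between classes.
#' @param junction_motif Length-2 character vector
#'   `c(acceptor, donor)`, or `NULL`.
#' @param noise Fraction of profile-swapped records in `[0, 0.5)`.
#' @param seed Integer seed; the generator is fully determined by it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_pos = 400L, n_neg = 400L,
                           length_range = c(500L, 1000L),
                           pos_orf_max = 300L, neg_orf_min = 450L,
                           gc_shift = 0.06,
                           junction_motif = c("AG", "GT"),
                           noise = 0, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1, length(length_range) == 2)
  if (length_range[1] <= 200) {
    stop("transcript lengths must exceed 200 nt", call. = FALSE)
  }
  if (length_range[2] < length_range[1]) stop("invalid length_range")
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)")
  if (gc_shift < 0 || gc_shift > 0.5) stop("gc_shift must be in [0, 0.5]")
  if (neg_orf_min > 0 && neg_orf_min > length_range[1] - 6) {
    stop("infeasible config: neg_orf_min = ", neg_orf_min,
         " does not fit in the shortest transcript (",
         length_range[1], " nt)", call. = FALSE)
  }
  if (!is.null(junction_motif)) {
    stopifnot(length(junction_motif) == 2,
              all(nchar(junction_motif) == 2))
    junction_motif <- normalize_seq(junction_motif)
  }
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    length_range = as.integer(length_range),
    pos_orf_max = pos_orf_max, neg_orf_min = as.integer(neg_orf_min),
    gc_shift = gc_shift, junction_motif = junction_motif,
    noise = noise, seed = as.integer(seed)
  ), class = "fixture_config")
}

random_dna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# positive-profile transcript: resample until the optimal ORF is short
gen_positive_seq <- function(L, gc, orf_max, tries = 30L) {
  best <- NULL; best_len <- Inf
  for (t in seq_len(tries)) {
    s <- random_dna(L, gc)
    ob <- orf_feature_block(s)
    if (ob[["ORF_length"]] <= orf_max) return(s)
    if (ob[["ORF_length"]] < best_len) {
      best <- s; best_len <- ob[["ORF_length"]]
    }
  }
  warning("could not reach pos_orf_max = ", orf_max, " in ", tries,
          " tries; keeping shortest-ORF draw (", best_len, " nt)")
  best
}

# negative-profile transcript: embed a stop-free ATG...stop frame
gen_negative_seq <- function(L, gc, orf_min) {
  s <- random_dna(L, gc)
  if (orf_min <= 0) return(list(seq = s, planted = NA_integer_))
  orf_len <- 3L * (min(L - 3L, orf_min + sample.int(150L, 1)) %/% 3L)
  orf_len <- max(orf_len, 3L * ((orf_min + 2L) %/% 3L))
  n_mid <- orf_len / 3L - 2L
  orf <- paste0("ATG",
                paste0(sample(NON_STOP_CODONS, n_mid, replace = TRUE),
                       collapse = ""),
                sample(c("TAA", "TAG", "TGA"), 1))
  at <- sample.int(L - orf_len + 1L, 1)  # 1-based insert position
  list(
    seq = paste0(substr(s, 1, at - 1L), orf,
                 substr(s, at + orf_len, L)),
    planted = orf_len
  )
}

LOCUS_PAD <- 60L

#' Generate a labeled synthetic dataset
#'
#' Builds `n_pos` circRNA-like positives and `n_neg` lncRNA-like
#' negatives with the signal structure described in
#' [fixture_config()], lays every transcript on the `+` strand of a
#' toy chromosome (`chr1`) with 60 nt of background on each side, and
#' records each candidate's two splice sites (genomic transcript start
#' and end, 0-based). Byte-identical for a given config.
#'
#' @param config A [fixture_config()].
#' @return A `circ_fixture` list: `sequences` (tibble `id`, `seq`,
#'   `label`, `length`), `genome` (named character vector),
#'   `junctions` (tibble `chrom`, `site5`, `site3`, `strand`,
#'   `seq_id`), `truth` (tibble with the generative profile and
#'   planted-ORF length per record), and `config`.
#' @export
generate_dataset <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, {
    n <- config$n_pos + config$n_neg
    label <- rep(c("positive", "negative"), c(config$n_pos, config$n_neg))
    id <- c(sprintf("circ_%04d", seq_len(config$n_pos)),
            sprintf("lnc_%04d", seq_len(config$n_neg)))
    swap <- stats::runif(n) < config$noise
    flipped <- ifelse(label == "positive", "negative", "positive")
    profile <- ifelse(swap, flipped, label)
    build_fixture(config, id, label, profile)
  })
}

#' Generate a signal-free null dataset
#'
#' Every record is drawn from one neutral profile (GC 0.5, no planted
#' ORF, no junction motif) and the positive/negative labels are
#' assigned by a random permutation, independently of the sequences.
#' Feature distributions are therefore exchangeable between the label
#' groups — the fixture for type-I-error and chance-level calibration
#' checks.
#'
#' @param config A [fixture_config()]; only the sizes, length range
#'   and seed are used.
#' @return A `circ_fixture`, as [generate_dataset()].
#' @export
generate_null_dataset <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  withr::with_seed(config$seed, {
    n <- config$n_pos + config$n_neg
    id <- sprintf("rec_%04d", seq_len(n))
    label <- sample(rep(c("positive", "negative"),
                        c(config$n_pos, config$n_neg)))
    null_cfg <- config
    null_cfg$gc_shift <- 0
    null_cfg$junction_motif <- NULL
    null_cfg$pos_orf_max <- Inf
    null_cfg$neg_orf_min <- 0L
    build_fixture(null_cfg, id, label, profile = rep("neutral", n))
  })
}

build_fixture <- function(config, id, label, profile) {
  n <- length(id)
  L <- sample(seq(config$length_range[1], config$length_range[2]), n,
              replace = TRUE)
  gc_pos <- 0.5 - config$gc_shift / 2
  gc_neg <- 0.5 + config$gc_shift / 2
  seqs <- character(n)
  planted <- rep(NA_integer_, n)
  chunks <- character(0)
  offset <- 0L
  j5 <- integer(n); j3 <- integer(n)
  for (i in seq_len(n)) {
    if (profile[i] == "positive") {
      seqs[i] <- gen_positive_seq(L[i], gc_pos, config$pos_orf_max)
    } else if (profile[i] == "negative") {
      g <- gen_negative_seq(L[i], gc_neg, config$neg_orf_min)
      seqs[i] <- g$seq; planted[i] <- g$planted
    } else {  # neutral (null fixture)
      seqs[i] <- random_dna(L[i], 0.5)
    }
    left <- random_dna(LOCUS_PAD, 0.5)
    right <- random_dna(LOCUS_PAD, 0.5)
    if (profile[i] == "positive" && !is.null(config$junction_motif)) {
      substr(left, LOCUS_PAD - 1L, LOCUS_PAD) <- config$junction_motif[1]
      substr(right, 1L, 2L) <- config$junction_motif[2]
    }
    j5[i] <- offset + LOCUS_PAD
    j3[i] <- j5[i] + L[i]
    chunks[[length(chunks) + 1L]] <- paste0(left, seqs[i], right)
    offset <- offset + LOCUS_PAD * 2L + L[i]
  }
  structure(list(
    sequences = tibble::tibble(id = id, seq = seqs, label = label,
                               length = L),
    genome = c(chr1 = paste0(chunks, collapse = "")),
    junctions = tibble::tibble(chrom = "chr1", site5 = j5, site3 = j3,
                               strand = "+", seq_id = id),
    truth = tibble::tibble(id = id, label = label, profile = profile,
                           length = L, planted_orf_length = planted),
    config = config
  ), class = "circ_fixture")
}

#' @export
print.circ_fixture <- function(x, ...) {
  cat("<circ_fixture>", nrow(x$sequences), "sequences (",
      sum(x$sequences$label == "positive"), "positive /",
      sum(x$sequences$label == "negative"),
      "negative ), toy genome", nchar(x$genome), "nt, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Write a fixture to disk
#'
#' Writes `pos.fa`, `neg.fa` (labels in headers), `genome.fa`,
#' `junctions.tsv` and `truth.tsv` under `dir`.
#'
#' @param fixture A `circ_fixture`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(fixture, dir) {
  stopifnot(inherits(fixture, "circ_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- fixture$sequences
  write_fasta(seqs[seqs$label == "positive", ], file.path(dir, "pos.fa"))
  write_fasta(seqs[seqs$label == "negative", ], file.path(dir, "neg.fa"))
  genome_set <- Biostrings::DNAStringSet(fixture$genome)
  Biostrings::writeXStringSet(genome_set, file.path(dir, "genome.fa"))
  write_junction_table(fixture$junctions, file.path(dir, "junctions.tsv"))
  readr::write_tsv(fixture$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
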
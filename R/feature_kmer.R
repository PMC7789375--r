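#' All k-mers of a given length, in schema order
#'
#' Lexicographic order over the alphabet A, C, G, T. This is the fixed
#' column order of the k-mer feature block (k ascending, lexicographic
#' within each k), which keeps the feature schema stable across runs
#' and model saves.
#'
#' @param k k-mer length.
#' @return Character vector of the 4^k k-mers.
#' @export
kmer_alphabet <- function(k) {
  stopifnot(k >= 1)
  grids <- rep(list(c("A", "C", "G", "T")), k)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  g <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste0, collapse = "")
}

#' Count overlapping k-mers in a sequence
#'
#' Counts occurrences of every k-mer over the `L - k + 1` overlapping
#' windows (stride 1). Windows containing `N` match no k-mer and are
#' skipped; the sequence length used downstream is unaffected.
#'
#' @param seq A single nucleotide string over `{A,C,G,T,N}`.
#' @param k k-mer length. If `k > nchar(seq)` all counts are zero, with
#'   a warning.
#' @return Named integer vector over all 4^k k-mers in schema order.
#' @export
#' @examples
#' count_kmers("AAAA", 2)["AA"]  # 3 overlapping windows
count_kmers <- function(seq, k) {
  stopifnot(length(seq) == 1L, k >= 1)
  seq <- normalize_seq(seq)
  ab <- kmer_alphabet(k)
  if (k > nchar(seq)) {
    warning("k = ", k, " exceeds sequence length ", nchar(seq),
            "; returning all-zero counts")
    return(stats::setNames(integer(length(ab)), ab))
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  counts <- counts[ab]
  stats::setNames(as.integer(counts), ab)
}

#' Length-normalized k-mer frequency
#'
#' The k-mer feature value `f = count * k / L`, where `L` is the full
#' sequence length. Note this is a length-scaled frequency, not a
#' probability: for k > 1 it can exceed 1 (e.g. "AAAA" has AA count 3,
#' so f = 3 * 2 / 4 = 1.5). The formula is applied exactly as defined;
#' downstream tree classifiers are insensitive to the scale.
#'
#' @param count k-mer occurrence count(s).
#' @param k k-mer length.
#' @param L full sequence length (> 0).
#' @return Numeric value(s) `count * k / L`.
#' @export
kmer_frequency <- function(count, k, L) {
  if (any(L <= 0)) stop("sequence length L must be positive")
  count * k / L
}

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` is excluded from both the
#' numerator and the denominator. An all-`N` sequence returns 0 with a
#' warning.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  seq <- normalize_seq(seq)
  if (any(nchar(seq) == 0)) stop("empty sequence")
  set <- Biostrings::DNAStringSet(seq)
  counts <- Biostrings::letterFrequency(set, c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- counts[, "G"] + counts[, "C"]
  out <- ifelse(denom == 0, 0, gc / denom)
  if (any(denom == 0)) warning("all-N sequence: GC content set to 0")
  as.numeric(out)
}

#' k-mer feature block for a single sequence
#'
#' The 341-dimensional composition block: all 4 + 16 + 64 + 256 = 340
#' k-mer frequencies for k = 1..4 (each `count * k / L`, overlapping
#' windows), plus GC content. Feature names are `k1_A` .. `k4_TTTT`,
#' `GC_content`. Sequences shorter than 4 nt get zeros for the absent
#' k's; an empty sequence is an error.
#'
#' @param seq A single nucleotide string.
#' @return Named numeric vector of length 341.
#' @export
kmer_feature_block <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- normalize_seq(seq)
  L <- nchar(seq)
  if (L == 0) stop("empty sequence")
  blocks <- lapply(1:4, function(k) {
    ab <- kmer_alphabet(k)
    if (k > L) {
      v <- stats::setNames(numeric(length(ab)), ab)
    } else {
      v <- kmer_frequency(count_kmers(seq, k), k, L)
    }
    stats::setNames(as.numeric(v), paste0("k", k, "_", ab))
  })
  c(do.call(c, blocks), GC_content = gc_content(seq))
}

#' k-mer feature table for a set of sequences
#'
#' Vectorized [kmer_feature_block()] over a sequence tibble; the
#' workhorse for the `kmer` block of [circ_features()].
#'
#' @param seqs Tibble with columns `id`, `seq` (and optionally `label`).
#' @return Tibble: `id`, `label` if present, then the 341 k-mer columns.
#' @export
kmer_features <- function(seqs) {
  check_sequence_tbl(seqs)
  if (any(nchar(seqs$seq) == 0)) stop("empty sequence in `seqs`")
  norm <- normalize_seq(seqs$seq)
  set <- Biostrings::DNAStringSet(norm)
  L <- nchar(norm)
  mats <- lapply(1:4, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(set, width = k)
    counts <- counts[, kmer_alphabet(k), drop = FALSE]
    counts[L < k, ] <- 0  # short sequences: block absent, features 0
    m <- counts * k / L
    colnames(m) <- paste0("k", k, "_", colnames(m))
    m
  })
  m <- do.call(cbind, mats)
  out <- tibble::as_tibble(m)
  out$GC_content <- suppressWarnings(gc_content(norm))
  bind_id_label(seqs, out)
}

bind_id_label <- function(seqs, features) {
  lead <- tibble::tibble(id = seqs$id)
  if ("label" %in% names(seqs)) lead$label <- seqs$label
  dplyr::bind_cols(lead, features)
}
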
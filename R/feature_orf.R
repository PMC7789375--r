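ORF_STOPS <- c("TAA", "TAG", "TGA")

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Find all maximal open reading frames in six frames
#'
#' Scans the three forward and three reverse-complement frames for
#' maximal `ATG ... stop` spans: each reported ORF starts at the first
#' `ATG` after the previous in-frame stop and runs through the next
#' in-frame stop codon (`TAA`, `TAG` or `TGA`), stop included. Internal
#' `ATG`s inside a reported span are not reported as separate ORFs, and
#' ORFs without a stop codon before the sequence end are not counted.
#' Sequences are treated as linear: ORFs do not wrap around the end
#' even for circRNA candidates. Codons containing `N` match neither
#' `ATG` nor a stop.
#'
#' Coordinates are 0-based half-open on the reading strand: for
#' `strand == "-"` they index into `revcomp(seq)`.
#'
#' @param seq A single nucleotide string.
#' @return Tibble with columns `start`, `end`, `strand`, `frame`,
#'   `length`, sorted by decreasing length then start then strand
#'   (`"+"` first); zero rows when no ORF exists.
#' @export
#' @examples
#' find_orfs("ATGTAA")  # one 6-nt ORF in frame 0
find_orfs <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- normalize_seq(seq)
  hits <- dplyr::bind_rows(
    scan_orfs_strand(seq, "+"),
    scan_orfs_strand(revcomp(seq), "-")
  )
  if (nrow(hits) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          strand = character(), frame = integer(),
                          length = integer()))
  }
  hits$length <- hits$end - hits$start
  hits[order(-hits$length, hits$start, match(hits$strand, c("+", "-"))), ]
}

scan_orfs_strand <- function(s, strand) {
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3L
    if (n_codons < 2L) next
    starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, starts, starts + 2L)
    stop_i <- which(codons %in% ORF_STOPS)
    if (!length(stop_i)) next
    atg_i <- which(codons == "ATG")
    if (!length(atg_i)) next
    # first ATG strictly after the previous stop, before this stop
    prev_stop <- c(0L, stop_i[-length(stop_i)])
    first_atg <- atg_i[findInterval(prev_stop, atg_i) + 1L]
    ok <- !is.na(first_atg) & first_atg < stop_i
    if (!any(ok)) next
    out[[length(out) + 1L]] <- cbind(starts[first_atg[ok]] - 1L,
                                     starts[stop_i[ok]] + 2L, frame)
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]),
                 strand = strand, frame = as.integer(m[, 3]))
}

#' Select the optimal (longest) ORF
#'
#' Ties are broken by smaller start coordinate, then `"+"` strand
#' before `"-"`.
#'
#' @param hits ORF tibble from [find_orfs()].
#' @return One-row tibble, or `NULL` when `hits` is empty.
#' @export
optimal_orf <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  hits[order(-hits$length, hits$start, match(hits$strand, c("+", "-")))[1], ]
}

#' ORF feature pair for a single sequence
#'
#' From the optimal ORF: `ORF_coverage_x10 = 10 * orf_length / L`
#' (the ORF-to-transcript length ratio, standardized by a factor of 10)
#' and `ORF_length` in nucleotides (stop codon included). When no ORF
#' exists both are 0.
#'
#' @param seq A single nucleotide string.
#' @return Named numeric vector `c(ORF_coverage_x10, ORF_length)`.
#' @export
#' @examples
#' orf_feature_block("ATGTAA")  # full coverage: c(10, 6)
orf_feature_block <- function(seq) {
  stopifnot(length(seq) == 1L)
  seq <- normalize_seq(seq)
  L <- nchar(seq)
  if (L == 0) stop("empty sequence")
  best <- optimal_orf(find_orfs(seq))
  len <- if (is.null(best)) 0L else best$length
  c(ORF_coverage_x10 = 10 * len / L, ORF_length = as.numeric(len))
}

#' ORF feature table for a set of sequences
#'
#' @param seqs Tibble with columns `id`, `seq` (and optionally `label`).
#' @return Tibble: `id`, `label` if present, `ORF_coverage_x10`,
#'   `ORF_length`.
#' @export
orf_features <- function(seqs) {
  check_sequence_tbl(seqs)
  m <- vapply(seqs$seq, orf_feature_block, numeric(2), USE.NAMES = FALSE)
  bind_id_label(seqs, tibble::tibble(ORF_coverage_x10 = m[1, ],
                                     ORF_length = m[2, ]))
}
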
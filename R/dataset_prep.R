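#' Percent identity between two sequences
#'
#' Global (Needleman-Wunsch) alignment with match score 1, mismatch 0
#' and gap -1 per gapped position; identity is the fraction of aligned
#' columns (gaps included in the denominator) that are exact matches.
#' This is the identity definition behind the redundancy filters; at
#' the scale of curated candidate sets it is exact and needs no
#' external aligner.
#'
#' @param a,b Nucleotide strings (non-empty).
#' @return Identity in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGA")  # 7/8
pairwise_identity <- function(a, b) {
  a <- normalize_seq(a); b <- normalize_seq(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

# identity can never exceed shorter/longer length ratio, so skip the
# alignment when even a perfect match could not clear the threshold
identity_upper_bound <- function(la, lb) pmin(la, lb) / pmax(la, lb)

new_filter_report <- function(n_input, n_kept, removed_ids, stage) {
  structure(list(n_input = n_input, n_kept = n_kept,
                 removed_ids = removed_ids, stage = stage),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", x$stage, ":", x$n_input, "->", x$n_kept,
      "records (", length(x$removed_ids), "removed )\n")
  invisible(x)
}

#' Retrieve the filter report attached to a filtered tibble
#'
#' @param x Result of [dedup_within()] or [length_outlier_filter()].
#' @return The `filter_report` object, or `NULL`.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Remove redundant sequences within a set
#'
#' Greedy redundancy removal: records are visited in decreasing length
#' order (ties by id for stability) and a record is dropped when its
#' [pairwise_identity()] with any already-kept record exceeds
#' `threshold` (strictly greater). The longest member of each
#' near-duplicate cluster therefore survives. Idempotent.
#'
#' @param seqs Sequence tibble (`id`, `seq`, ...).
#' @param threshold Identity above which records are considered
#'   redundant (default 0.95, i.e. "similarity higher than 95%").
#' @return The kept rows, in the original row order, with a
#'   [filter_report()] attribute.
#' @export
dedup_within <- function(seqs, threshold = 0.95) {
  check_sequence_tbl(seqs)
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(seqs)
  len <- nchar(seqs$seq)
  ord <- order(-len, seqs$id)
  kept <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (j in kept) {
      if (identity_upper_bound(len[i], len[j]) <= threshold) next
      if (pairwise_identity(seqs$seq[i], seqs$seq[j]) > threshold) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, i)
  }
  kept <- sort(kept)
  out <- seqs[kept, ]
  attr(out, "filter_report") <- new_filter_report(
    n, length(kept), seqs$id[setdiff(seq_len(n), kept)], "dedup_within")
  out
}

#' Remove cross-set redundant sequences
#'
#' Every pair `(a in set_a, b in set_b)` with identity above
#' `threshold` causes both members to be removed from their sets, so
#' the two classes share no near-identical sequences.
#'
#' @param set_a,set_b Sequence tibbles.
#' @param threshold Identity threshold (default 0.95, strict).
#' @return List with elements `a`, `b` (the surviving tibbles) and
#'   `report` (removed ids per set).
#' @export
dedup_across <- function(set_a, set_b, threshold = 0.95) {
  check_sequence_tbl(set_a, "set_a"); check_sequence_tbl(set_b, "set_b")
  stopifnot(threshold > 0, threshold <= 1)
  la <- nchar(set_a$seq); lb <- nchar(set_b$seq)
  drop_a <- logical(nrow(set_a)); drop_b <- logical(nrow(set_b))
  for (i in seq_len(nrow(set_a))) {
    for (j in seq_len(nrow(set_b))) {
      if (drop_a[i] && drop_b[j]) next
      if (identity_upper_bound(la[i], lb[j]) <= threshold) next
      if (pairwise_identity(set_a$seq[i], set_b$seq[j]) > threshold) {
        drop_a[i] <- TRUE
        drop_b[j] <- TRUE
      }
    }
  }
  list(
    a = set_a[!drop_a, ],
    b = set_b[!drop_b, ],
    report = list(removed_a = set_a$id[drop_a], removed_b = set_b$id[drop_b])
  )
}

#' Remove sequence-length outliers by the box-whisker rule
#'
#' Keeps records whose length lies inside the Tukey fences
#' `[Q1 - coef * IQR, Q3 + coef * IQR]`, with quartiles computed by the
#' linear-interpolation method (`stats::quantile()` type 7) and
#' `coef = 1.5` by default. Fewer than 4 records pass through
#' unchanged with a warning (quartiles are not meaningful).
#'
#' @param seqs Sequence tibble.
#' @param coef Whisker multiplier (default 1.5).
#' @return Kept rows with a [filter_report()] attribute.
#' @export
length_outlier_filter <- function(seqs, coef = 1.5) {
  check_sequence_tbl(seqs)
  n <- nrow(seqs)
  len <- nchar(seqs$seq)
  if (n < 4) {
    warning("fewer than 4 records: length filter skipped")
    out <- seqs
    attr(out, "filter_report") <- new_filter_report(n, n, character(0),
                                                    "length_outlier_filter")
    return(out)
  }
  q <- stats::quantile(len, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  keep <- len >= q[1] - coef * iqr & len <= q[2] + coef * iqr
  out <- seqs[keep, ]
  attr(out, "filter_report") <- new_filter_report(n, sum(keep),
                                                  seqs$id[!keep],
                                                  "length_outlier_filter")
  out
}

#' Run the full dataset preparation pipeline
#'
#' Cross-set redundancy removal, then within-set redundancy removal
#' (keeping the longest representative), then box-whisker length
#' outlier filtering, applied per class.
#'
#' @param pos,neg Positive and negative sequence tibbles.
#' @param threshold Identity threshold (default 0.95).
#' @param coef Whisker multiplier (default 1.5).
#' @return List with `pos`, `neg` (filtered tibbles) and `report`
#'   (per-stage counts).
#' @export
prepare_dataset <- function(pos, neg, threshold = 0.95, coef = 1.5) {
  cross <- dedup_across(pos, neg, threshold)
  pos2 <- dedup_within(cross$a, threshold)
  neg2 <- dedup_within(cross$b, threshold)
  pos3 <- length_outlier_filter(pos2)
  neg3 <- length_outlier_filter(neg2)
  list(
    pos = pos3, neg = neg3,
    report = list(
      n_input = c(pos = nrow(pos), neg = nrow(neg)),
      n_after_cross_dedup = c(pos = nrow(cross$a), neg = nrow(cross$b)),
      n_after_self_dedup = c(pos = nrow(pos2), neg = nrow(neg2)),
      n_after_length_filter = c(pos = nrow(pos3), neg = nrow(neg3)),
      removed_ids = list(
        cross = cross$report,
        self = c(filter_report(pos2)$removed_ids,
                 filter_report(neg2)$removed_ids),
        length = c(filter_report(pos3)$removed_ids,
                   filter_report(neg3)$removed_ids)
      )
    )
  )
}

#' Seeded stratified train/test split
#'
#' Samples `n_per_class` records uniformly without replacement from
#' each class for the training set; all remaining records form the
#' independent test set. Deterministic for a given seed; train and
#' test are disjoint by construction.
#'
#' @param pos,neg Positive and negative sequence tibbles.
#' @param n_per_class Training records per class.
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`, each carrying a
#'   `label` column.
#' @export
split_train_test <- function(pos, neg, n_per_class, seed = 1L) {
  check_sequence_tbl(pos, "pos"); check_sequence_tbl(neg, "neg")
  if (nrow(pos) < n_per_class || nrow(neg) < n_per_class) {
    stop("each class needs at least n_per_class = ", n_per_class,
         " records (have ", nrow(pos), " / ", nrow(neg), ")", call. = FALSE)
  }
  pos$label <- "positive"; neg$label <- "negative"
  withr::with_seed(seed, {
    ip <- sample.int(nrow(pos), n_per_class)
    ineg <- sample.int(nrow(neg), n_per_class)
    list(
      train = dplyr::bind_rows(pos[ip, ], neg[ineg, ]),
      test = dplyr::bind_rows(pos[-ip, ], neg[-ineg, ])
    )
  })
}
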
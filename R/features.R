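#' Extract the full feature table for classification
#'
#' Assembles the named feature blocks for each candidate sequence, in
#' the fixed schema order the trained models expect:
#'
#' * `kmer` — 341 columns `k1_A` .. `k4_TTTT`, `GC_content`
#'   ([kmer_features()])
#' * `orf` — 2 columns `ORF_coverage_x10`, `ORF_length`
#'   ([orf_features()])
#' * `sjsc` — `4 * flank` columns `sjsc_0` .. (default 200)
#'   ([sjsc_features()])
#'
#' With all blocks and the default flank the table has 543 feature
#' columns after `id` and (if present) `label`.
#'
#' @param seqs Tibble with columns `id`, `seq`, optionally `label`.
#' @param genome,junctions Genome and junction table for SJSC window
#'   extraction; when either is `NULL` the SJSC block falls back to
#'   transcript-end windows (see [sjsc_features()]).
#' @param blocks Subset of `c("kmer", "orf", "sjsc")`.
#' @param flank SJSC window half-width (default 50).
#' @return Feature tibble; attribute `sjsc_mode` as in
#'   [sjsc_features()] when the `sjsc` block is included.
#' @export
#' @examples
#' seqs <- tibble::tibble(id = "t1", seq = strrep("ACGT", 100),
#'                        label = "positive")
#' dim(circ_features(seqs))
circ_features <- function(seqs, genome = NULL, junctions = NULL,
                          blocks = c("kmer", "orf", "sjsc"), flank = 50L) {
  check_sequence_tbl(seqs)
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (!length(blocks)) stop("at least one feature block is required")
  parts <- list()
  if ("kmer" %in% blocks) parts$kmer <- kmer_features(seqs)
  if ("orf" %in% blocks) parts$orf <- orf_features(seqs)
  mode <- NULL
  if ("sjsc" %in% blocks) {
    parts$sjsc <- sjsc_features(seqs, genome, junctions, flank)
    mode <- attr(parts$sjsc, "sjsc_mode")
  }
  out <- parts[[1]]
  for (p in parts[-1]) {
    out <- dplyr::bind_cols(out, p[setdiff(names(p), c("id", "label"))])
  }
  if (!is.null(mode)) attr(out, "sjsc_mode") <- mode
  out
}

#' Map feature columns to their blocks
#'
#' @param features A feature tibble (or its column names).
#' @return Named list with elements `kmer`, `orf`, `sjsc`, each a
#'   character vector of column names present in `features` (possibly
#'   empty).
#' @export
feature_block_columns <- function(features) {
  nm <- if (is.character(features)) features else names(features)
  nm <- setdiff(nm, c("id", "label"))
  list(
    kmer = nm[grepl("^k[1-4]_", nm) | nm == "GC_content"],
    orf = nm[grepl("^ORF_", nm)],
    sjsc = nm[grepl("^sjsc_", nm)]
  )
}
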
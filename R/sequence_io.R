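#' Read candidate sequences from a FASTA file
#'
#' Reads transcript sequences into a tibble, one row per FASTA entry.
#' Sequences are normalized with [normalize_seq()]: uppercased, `U`
#' converted to `T`, and any character outside `{A,C,G,T}` (IUPAC
#' ambiguity codes included) mapped to `N`.
#'
#' Class labels can travel inside the FASTA header with a `|label`
#' suffix, e.g. `>tx1|positive`. The suffix is parsed leniently:
#' `positive`/`pos`/`circRNA`/`1` map to `"positive"`,
#' `negative`/`neg`/`lncRNA`/`0` map to `"negative"`; anything else is
#' left as `NA` and the full header is kept as the id.
#'
#' @param path Path to a FASTA file.
#' @param parse_labels Parse a trailing `|label` from headers (default
#'   `TRUE`).
#' @return A tibble with columns `id`, `seq`, `label`
#'   (`"positive"`/`"negative"`/`NA`) and `length` (nucleotides).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x|positive", "acgu", ">y", "NN"), fa)
#' read_fasta(fa)
read_fasta <- function(path, parse_labels = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("empty FASTA file (no records): ", path, call. = FALSE)
  }
  ids <- names(set)
  if (any(!nzchar(ids))) {
    stop("malformed FASTA: empty header line in ", path, call. = FALSE)
  }
  seqs <- unname(normalize_seq(as.character(set)))
  label <- rep(NA_character_, length(ids))
  if (parse_labels) {
    parsed <- parse_label_suffix(ids)
    ids <- parsed$id
    label <- parsed$label
  }
  tibble::tibble(id = ids, seq = seqs, label = label, length = nchar(seqs))
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: writes one entry per row, appending
#' `|label` to the header when a non-`NA` label is present so that
#' labels round-trip through FASTA.
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `label`.
#' @param path Output path.
#' @param with_labels Append `|label` suffixes (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, with_labels = TRUE) {
  check_sequence_tbl(seqs)
  headers <- seqs$id
  if (with_labels && "label" %in% names(seqs)) {
    has <- !is.na(seqs$label)
    headers[has] <- paste0(seqs$id[has], "|", seqs$label[has])
  }
  set <- Biostrings::DNAStringSet(seqs$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Normalize a nucleotide string
#'
#' Uppercases, maps RNA `U` to `T`, and replaces every character outside
#' `{A,C,G,T}` (IUPAC ambiguity codes, gaps, anything else) with `N`.
#' Idempotent: `normalize_seq(normalize_seq(x)) == normalize_seq(x)`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector over the alphabet `{A,C,G,T,N}`.
#' @export
normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  gsub("[^ACGT]", "N", x)
}

parse_label_suffix <- function(headers) {
  has_pipe <- grepl("|", headers, fixed = TRUE)
  id <- headers
  label <- rep(NA_character_, length(headers))
  if (any(has_pipe)) {
    suffix <- tolower(sub("^.*\\|", "", headers[has_pipe]))
    lab <- dplyr::case_when(
      suffix %in% c("positive", "pos", "circrna", "circ", "1") ~ "positive",
      suffix %in% c("negative", "neg", "lncrna", "0") ~ "negative",
      TRUE ~ NA_character_
    )
    recognized <- !is.na(lab)
    idx <- which(has_pipe)[recognized]
    id[idx] <- sub("\\|[^|]*$", "", headers[idx])
    label[idx] <- lab[recognized]
  }
  list(id = id, label = label)
}

check_sequence_tbl <- function(seqs, arg = "seqs") {
  if (!is.data.frame(seqs) || !all(c("id", "seq") %in% names(seqs))) {
    stop("`", arg, "` must be a data frame with columns `id` and `seq`",
         call. = FALSE)
  }
  invisible(seqs)
}

#' Read a junction coordinate table
#'
#' Reads the BED-like table that places each candidate's two splice
#' sites on the genome. Coordinates are 0-based (BED convention): a
#' site is the position of the first base downstream of the junction,
#' and windows around it are half-open `[site - 50, site + 50)`.
#' For lncRNA-like negatives, which have no back-splice, the transcript's
#' genomic start and end stand in as the two sites.
#'
#' The file is tab-delimited with at least five columns in the order
#' `chrom, site5, site3, strand, seq_id`; a header line is detected and
#' skipped if the coordinate fields of the first line are not integers.
#'
#' @param path Path to the tab-delimited table.
#' @return A tibble with columns `chrom` (character), `site5`, `site3`
#'   (integer, 0-based), `strand` (`"+"`/`"-"`), `seq_id`.
#' @export
read_junction_table <- function(path) {
  if (!file.exists(path)) stop("junction table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty junction table: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_int <- function(x) grepl("^-?[0-9]+$", x)
  first <- fields[[1]]
  start_row <- 1L
  if (length(first) >= 3 && (!is_int(first[2]) || !is_int(first[3]))) {
    start_row <- 2L  # header line
    if (length(fields) < 2L) {
      stop("junction table has a header but no data rows: ", path,
           call. = FALSE)
    }
  }
  rows <- lapply(seq(start_row, length(fields)), function(i) {
    f <- fields[[i]]
    if (length(f) < 5L) {
      stop("junction table row ", i, ": expected >= 5 tab-delimited ",
           "columns (chrom, site5, site3, strand, seq_id), got ",
           length(f), call. = FALSE)
    }
    if (!is_int(f[2]) || !is_int(f[3])) {
      stop("junction table row ", i, ": non-integer coordinate ('",
           f[2], "', '", f[3], "')", call. = FALSE)
    }
    site5 <- as.integer(f[2]); site3 <- as.integer(f[3])
    if (site5 < 0L || site3 < 0L) {
      stop("junction table row ", i, ": negative coordinate", call. = FALSE)
    }
    if (!f[4] %in% c("+", "-")) {
      stop("junction table row ", i, ": unknown strand '", f[4],
           "' (expected '+' or '-')", call. = FALSE)
    }
    tibble::tibble(chrom = f[1], site5 = site5, site3 = site3,
                   strand = f[4], seq_id = f[5])
  })
  dplyr::bind_rows(rows)
}

#' Write a junction coordinate table
#'
#' @param junctions Tibble with columns `chrom`, `site5`, `site3`,
#'   `strand`, `seq_id` (as returned by [read_junction_table()]).
#' @param path Output path.
#' @param header Write a header line (default `TRUE`; the reader
#'   detects and skips it).
#' @return `path`, invisibly.
#' @export
write_junction_table <- function(junctions, path, header = TRUE) {
  need <- c("chrom", "site5", "site3", "strand", "seq_id")
  if (!all(need %in% names(junctions))) {
    stop("`junctions` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(junctions[need], path, col_names = header)
  invisible(path)
}

#' Write a feature table to delimited text
#'
#' Writes an extracted feature table ([circ_features()] output) as TSV:
#' first column `id`, then `label` when present, then the feature
#' columns in their fixed schema order. Numbers are written with full
#' double precision so that [read_feature_table()] round-trips the
#' table losslessly (to at least 12 decimal digits).
#'
#' @param features Feature tibble: `id`, optional `label`, numeric
#'   feature columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  if (!is.data.frame(features) || names(features)[1] != "id") {
    stop("`features` must be a data frame whose first column is `id`",
         call. = FALSE)
  }
  feat_cols <- setdiff(names(features), c("id", "label"))
  bad <- feat_cols[!vapply(features[feat_cols], is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ord <- c("id", intersect("label", names(features)), feat_cols)
  out <- features[ord]
  out[feat_cols] <- lapply(out[feat_cols], function(x) {
    formatC(x, digits = 17, format = "g")
  })
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the TSV.
#' @return Tibble with `id`, optional `label`, and numeric feature
#'   columns.
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(tab) && !ncol(tab)) stop("empty feature table: ", path)
  if (names(tab)[1] != "id") {
    stop("feature table must start with an `id` column: ", path,
         call. = FALSE)
  }
  tab$id <- as.character(tab$id)
  feat_cols <- setdiff(names(tab), c("id", "label"))
  tab[feat_cols] <- lapply(tab[feat_cols], as.numeric)
  tab
}
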
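SJSC_CODE <- c(A = 1L, T = -1L, C = 2L, G = -2L, N = 0L)

as_genome <- function(genome) {
  if (isTRUE(attr(genome, "circlass_normalized"))) return(genome)
  if (inherits(genome, "DNAStringSet") || inherits(genome, "BStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  } else if (is.data.frame(genome)) {
    if (!all(c("chrom", "seq") %in% names(genome))) {
      stop("genome data frame must have columns `chrom` and `seq`",
           call. = FALSE)
    }
    genome <- stats::setNames(genome$seq, genome$chrom)
  }
  if (!is.character(genome) || is.null(names(genome))) {
    stop("genome must be a named character vector, DNAStringSet, or a ",
         "data frame with columns `chrom` and `seq`", call. = FALSE)
  }
  out <- stats::setNames(normalize_seq(genome), names(genome))
  attr(out, "circlass_normalized") <- TRUE
  out
}

#' Read a genome FASTA into a named sequence vector
#'
#' @param path Path to a (multi-)FASTA of chromosomes/contigs.
#' @return Named character vector, one element per contig, normalized
#'   to `{A,C,G,T,N}`.
#' @export
read_genome <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty genome FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))  # first word of header
  stats::setNames(normalize_seq(as.character(set)), ids)
}

#' Extract the +/-50 bp genomic window around a splice site
#'
#' Returns the genomic slice `[site - flank, site + flank)` (0-based,
#' half-open; the site base itself is the first base of the downstream
#' half). On the `"-"` strand the reverse complement of that slice is
#' returned, so "upstream"/"downstream" are in transcript orientation
#' and donor/acceptor context is strand-invariant. Positions beyond the
#' chromosome ends are padded with `N`, so the window is always exactly
#' `2 * flank` nt.
#'
#' @param genome Named character vector (or `DNAStringSet`, or tibble
#'   with `chrom`/`seq`) of chromosome sequences.
#' @param chrom Chromosome name; must be present in `genome`.
#' @param site 0-based genomic coordinate of the splice site.
#' @param strand `"+"` or `"-"`.
#' @param flank Bases on each side of the site (default 50).
#' @return A `2 * flank`-character string.
#' @export
extract_window <- function(genome, chrom, site, strand = "+", flank = 50L) {
  genome <- as_genome(genome)
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not found in genome", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (site < 0) stop("site must be non-negative")
  chrom_seq <- genome[[chrom]]
  L <- nchar(chrom_seq)
  lo <- site - flank       # 0-based inclusive
  hi <- site + flank       # 0-based exclusive
  left_pad <- max(0L, -lo)
  right_pad <- max(0L, hi - L)
  core <- substr(chrom_seq, max(lo, 0L) + 1L, min(hi, L))
  w <- paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  if (strand == "-") w <- revcomp(w)
  w
}

#' Integer-encode a junction window
#'
#' The positionwise splice-junction sequence coding: `A -> 1`,
#' `T -> -1`, `C -> 2`, `G -> -2`, `N -> 0`. The hash is a bijection on
#' `{A,C,G,T}` and maps complementary bases to negated codes, so
#' reverse-complementing a window reverses and negates its code array;
#' 0 is the unique `N` code preserving that symmetry.
#'
#' @param window Nucleotide string over `{A,C,G,T,N}` (normalized if
#'   not).
#' @return Integer vector, one code per position.
#' @export
#' @examples
#' encode_sjsc("ATCG")  # 1 -1 2 -2
encode_sjsc <- function(window) {
  stopifnot(length(window) == 1L)
  chars <- strsplit(normalize_seq(window), "", fixed = TRUE)[[1]]
  unname(SJSC_CODE[chars])
}

#' Decode an integer code array back to sequence
#'
#' Inverse of [encode_sjsc()] (exact on `{A,C,G,T}`; 0 decodes to `N`).
#'
#' @param codes Integer vector over `{1, -1, 2, -2, 0}`.
#' @return Nucleotide string.
#' @export
decode_sjsc <- function(codes) {
  lut <- stats::setNames(names(SJSC_CODE), as.character(SJSC_CODE))
  bad <- setdiff(as.character(codes), names(lut))
  if (length(bad)) stop("invalid SJSC code(s): ", paste(bad, collapse = ", "))
  paste0(lut[as.character(codes)], collapse = "")
}

#' SJSC code block for one junction
#'
#' Concatenates the encoded +/-`flank` windows at the two splice sites,
#' `site5` (transcript-5') first: `2 * 2 * flank` codes in total (200
#' at the default flank of 50).
#'
#' @param genome Genome as in [extract_window()].
#' @param junction One-row data frame (or named list) with `chrom`,
#'   `site5`, `site3`, `strand`.
#' @param flank Bases each side of each site (default 50).
#' @return Integer vector of length `4 * flank`.
#' @export
sjsc_block <- function(genome, junction, flank = 50L) {
  w5 <- extract_window(genome, junction$chrom, junction$site5,
                       junction$strand, flank)
  w3 <- extract_window(genome, junction$chrom, junction$site3,
                       junction$strand, flank)
  c(encode_sjsc(w5), encode_sjsc(w3))
}

#' SJSC feature table for a set of sequences
#'
#' Looks up each record's junction by `seq_id`, extracts the two
#' +/-`flank` windows from the genome and encodes them. Feature columns
#' are `sjsc_0` .. `sjsc_199` (site5 window positions first).
#'
#' When `genome` or `junctions` is `NULL` (FASTA-only mode) the windows
#' are taken from the candidate sequence itself: the site5 window is 50
#' `N`s followed by the transcript's first 50 nt, the site3 window is
#' its last 50 nt followed by 50 `N`s. This degraded mode keeps the
#' classifier runnable without genome coordinates and is flagged in the
#' result's `sjsc_mode` attribute (`"genome"` vs `"fasta_fallback"`).
#'
#' @param seqs Tibble with columns `id`, `seq` (and optionally `label`).
#' @param genome Genome as in [extract_window()], or `NULL`.
#' @param junctions Junction tibble as from [read_junction_table()], or
#'   `NULL`.
#' @param flank Bases each side of each site (default 50).
#' @return Tibble: `id`, `label` if present, then `4 * flank` integer
#'   code columns; attribute `sjsc_mode` records the extraction mode.
#' @export
sjsc_features <- function(seqs, genome = NULL, junctions = NULL,
                          flank = 50L) {
  check_sequence_tbl(seqs)
  fallback <- is.null(genome) || is.null(junctions)
  if (fallback) {
    norm <- normalize_seq(seqs$seq)
    codes <- lapply(norm, function(s) {
      head50 <- substr(s, 1L, min(flank, nchar(s)))
      tail50 <- substr(s, max(1L, nchar(s) - flank + 1L), nchar(s))
      w5 <- paste0(strrep("N", flank),
                   head50, strrep("N", flank - nchar(head50)))
      w3 <- paste0(strrep("N", flank - nchar(tail50)), tail50,
                   strrep("N", flank))
      c(encode_sjsc(w5), encode_sjsc(w3))
    })
  } else {
    genome <- as_genome(genome)
    idx <- match(seqs$id, junctions$seq_id)
    if (anyNA(idx)) {
      stop("no junction entry for sequence id(s): ",
           paste(utils::head(seqs$id[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    jn <- junctions[idx, ]
    codes <- lapply(seq_len(nrow(jn)), function(i) {
      sjsc_block(genome, jn[i, ], flank)
    })
  }
  m <- do.call(rbind, codes)
  colnames(m) <- paste0("sjsc_", seq_len(4L * flank) - 1L)
  out <- bind_id_label(seqs, tibble::as_tibble(m))
  attr(out, "sjsc_mode") <- if (fallback) "fasta_fallback" else "genome"
  out
}
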
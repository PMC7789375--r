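# Independent oracles used across tests. These deliberately avoid the
# package's code paths: plain sliding windows, exhaustive scans and
# textbook identities.

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

# brute-force k-mer counting: enumerate every window, drop N windows
bf_count_kmers <- function(seq, k) {
  L <- nchar(seq)
  kmers <- circlass::kmer_alphabet(k)
  counts <- setNames(integer(length(kmers)), kmers)
  if (k > L) return(counts)
  for (i in 1:(L - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (!grepl("N", w, fixed = TRUE)) counts[w] <- counts[w] + 1L
  }
  counts
}

bf_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# exhaustive ORF scan: every (ATG, next in-frame stop) pair on both
# strands, then keep only the earliest ATG per stop
bf_find_orfs <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else bf_revcomp(seq)
    L <- nchar(s)
    for (a in seq_len(max(L - 5, 0))) {
      if (substr(s, a, a + 2) != "ATG") next
      j <- a + 3
      while (j + 2 <= L) {
        if (substr(s, j, j + 2) %in% stops) {
          hits[[length(hits) + 1]] <- data.frame(
            start = a - 1L, end = j + 2L, strand = strand,
            frame = (a - 1L) %% 3L)
          break
        }
        j <- j + 3
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer()))
  }
  h <- do.call(rbind, hits)
  # earliest ATG per (stop, strand): internal ATGs are not separate ORFs
  keep <- !duplicated(h[c("end", "strand", "frame")])
  h <- h[keep, ]
  h[order(h$strand, h$start), ]
}

# MCC equals the Pearson correlation of the binary truth/pred vectors;
# the other metrics fall out of the reconstructed vectors directly
bf_metrics_from_counts <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  mcc <- suppressWarnings(cor(truth, pred))
  if (is.na(mcc)) mcc <- 0
  list(
    recall = if (sum(truth) == 0) 0 else sum(truth & pred) / sum(truth),
    precision = if (sum(pred) == 0) 0 else sum(truth & pred) / sum(pred),
    accuracy = mean(truth == pred),
    mcc = mcc
  )
}

sorted_orf_key <- function(df) {
  df <- df[order(df$strand, df$start, df$end), ]
  paste(df$start, df$end, df$strand, df$frame, sep = ":", collapse = ";")
}

# small fixture config for fast unit tests
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_pos = 25L, n_neg = 25L, length_range = c(250L, 400L),
                   pos_orf_max = 200L, neg_orf_min = 220L, seed = 42L)
  do.call(circlass::fixture_config, utils::modifyList(defaults, args))
}
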
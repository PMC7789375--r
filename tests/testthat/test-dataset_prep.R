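test_that("pairwise identity matches hand-computed alignments", {
  withr::with_seed(61, s <- random_seq(60))
  expect_equal(pairwise_identity(s, s), 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGA"), 7 / 8)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

make_cluster_fixture <- function() {
  # 3 planted near-duplicate clusters + singletons; mutate a few bases
  withr::with_seed(67, {
    bases <- replicate(3, random_seq(150))
    mutate_few <- function(s, n_mut) {
      chars <- strsplit(s, "")[[1]]
      at <- sample(length(chars), n_mut)
      chars[at] <- vapply(chars[at], function(ch) {
        sample(setdiff(c("A", "C", "G", "T"), ch), 1)
      }, character(1))
      paste0(chars, collapse = "")
    }
    clustered <- unlist(lapply(1:3, function(ci) {
      c(paste0(bases[ci], random_seq(4)),        # longest: base + 4 nt
        mutate_few(bases[ci], 1),                 # ~99% identity to base
        mutate_few(bases[ci], 2))                 # ~96% identity to longest
    }))
    singles <- replicate(11, random_seq(sample(120:180, 1)))
    tibble::tibble(
      id = sprintf("r%02d", 1:20),
      seq = c(clustered, singles))
  })
}

test_that("within-set dedup keeps the longest of near-identical records", {
  seqs <- tibble::tibble(
    id = c("short", "long"),
    seq = c(substr(strrep("ACGT", 25), 1, 98), strrep("ACGT", 25)))
  kept <- dedup_within(seqs)
  expect_equal(kept$id, "long")
  expect_equal(filter_report(kept)$removed_ids, "short")
})

test_that("distinct sets pass dedup unchanged and dedup is idempotent", {
  withr::with_seed(71, {
    seqs <- tibble::tibble(id = paste0("s", 1:8),
                           seq = replicate(8, random_seq(100)))
  })
  kept <- dedup_within(seqs)
  expect_equal(nrow(kept), 8L)
  again <- dedup_within(kept)
  expect_equal(again$id, kept$id)
})

test_that("dedup recovers planted clusters, matching all-pairs clustering", {
  seqs <- make_cluster_fixture()
  kept <- dedup_within(seqs)
  # one representative (the extended, longest member) per planted cluster
  expect_equal(intersect(kept$id, sprintf("r%02d", 1:9)),
               c("r01", "r04", "r07"))
  expect_equal(nrow(kept), 3L + 11L)

  # all-pairs oracle: full identity matrix, then greedy longest-first
  n <- nrow(seqs)
  M <- diag(1, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- pairwise_identity(seqs$seq[i], seqs$seq[j])
    }
  }
  ord <- order(-nchar(seqs$seq), seqs$id)
  oracle_kept <- integer(0)
  for (i in ord) {
    if (!any(M[i, oracle_kept] > 0.95)) oracle_kept <- c(oracle_kept, i)
  }
  expect_setequal(kept$id, seqs$id[oracle_kept])
})

test_that("cross-set dedup removes shared sequences from both sides", {
  withr::with_seed(73, {
    a <- tibble::tibble(id = paste0("a", 1:6),
                        seq = replicate(6, random_seq(120)))
    b <- tibble::tibble(id = paste0("b", 1:6),
                        seq = replicate(6, random_seq(120)))
  })
  res <- dedup_across(a, b)
  expect_equal(nrow(res$a), 6L)  # disjoint: unchanged
  expect_equal(nrow(res$b), 6L)

  b2 <- b
  b2$seq[3] <- a$seq[2]  # plant one shared sequence
  res2 <- dedup_across(a, b2)
  expect_equal(res2$report$removed_a, "a2")
  expect_equal(res2$report$removed_b, "b3")
  expect_false("a2" %in% res2$a$id)
  expect_false("b3" %in% res2$b$id)
})

test_that("cross-set dedup finds exactly the planted duplicates", {
  withr::with_seed(79, {
    a <- tibble::tibble(id = paste0("a", 1:15),
                        seq = replicate(15, random_seq(130)))
    b <- tibble::tibble(id = paste0("b", 1:15),
                        seq = replicate(15, random_seq(130)))
    planted <- c(2, 5, 9, 11, 14)
    b$seq[planted] <- a$seq[planted]
  })
  res <- dedup_across(a, b)
  expect_setequal(res$report$removed_a, paste0("a", planted))
  expect_setequal(res$report$removed_b, paste0("b", planted))
})

test_that("length filtering applies the Tukey box-whisker fences", {
  seqs <- tibble::tibble(id = paste0("s", 1:11),
                         seq = c(replicate(10, strrep("A", 100)),
                                 strrep("A", 10000)))
  kept <- length_outlier_filter(seqs)
  expect_equal(filter_report(kept)$removed_ids, "s11")

  # identical lengths: IQR 0, nothing removed
  same <- tibble::tibble(id = paste0("t", 1:6), seq = strrep("AC", 50))
  expect_equal(nrow(length_outlier_filter(same)), 6L)

  # lengths 1..100 plus two gross outliers: exactly those two removed,
  # agreeing with direct quantile computation
  lens <- c(1:100, 1000, 2000)
  seqs2 <- tibble::tibble(id = paste0("u", seq_along(lens)),
                          seq = vapply(lens, strrep, character(1), x = "A"))
  kept2 <- length_outlier_filter(seqs2)
  q <- quantile(lens, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
  expect_setequal(filter_report(kept2)$removed_ids,
                  seqs2$id[lens < fence[1] | lens > fence[2]])
  expect_setequal(filter_report(kept2)$removed_ids, c("u101", "u102"))
})

test_that("length filtering passes tiny sets through with a warning", {
  seqs <- tibble::tibble(id = c("a", "b"), seq = c("ACGT", "ACGTACGT"))
  expect_warning(kept <- length_outlier_filter(seqs), "fewer than 4")
  expect_equal(nrow(kept), 2L)
})

test_that("train/test splits are seeded, stratified and disjoint", {
  withr::with_seed(83, {
    pos <- tibble::tibble(id = paste0("p", 1:30),
                          seq = replicate(30, random_seq(50)))
    neg <- tibble::tibble(id = paste0("n", 1:25),
                          seq = replicate(25, random_seq(50)))
  })
  sp1 <- split_train_test(pos, neg, 20, seed = 9)
  sp2 <- split_train_test(pos, neg, 20, seed = 9)
  expect_identical(sp1$train$id, sp2$train$id)
  expect_equal(nrow(sp1$train), 40L)
  expect_equal(nrow(sp1$test), 15L)
  expect_length(intersect(sp1$train$id, sp1$test$id), 0L)
  expect_equal(sum(sp1$train$label == "positive"), 20L)
  expect_error(split_train_test(pos, neg, 26), "at least")
})

test_that("the full preparation pipeline reports non-increasing counts", {
  seqs <- make_cluster_fixture()
  pos <- seqs[1:10, ]; neg <- seqs[11:20, ]
  res <- prepare_dataset(pos, neg)
  r <- res$report
  expect_true(all(r$n_after_cross_dedup <= r$n_input))
  expect_true(all(r$n_after_self_dedup <= r$n_after_cross_dedup))
  expect_true(all(r$n_after_length_filter <= r$n_after_self_dedup))
})
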
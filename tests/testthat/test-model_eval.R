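test_that("metrics evaluate the confusion-table formulas", {
  perfect <- compute_metrics(10, 0, 10, 0)
  expect_equal(unlist(perfect[c("recall", "precision", "accuracy", "f1",
                                "mcc")]),
               c(recall = 1, precision = 1, accuracy = 1, f1 = 1, mcc = 1))

  m <- compute_metrics(8, 2, 7, 3)
  expect_equal(m$recall, 8 / 11)
  expect_equal(m$precision, 0.8)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$f1, 2 * 0.8 * (8 / 11) / (0.8 + 8 / 11))
  expect_equal(m$mcc, (8 * 7 - 2 * 3) / sqrt(10 * 11 * 9 * 10))

  chance <- compute_metrics(5, 5, 5, 5)
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$mcc, 0)
})

test_that("metrics match the correlation-based oracle on random tables", {
  withr::with_seed(307, {
    for (i in 1:100) {
      cc <- as.list(sample(0:40, 4, replace = TRUE))
      names(cc) <- c("tp", "fp", "tn", "fn")
      if (Reduce(`+`, cc) == 0) next
      got <- do.call(compute_metrics, cc)
      want <- do.call(bf_metrics_from_counts, cc)
      expect_equal(got$recall, want$recall)
      expect_equal(got$precision, want$precision)
      expect_equal(got$accuracy, want$accuracy)
      expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
    }
  })
})

test_that("zero denominators follow the documented conventions", {
  m <- compute_metrics(0, 0, 10, 5)  # nothing predicted positive
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_equal(m$mcc, 0)
  expect_error(compute_metrics(0, 0, 0, 0), "zero")
})

test_that("swapping the label convention transforms metrics coherently", {
  withr::with_seed(311, {
    for (i in 1:25) {
      cc <- sample(1:30, 4)  # tp fp tn fn, all positive
      a <- compute_metrics(cc[1], cc[2], cc[3], cc[4])
      b <- compute_metrics(cc[3], cc[4], cc[1], cc[2])  # classes swapped
      expect_equal(a$accuracy, b$accuracy)
      expect_equal(abs(a$mcc), abs(b$mcc), tolerance = 1e-12)
      # swapped recall is the original specificity TN/(TN+FP)
      expect_equal(b$recall, cc[3] / (cc[3] + cc[2]))
    }
  })
})

make_toy_features <- function(n_per_class = 30, p = 4, gap = 2, seed = 401) {
  withr::with_seed(seed, {
    x_pos <- matrix(rnorm(n_per_class * p, mean = gap), n_per_class, p)
    x_neg <- matrix(rnorm(n_per_class * p, mean = 0), n_per_class, p)
    m <- rbind(x_pos, x_neg)
    colnames(m) <- paste0("f", seq_len(p))
    dplyr::bind_cols(
      tibble::tibble(id = paste0("r", seq_len(2 * n_per_class)),
                     label = rep(c("positive", "negative"),
                                 each = n_per_class)),
      tibble::as_tibble(m))
  })
}

test_that("training is deterministic and records hyperparameters", {
  feats <- make_toy_features()
  m1 <- train_classifier(feats, "rf", seed = 5)
  m2 <- train_classifier(feats, "rf", seed = 5)
  expect_equal(m1$hyperparameters$n_estimators, 100L)
  expect_equal(m1$fit$ntree, 100)
  p1 <- predict(m1, feats)
  p2 <- predict(m2, feats)
  expect_identical(p1$score, p2$score)

  msvm <- train_classifier(feats, "svm", seed = 5)
  expect_equal(msvm$hyperparameters, list(C = 10, gamma = 0.001,
                                          kernel = "rbf"))
  mknn <- train_classifier(feats, "knn", seed = 5)
  expect_equal(mknn$hyperparameters$n_neighbors, 7L)
})

test_that("every algorithm separates well-separated classes", {
  feats <- make_toy_features(gap = 6)
  for (alg in c("rf", "knn", "gnb", "svm")) {
    model <- train_classifier(feats, alg, seed = 2)
    pred <- predict(model, feats)
    acc <- mean((pred$score >= 0.5) == (feats$label == "positive"))
    expect_gte(acc, 0.97)
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    expect_true(all(pred$label %in% c("circRNA", "non-circRNA")))
  }
})

test_that("degenerate training inputs are rejected with clear errors", {
  feats <- make_toy_features()
  one_class <- dplyr::filter(feats, .data$label == "positive")
  expect_error(train_classifier(one_class, "rf"), "both classes")
  bad <- feats
  bad$f2[3] <- NaN
  expect_error(train_classifier(bad, "rf"), "f2")
})

test_that("prediction validates the feature schema and is row-stateless", {
  feats <- make_toy_features()
  model <- train_classifier(feats, "rf", seed = 7)
  renamed <- dplyr::rename(feats, zz = "f1")
  expect_error(predict(model, renamed), "f1")
  expect_error(predict(model, renamed), "zz")

  shuffled <- feats[rev(seq_len(nrow(feats))), ]
  p_fwd <- predict(model, feats)
  p_rev <- predict(model, shuffled)
  expect_equal(p_rev$score[match(p_fwd$id, p_rev$id)], p_fwd$score)
})

test_that("model bundles round-trip through disk and check their version", {
  feats <- make_toy_features()
  model <- train_classifier(feats, "rf", seed = 11)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  loaded <- load_model(path)
  expect_identical(predict(loaded, feats)$score, predict(model, feats)$score)
  expect_equal(length(loaded$feature_schema), 4L)

  # truncated file
  raw_bytes <- readBin(path, "raw", file.size(path))
  writeBin(raw_bytes[1:20], path)
  expect_error(load_model(path), "failed to read")

  # version mismatch
  stale <- model
  stale$version <- "0.0"
  saveRDS(stale, path)
  expect_error(load_model(path), "version")

  saveRDS(list(1, 2), path)
  expect_error(load_model(path), "circ_model")
})

test_that("the ROC sweep agrees with an independent AUC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(419, {
    for (i in 1:10) {
      truth <- sample(c("positive", "negative"), 150, replace = TRUE)
      score <- rnorm(150) + (truth == "positive") * runif(1, 0, 2)
      got <- roc_auc(truth, score)
      want <- as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = score, levels = c("negative",
        "positive"), direction = "<", quiet = TRUE)))
      expect_equal(got, want, tolerance = 1e-12)
      r <- compute_roc(truth, score)
      expect_equal(unlist(r[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
      expect_equal(unlist(r[nrow(r), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
    }
  })
})

test_that("repeated k-fold CV runs the full stratified protocol", {
  feats <- make_toy_features(n_per_class = 25, gap = 4)
  cv <- repeated_kfold_cv(feats, "rf", k = 5, repeats = 3, seed = 13)
  expect_equal(nrow(cv$folds), 15L)
  expect_equal(nrow(cv$repeat_means), 3L)
  expect_equal(nrow(cv$summary), 1L)
  expect_gte(cv$summary$accuracy, 0.9)
  expect_equal(nrow(cv$scores), 3L * 50L)
  # every record held out exactly once per repeat
  expect_equal(sort(table(cv$scores$id)), sort(rep(3L, 50)),
               ignore_attr = TRUE)

  cv2 <- repeated_kfold_cv(feats, "rf", k = 5, repeats = 3, seed = 13)
  expect_identical(cv$folds, cv2$folds)
  expect_error(repeated_kfold_cv(feats, "rf", k = 30), "stratified")
})

test_that("CV accuracy sits at chance on label-permuted data", {
  feats <- make_toy_features(n_per_class = 30, gap = 3)
  feats$label <- withr::with_seed(421, sample(feats$label))
  cv <- repeated_kfold_cv(feats, "rf", k = 5, repeats = 2, seed = 17)
  se <- sqrt(0.25 / nrow(feats))
  expect_lt(abs(cv$summary$accuracy - 0.5), 4 * se)
})

test_that("the combination grid enumerates 2^b - 1 block subsets", {
  withr::with_seed(431, {
    seqs <- tibble::tibble(
      id = paste0("s", 1:40),
      seq = replicate(40, random_seq(sample(250:350, 1))),
      label = rep(c("positive", "negative"), each = 20))
  })
  feats <- circ_features(seqs)  # FASTA-only SJSC
  grid <- feature_combination_grid(feats, "rf", k = 4, repeats = 1,
                                   seed = 19)
  expect_s3_class(grid, "circ_grid")
  expect_equal(nrow(grid), 7L)
  expect_setequal(grid$combination,
                  c("K", "J", "O", "K+J", "K+O", "J+O", "K+J+O"))
  expect_equal(grid$n_features[grid$combination == "K+J+O"], 543L)
  grid2 <- feature_combination_grid(feats, "rf", k = 4, repeats = 1,
                                    seed = 19)
  expect_identical(tibble::as_tibble(grid), tibble::as_tibble(grid2))
  no_blocks <- feats[c("id", "label")]
  expect_error(feature_combination_grid(no_blocks), "no feature blocks")
})

test_that("tidy and glance expose CV and model summaries", {
  feats <- make_toy_features(n_per_class = 20)
  cv <- repeated_kfold_cv(feats, "rf", k = 4, repeats = 2, seed = 23)
  td <- tidy(cv)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 8L)
  gl <- glance(cv)
  expect_equal(gl$algorithm, "rf")
  expect_equal(gl$k, 4L)
  expect_true(all(c("accuracy", "mcc", "auc") %in% names(gl)))

  model <- train_classifier(feats, "rf", seed = 23)
  expect_equal(nrow(tidy(model)), 4L)  # one row per feature importance
  expect_equal(glance(model)$n_features, 4L)
})

test_that("autoplot returns ggplot objects for CV and grid results", {
  feats <- make_toy_features(n_per_class = 15)
  cv <- repeated_kfold_cv(feats, "rf", k = 3, repeats = 1, seed = 29)
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
  expect_s3_class(plot_pr_curve(cv), "ggplot")
})
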
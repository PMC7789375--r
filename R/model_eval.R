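#' Confusion counts from truth and predicted labels
#'
#' @param truth,pred Vectors of class labels.
#' @param positive The label counted as positive (default
#'   `"positive"`, the circRNA class).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(truth, pred, positive = "positive") {
  stopifnot(length(truth) == length(pred))
  t_pos <- truth == positive
  p_pos <- pred == positive
  c(tp = sum(t_pos & p_pos), fp = sum(!t_pos & p_pos),
    tn = sum(!t_pos & !p_pos), fn = sum(t_pos & !p_pos))
}

#' Classification metrics from a confusion table
#'
#' Computes recall `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/n`, F1 `2*P*R/(P+R)` and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Zero-denominator conventions: recall, precision and F1 are 0 when
#' their denominator is 0; MCC is defined as 0 when any factor of its
#' denominator is 0 (the formula is otherwise undefined there).
#'
#' @param tp,fp,tn,fn Confusion counts (non-negative; together > 0).
#'   Alternatively `tp` may be a named vector as from
#'   [confusion_counts()].
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `recall`,
#'   `precision`, `accuracy`, `f1`, `mcc`.
#' @export
#' @examples
#' compute_metrics(8, 2, 7, 3)
compute_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.null(fp) && length(tp) == 4 && !is.null(names(tp))) {
    fp <- tp[["fp"]]; tn <- tp[["tn"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("negative confusion count")
  n <- tp + fp + tn + fn
  if (n == 0) stop("all confusion counts are zero")
  # doubles: products of large counts overflow integers
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  accuracy <- (tp + tn) / n
  f1 <- safe_div(2 * precision * recall, precision + recall)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn, recall = recall,
                 precision = precision, accuracy = accuracy, f1 = f1,
                 mcc = mcc)
}

ALGORITHMS <- c("rf", "knn", "gnb", "svm")

algorithm_hyperparameters <- function(algorithm) {
  switch(algorithm,
    rf = list(n_estimators = 100L),
    svm = list(C = 10, gamma = 0.001, kernel = "rbf"),
    knn = list(n_neighbors = 7L, weights = "uniform", p = 2L),
    gnb = list()
  )
}

feature_matrix <- function(features, schema = NULL) {
  feat_cols <- setdiff(names(features), c("id", "label"))
  if (!is.null(schema)) {
    missing <- setdiff(schema, feat_cols)
    extra <- setdiff(feat_cols, schema)
    if (length(missing) || length(extra)) {
      stop("feature schema mismatch.",
           if (length(missing)) paste0(" Missing: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) " ..."),
           if (length(extra)) paste0(" Extra: ",
             paste(utils::head(extra, 5), collapse = ", "),
             if (length(extra) > 5) " ..."),
           call. = FALSE)
    }
    feat_cols <- schema
  }
  m <- as.matrix(features[feat_cols])
  if (!is.numeric(m)) stop("feature columns must be numeric")
  bad <- colnames(m)[!apply(is.finite(m), 2, all)]
  if (length(bad)) {
    stop("non-finite values in feature column(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  m
}

#' Train a circRNA-vs-lncRNA classifier
#'
#' Fits one of four algorithms on a labeled feature table, with fixed
#' hyperparameters: random forest with 100 trees (`rf`, the default
#' and recommended model), RBF-kernel support vector machine with
#' `C = 10`, `gamma = 0.001` (`svm`), 7-nearest-neighbours with
#' uniform weights and Euclidean distance (`knn`), and Gaussian naive
#' Bayes (`gnb`). All other settings are the backends' defaults;
#' features are not rescaled.
#'
#' @param features Feature tibble with `id`, `label`
#'   (`"positive"`/`"negative"`, both present) and numeric feature
#'   columns.
#' @param algorithm One of `"rf"`, `"knn"`, `"gnb"`, `"svm"`.
#' @param seed Integer seed for the stochastic fits (`NULL` to use the
#'   current RNG state, e.g. inside cross-validation).
#' @return A `circ_model` bundle: fitted backend object, algorithm,
#'   hyperparameters, ordered feature schema, and training metadata
#'   (seed, timestamp, dataset hash, class sizes).
#' @export
train_classifier <- function(features, algorithm = "rf", seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (!"label" %in% names(features)) stop("`features` must have a `label` column")
  x <- feature_matrix(features)
  y <- factor(features$label, levels = c("negative", "positive"))
  if (anyNA(y)) stop("labels must be 'positive' or 'negative'")
  if (length(unique(y)) < 2) stop("both classes must be present in `label`")
  fit_fun <- function() {
    switch(algorithm,
      rf = randomForest::randomForest(x, y, ntree = 100L),
      svm = e1071::svm(x, y, cost = 10, gamma = 0.001, kernel = "radial",
                       probability = TRUE, scale = FALSE),
      gnb = e1071::naiveBayes(x, y),
      knn = list(train = x, cl = y)  # lazy learner: memorize training set
    )
  }
  fit <- if (is.null(seed)) fit_fun() else withr::with_seed(seed, fit_fun())
  structure(list(
    algorithm = algorithm,
    hyperparameters = algorithm_hyperparameters(algorithm),
    feature_schema = colnames(x),
    fit = fit,
    seed = seed,
    trained_at = format(Sys.time(), tz = "UTC"),
    dataset_hash = digest::digest(list(x, as.character(y))),
    n_train = c(negative = sum(y == "negative"),
                positive = sum(y == "positive")),
    version = CIRC_MODEL_VERSION
  ), class = "circ_model")
}

CIRC_MODEL_VERSION <- "1.0"

#' @export
print.circ_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat("<circ_model> algorithm:", x$algorithm,
      if (nzchar(hp)) paste0("(", hp, ")"), "\n")
  cat("  features:", length(x$feature_schema),
      "| trained on", sum(x$n_train), "records (",
      x$n_train[["positive"]], "positive /",
      x$n_train[["negative"]], "negative )\n")
  invisible(x)
}

score_positive <- function(model, x) {
  # make sure the backend's predict() S3 methods are registered, even in
  # a fresh session that only deserialized the bundle
  backend <- switch(model$algorithm, rf = "randomForest", knn = "class",
                    "e1071")
  loadNamespace(backend)
  switch(model$algorithm,
    rf = unname(stats::predict(model$fit, x, type = "prob")[, "positive"]),
    svm = {
      p <- stats::predict(model$fit, x, probability = TRUE)
      unname(attr(p, "probabilities")[, "positive"])
    },
    gnb = {
      raw <- stats::predict(model$fit, x, type = "raw")
      p <- unname(raw[, "positive"])
      if (anyNA(p)) {  # degenerate densities: fall back to hard labels
        cls <- stats::predict(model$fit, x, type = "class")
        p[is.na(p)] <- as.numeric(cls[is.na(p)] == "positive")
      }
      p
    },
    knn = {
      pred <- class::knn(model$fit$train, x, model$fit$cl, k = 7L,
                         prob = TRUE)
      win <- attr(pred, "prob")  # vote share of the winning class
      ifelse(pred == "positive", win, 1 - win)
    }
  )
}

#' Predict circRNA labels and scores
#'
#' Scores each record with the class probability of the circRNA
#' (positive) class and thresholds it at 0.5. The feature columns of
#' `newdata` must match the model's schema exactly; missing or extra
#' columns are reported by name. Predictions depend only on each row's
#' features, never on the other rows in the batch.
#'
#' @param object A `circ_model` from [train_classifier()].
#' @param newdata Feature tibble with `id` and the model's feature
#'   columns.
#' @param ... Unused.
#' @return Tibble: `id`, `score` (P(circRNA) in `[0, 1]`), `label`
#'   (`"circRNA"` or `"non-circRNA"`).
#' @export
predict.circ_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata, schema = object$feature_schema)
  score <- score_positive(object, x)
  tibble::tibble(
    id = if ("id" %in% names(newdata)) newdata$id else
      as.character(seq_len(nrow(newdata))),
    score = score,
    label = ifelse(score >= 0.5, "circRNA", "non-circRNA")
  )
}

#' Save / load a trained model bundle
#'
#' The bundle is serialized with its format version; loading a file
#' that is not a `circ_model` or carries a different version fails with
#' an explicit error. A save/load round trip reproduces predictions
#' exactly.
#'
#' @param model A `circ_model`.
#' @param path File path.
#' @return `save_model()`: `path` invisibly; `load_model()`: the
#'   `circ_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "circ_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("failed to read model bundle '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  if (!inherits(model, "circ_model")) {
    stop("'", path, "' does not contain a circ_model bundle", call. = FALSE)
  }
  if (!identical(model$version, CIRC_MODEL_VERSION)) {
    stop("model bundle version ", model$version,
         " does not match supported version ", CIRC_MODEL_VERSION,
         call. = FALSE)
  }
  model
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (descending)
#' and records (FPR, TPR) at each, prepending (0, 0); with finite
#' distinct scores the curve ends at (1, 1). `roc_auc()` integrates it
#' by the trapezoid rule.
#'
#' @param truth Labels (`positive` per the `positive` argument).
#' @param score Numeric classifier scores, higher = more positive.
#' @param positive Positive label (default `"positive"`).
#' @return `compute_roc()`: tibble `threshold`, `fpr`, `tpr`;
#'   `compute_pr()`: tibble `threshold`, `recall`, `precision`.
#' @export
compute_roc <- function(truth, score, positive = "positive") {
  sw <- threshold_sweep(truth, score, positive)
  tibble::tibble(
    threshold = c(Inf, sw$threshold),
    fpr = c(0, sw$fp / max(sw$n_neg, 1)),
    tpr = c(0, sw$tp / max(sw$n_pos, 1))
  )
}

#' @rdname compute_roc
#' @export
compute_pr <- function(truth, score, positive = "positive") {
  sw <- threshold_sweep(truth, score, positive)
  tibble::tibble(
    threshold = sw$threshold,
    recall = sw$tp / max(sw$n_pos, 1),
    precision = ifelse(sw$tp + sw$fp == 0, 1, sw$tp / (sw$tp + sw$fp))
  )
}

threshold_sweep <- function(truth, score, positive = "positive") {
  stopifnot(length(truth) == length(score))
  pos <- truth == positive
  ord <- order(-score)
  score <- score[ord]; pos <- pos[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(score, fromLast = TRUE)  # one point per unique score
  list(threshold = score[last], tp = tp[last], fp = fp[last],
       n_pos = sum(pos), n_neg = sum(!pos))
}

#' @rdname compute_roc
#' @export
roc_auc <- function(truth, score, positive = "positive") {
  r <- compute_roc(truth, score, positive)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Stratified repeated k-fold cross-validation
#'
#' The evaluation protocol: stratified ten-fold cross-validation,
#' metrics averaged over the folds, the whole procedure repeated ten
#' times with fresh fold assignments, and the repeat means averaged
#' into a grand mean. Folds are stratified by class and fully
#' determined by `seed`. ROC and PR curves are computed from the
#' pooled held-out scores of all repeats.
#'
#' @param features Labeled feature tibble (as for
#'   [train_classifier()]).
#' @param algorithm One of `"rf"`, `"knn"`, `"gnb"`, `"svm"`.
#' @param k Number of folds (default 10); each class must have at
#'   least `k` records.
#' @param repeats Number of repetitions (default 10).
#' @param seed Master seed driving fold assignment and model fits.
#' @return A `circ_cv` object: `$folds` (one row per fold with
#'   confusion counts and metrics), `$repeat_means`, `$summary` (grand
#'   mean, one row), `$roc`, `$pr`, `$auc`, plus protocol metadata.
#' @export
repeated_kfold_cv <- function(features, algorithm = "rf", k = 10L,
                              repeats = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (!"label" %in% names(features)) stop("`features` must have a `label` column")
  y <- features$label
  class_n <- table(y)
  if (length(class_n) < 2) stop("both classes must be present")
  if (any(class_n < k)) {
    stop("stratified ", k, "-fold CV needs >= ", k,
         " records per class (have ", paste(class_n, collapse = "/"), ")",
         call. = FALSE)
  }
  metric_cols <- c("recall", "precision", "accuracy", "f1", "mcc")
  withr::with_seed(seed, {
    fold_rows <- list()
    score_rows <- list()
    for (r in seq_len(repeats)) {
      fold_of <- integer(nrow(features))
      for (cl in names(class_n)) {
        idx <- which(y == cl)
        fold_of[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
      for (f in seq_len(k)) {
        hold <- fold_of == f
        model <- train_classifier(features[!hold, ], algorithm, seed = NULL)
        pred <- predict(model, features[hold, ])
        pred_lab <- ifelse(pred$score >= 0.5, "positive", "negative")
        cc <- confusion_counts(y[hold], pred_lab)
        fold_rows[[length(fold_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(repeat_ = r, fold = f), compute_metrics(cc))
        score_rows[[length(score_rows) + 1L]] <- tibble::tibble(
          repeat_ = r, id = pred$id, truth = y[hold], score = pred$score)
      }
    }
    folds <- dplyr::bind_rows(fold_rows)
    scores <- dplyr::bind_rows(score_rows)
    repeat_means <- folds |>
      dplyr::group_by(.data$repeat_) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean),
                       .groups = "drop")
    summary <- repeat_means |>
      dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols), mean))
    structure(list(
      folds = folds,
      repeat_means = repeat_means,
      summary = summary,
      scores = scores,
      roc = compute_roc(scores$truth, scores$score),
      pr = compute_pr(scores$truth, scores$score),
      auc = roc_auc(scores$truth, scores$score),
      algorithm = algorithm, k = k, repeats = repeats, seed = seed,
      n = nrow(features)
    ), class = "circ_cv")
  })
}

#' @export
print.circ_cv <- function(x, ...) {
  cat("<circ_cv>", x$repeats, "x", x$k, "-fold stratified CV,",
      x$algorithm, "on", x$n, "records (seed", paste0(x$seed, ")\n"))
  s <- x$summary
  cat(sprintf("  accuracy %.4f | precision %.4f | recall %.4f | F1 %.4f | MCC %.4f | AUC %.4f\n",
              s$accuracy, s$precision, s$recall, s$f1, s$mcc, x$auc))
  invisible(x)
}

BLOCK_LETTERS <- c(kmer = "K", sjsc = "J", orf = "O")

#' Cross-validated comparison of feature-block combinations
#'
#' Evaluates every non-empty combination of the feature blocks present
#' in `features` (7 combinations when all of k-mers `K`, SJSC `J` and
#' ORFs `O` are available), for each requested algorithm, using
#' [repeated_kfold_cv()] with a shared seed so all cells see the same
#' fold structure.
#'
#' @param features Labeled feature tibble containing one or more
#'   blocks.
#' @param algorithms Subset of `c("rf", "knn", "gnb", "svm")`.
#' @param k,repeats,seed CV protocol, as in [repeated_kfold_cv()].
#' @return A `circ_grid` tibble: `combination` (e.g. `"K+O"`),
#'   `algorithm`, `n_features`, the five mean metrics and `auc`, sorted
#'   by decreasing accuracy.
#' @export
feature_combination_grid <- function(features, algorithms = "rf", k = 10L,
                                     repeats = 10L, seed = 1L) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  cols <- feature_block_columns(features)
  present <- intersect(c("kmer", "sjsc", "orf"),  # K, J, O label order
                       names(cols)[lengths(cols) > 0])
  if (!length(present)) stop("no feature blocks found in `features`")
  combos <- unlist(lapply(seq_along(present), function(m) {
    utils::combn(present, m, simplify = FALSE)
  }), recursive = FALSE)
  lead_cols <- intersect(c("id", "label"), names(features))
  rows <- list()
  for (combo in combos) {
    feat_cols <- unlist(cols[combo], use.names = FALSE)
    sub <- features[c(lead_cols, feat_cols)]
    for (alg in algorithms) {
      cv <- repeated_kfold_cv(sub, alg, k = k, repeats = repeats,
                              seed = seed)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          combination = paste(BLOCK_LETTERS[combo], collapse = "+"),
          algorithm = alg, n_features = length(feat_cols)),
        cv$summary, tibble::tibble(auc = cv$auc))
    }
  }
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(dplyr::desc(.data$accuracy))
  class(out) <- c("circ_grid", class(out))
  out
}
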
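#' Tidy a cross-validation result
#'
#' One row per held-out fold, with confusion counts and the five
#' metrics.
#'
#' @param x A `circ_cv` from [repeated_kfold_cv()].
#' @param ... Unused.
#' @return Tibble with columns `repeat_`, `fold`, `tp`, `fp`, `tn`,
#'   `fn`, `recall`, `precision`, `accuracy`, `f1`, `mcc`.
#' @method tidy circ_cv
#' @export
tidy.circ_cv <- function(x, ...) x$folds

#' Glance at a cross-validation result
#'
#' @param x A `circ_cv`.
#' @param ... Unused.
#' @return One-row tibble: grand-mean metrics, `auc`, and the protocol
#'   (`algorithm`, `k`, `repeats`, `n`, `seed`).
#' @method glance circ_cv
#' @export
glance.circ_cv <- function(x, ...) {
  dplyr::bind_cols(
    x$summary,
    tibble::tibble(auc = x$auc, algorithm = x$algorithm, k = x$k,
                   repeats = x$repeats, n = x$n, seed = x$seed)
  )
}

#' Tidy a trained model
#'
#' For random forests, one row per feature with its mean decrease in
#' Gini importance; for the other algorithms, one row per
#' hyperparameter.
#'
#' @param x A `circ_model` from [train_classifier()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy circ_model
#' @export
tidy.circ_model <- function(x, ...) {
  if (x$algorithm == "rf") {
    imp <- randomForest::importance(x$fit)
    tibble::tibble(term = rownames(imp),
                   importance = as.numeric(imp[, 1])) |>
      dplyr::arrange(dplyr::desc(.data$importance))
  } else {
    tibble::tibble(term = names(x$hyperparameters),
                   value = as.character(unlist(x$hyperparameters)))
  }
}

#' Glance at a trained model
#'
#' @param x A `circ_model`.
#' @param ... Unused.
#' @return One-row tibble: `algorithm`, `n_features`, `n_train`,
#'   `n_positive`, `n_negative`, `version`.
#' @method glance circ_model
#' @export
glance.circ_model <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_features = length(x$feature_schema),
    n_train = sum(x$n_train),
    n_positive = x$n_train[["positive"]],
    n_negative = x$n_train[["negative"]],
    version = x$version
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
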
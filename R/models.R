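#' Ordinary least squares fit
#'
#' Plain OLS via QR, as used for all k-feature entropy models.
#'
#' @param x Numeric matrix or data frame of predictor columns (no intercept
#'   column; one is added).
#' @param y Numeric response.
#' @return A list: `intercept`, `coefficients` (named), `rss`, `fitted`.
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) <= ncol(x) + 1L) {
    rlang::abort("Need more observations than parameters for OLS.")
  }
  X <- cbind(`(Intercept)` = 1, x)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    rlang::abort(paste0("Rank-deficient design; collinear column(s): ",
                        paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  list(intercept = unname(beta[1]),
       coefficients = beta[-1],
       rss = sum((y - fitted)^2),
       fitted = fitted)
}

#' Gaussian-likelihood Bayesian information criterion
#'
#' `n * log(RSS / n) + (p + 2) * log(n)`, counting the intercept and the
#' error variance among the parameters. Lower is better.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_obs Number of observations.
#' @param p Number of predictor features (excluding intercept).
#' @return The BIC value; `-Inf` with a warning when `rss` is exactly 0.
#' @export
bic_score <- function(rss, n_obs, p) {
  stopifnot(n_obs > p + 2)
  if (rss == 0) {
    rlang::warn("RSS is exactly 0; BIC is -Inf.")
    return(-Inf)
  }
  n_obs * log(rss / n_obs) + (p + 2) * log(n_obs)
}

#' Seeded cross-validation fold assignment
#'
#' Uniform random permutation into `n_folds` folds whose sizes differ by at
#' most one; deterministic given the seed.
#'
#' @param n Number of observations.
#' @param n_folds Number of folds. Default 5.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..n_folds`.
#' @export
cv_folds <- function(n, n_folds = 5, seed = 1) {
  stopifnot(n >= n_folds)
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(n_folds), n))
}

#' Cross-validated predictive power of one feature subset
#'
#' Fits the subset's OLS model on each training split, predicts the held-out
#' fold, and scores the Pearson correlation between predicted and measured
#' entropy per fold; the mean of the fold PCCs is the model's predictive
#' power. Reported coefficients come from a final fit on all data. A fold
#' whose predictions have zero variance scores PCC 0 with a warning.
#'
#' @param data Data frame holding the response and feature columns.
#' @param response Name of the response column.
#' @param features Character vector of feature column names.
#' @param n_folds,seed Passed to [cv_folds()] (or supply `folds` directly).
#' @param folds Optional explicit fold assignment.
#' @return A one-row tibble (class `tss_model` rowset): `features`
#'   (list-column), `k`, `intercept`, `coefficients` (list-column),
#'   `fold_pcc` (list-column), `mean_pcc`, `bic`, `n_obs`.
#' @export
cv_pcc <- function(data, response, features, n_folds = 5, seed = 1, folds = NULL) {
  y <- data[[response]]
  X <- as.matrix(data[features])
  if (is.null(folds)) folds <- cv_folds(nrow(X), n_folds, seed)
  pccs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fit_ols(X[tr, , drop = FALSE], y[tr])
    pred <- drop(cbind(1, X[!tr, , drop = FALSE]) %*% c(fit$intercept, fit$coefficients))
    if (stats::sd(pred) == 0 || stats::sd(y[!tr]) == 0) {
      rlang::warn("Zero-variance predictions in a fold; PCC set to 0.")
      0
    } else {
      stats::cor(pred, y[!tr])
    }
  }, numeric(1))
  full <- fit_ols(X, y)
  n_feat <- length(features)
  tibble::tibble(
    features = list(features),
    k = n_feat,
    intercept = full$intercept,
    coefficients = list(full$coefficients),
    fold_pcc = list(pccs),
    mean_pcc = mean(pccs),
    bic = bic_score(full$rss, nrow(X), ncol(X)),
    n_obs = nrow(X)
  )
}

#' Enumerate and rank k-feature linear models
#'
#' Evaluates every size-`k` feature subset by cross-validated PCC (see
#' [cv_pcc()]) when the subset count is within `cap`, otherwise falls back to
#' a greedy forward beam search (width `beam`) with a message. `k = "full"`
#' evaluates the single model using every feature. Results are ranked by mean
#' CV PCC (descending), ties broken by smaller BIC then lexicographic feature
#' names.
#'
#' @inheritParams cv_pcc
#' @param features Feature columns to draw subsets from; defaults to every
#'   column except the response and `promoter_id`.
#' @param k Subset size (integer) or `"full"`.
#' @param cap Maximum number of subsets enumerated exhaustively. Default
#'   2e5.
#' @param strategy `"auto"` (cap decides), `"exhaustive"` or `"greedy"`.
#' @param beam Beam width of the greedy search. Default 20.
#' @return A `tss_models` tibble, one row per evaluated model.
#' @export
enumerate_models <- function(data, response, features = NULL, k = 1,
                             n_folds = 5, seed = 1, cap = 2e5,
                             strategy = c("auto", "exhaustive", "greedy"),
                             beam = 20) {
  strategy <- match.arg(strategy)
  if (is.null(features)) {
    features <- setdiff(names(data), c(response, "promoter_id"))
  }
  if (identical(k, "full")) k <- length(features)
  k <- as.integer(k)
  if (k > length(features)) rlang::abort("`k` exceeds the number of features.")
  folds <- cv_folds(nrow(data), n_folds, seed)
  n_subsets <- choose(length(features), k)
  use_greedy <- strategy == "greedy" || (strategy == "auto" && n_subsets > cap)
  subsets <- if (!use_greedy) {
    utils::combn(features, k, simplify = FALSE)
  } else {
    rlang::inform(sprintf(
      "C(%d, %d) = %.3g subsets exceeds cap; using greedy forward beam search (width %d).",
      length(features), k, n_subsets, beam))
    greedy_subsets(data, response, features, k, folds, beam)
  }
  results <- purrr::map(subsets, function(s) {
    cv_pcc(data, response, s, folds = folds)
  }) |>
    dplyr::bind_rows()
  rank_models(results)
}

rank_models <- function(results) {
  key <- purrr::map_chr(results$features, ~ paste(sort(.x), collapse = "|"))
  out <- results[order(-results$mean_pcc, results$bic, key), ]
  class(out) <- c("tss_models", class(out))
  out
}

greedy_subsets <- function(data, response, features, k, folds, beam) {
  frontier <- list(character(0))
  for (step in seq_len(k)) {
    cand <- unique(unlist(purrr::map(frontier, function(s) {
      purrr::map(setdiff(features, s), ~ sort(c(s, .x)))
    }), recursive = FALSE))
    cand <- unique(cand)
    scores <- purrr::map_dbl(cand, function(s) {
      cv_pcc(data, response, s, folds = folds)$mean_pcc
    })
    frontier <- cand[order(-scores)][seq_len(min(beam, length(cand)))]
  }
  frontier
}

#' @export
print.tss_models <- function(x, n = 5, ...) {
  cat(sprintf("<tss_models> %d model(s), k = %s\n", nrow(x),
              paste(sort(unique(x$k)), collapse = ",")))
  top <- utils::head(x, n)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %s: mean CV PCC %.3f, BIC %.1f\n",
                paste(top$features[[i]], collapse = " + "),
                top$mean_pcc[i], top$bic[i]))
  }
  if (nrow(x) > n) cat(sprintf("  ... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' @rdname enumerate_models
#' @param x A `tss_models` tibble.
#' @param ... Unused.
#' @export
tidy.tss_models <- function(x, ...) {
  x |>
    dplyr::mutate(model_rank = dplyr::row_number()) |>
    dplyr::select("model_rank", "k", "features", "intercept", "coefficients",
                  "mean_pcc", "bic") |>
    dplyr::mutate(term = purrr::map(.data$coefficients, names)) |>
    tidyr::unnest(c("term", "coefficients")) |>
    dplyr::select("model_rank", "k", "term", estimate = "coefficients",
                  "intercept", "mean_pcc", "bic")
}

#' @rdname enumerate_models
#' @export
glance.tss_models <- function(x, ...) {
  best <- x[1, ]
  tibble::tibble(
    n_models = nrow(x),
    k = best$k,
    best_features = paste(best$features[[1]], collapse = "+"),
    best_mean_pcc = best$mean_pcc,
    best_bic = best$bic,
    n_obs = best$n_obs
  )
}

#' Filter models by predictive power
#'
#' Keeps models whose mean CV PCC exceeds the threshold (default 0.1), the
#' working definition of a "best model".
#'
#' @param results A `tss_models` tibble.
#' @param pcc_threshold Strict lower bound on mean CV PCC. Default 0.1.
#' @return The filtered `tss_models` tibble (possibly empty).
#' @export
best_models <- function(results, pcc_threshold = 0.1) {
  stopifnot(nrow(results) >= 1)
  results[results$mean_pcc > pcc_threshold, ]
}

#' Feature-type composition of a model set
#'
#' For each model-size class, the fraction of feature selections per feature
#' type (HM / NU / SEQ / DNase).
#'
#' @param results A `tss_models` tibble (typically after [best_models()]).
#' @param feature_info Tibble mapping `feature` to `type`.
#' @return A tibble: `k`, `type`, `n_selected`, `fraction`.
#' @export
feature_composition <- function(results, feature_info) {
  sel <- tibble::tibble(
    k = rep(results$k, lengths(results$features)),
    feature = unlist(results$features)
  ) |>
    dplyr::left_join(feature_info[c("feature", "type")], by = "feature")
  sel |>
    dplyr::count(.data$k, .data$type, name = "n_selected") |>
    dplyr::mutate(fraction = .data$n_selected / sum(.data$n_selected), .by = "k")
}

#' Apply a trained model to another dataset
#'
#' Predicts with frozen coefficients and reports the Pearson correlation with
#' the other dataset's measured entropy (cross-cell-type transfer).
#'
#' @param model A one-row slice of a `tss_models` tibble.
#' @param data Data frame holding the model's feature columns.
#' @param response Name of the response column in `data`.
#' @return The transfer PCC (single numeric).
#' @export
transfer_evaluate <- function(model, data, response) {
  stopifnot(nrow(model) == 1)
  feats <- model$features[[1]]
  missing <- setdiff(feats, names(data))
  if (length(missing)) {
    rlang::abort(paste0("Feature column(s) absent from the target data: ",
                        paste(missing, collapse = ", ")))
  }
  pred <- drop(as.matrix(data[feats]) %*% model$coefficients[[1]]) + model$intercept
  stats::cor(pred, data[[response]])
}

#' ROC analysis of narrow-vs-broad promoter classification
#'
#' Sweeps a threshold over predicted entropies, treating "broad" as the
#' positive class, and reports TPR/FPR per threshold plus the trapezoidal
#' AUC.
#'
#' @param predicted Numeric vector of predicted entropies (higher = broader).
#' @param labels Character/factor vector of `"narrow"` / `"broad"` labels.
#' @return A tibble of class `tss_roc`: `threshold`, `tpr`, `fpr`; the AUC is
#'   in `attr(, "auc")` and via [glance()].
#' @export
roc_classification <- function(predicted, labels) {
  labels <- as.character(labels)
  stopifnot(length(predicted) == length(labels),
            all(labels %in% c("narrow", "broad")))
  pos <- labels == "broad"
  if (all(pos) || !any(pos)) {
    rlang::abort("Both classes must be present for an ROC analysis.")
  }
  thr <- c(Inf, sort(unique(predicted), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(predicted[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(predicted[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr)
  class(out) <- c("tss_roc", class(out))
  attr(out, "auc") <- auc
  out
}

#' @rdname roc_classification
#' @param x A `tss_roc` tibble.
#' @param ... Unused.
#' @export
glance.tss_roc <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_points = nrow(x))
}

#' Narrow/broad labels from true sigma
#'
#' In synthetic mode the ground-truth shape class derives from the true
#' sigma: narrow when `sigma_true <= sigma_cut` (default 10 bp), broad
#' otherwise.
#'
#' @param truth Truth tibble with a `sigma_true` column.
#' @param sigma_cut Narrow/broad boundary in bp. Default 10.
#' @return Character vector of `"narrow"` / `"broad"`.
#' @export
label_promoters <- function(truth, sigma_cut = 10) {
  ifelse(truth$sigma_true <= sigma_cut, "narrow", "broad")
}
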
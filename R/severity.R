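# Gradient-boosted disease-probability score with repeated stratified
# cross-validation for hyperparameter selection, and its correlation with
# clinical severity scales.

# Stratified fold assignment: each class is split evenly across folds.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

log_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Cross-validated gradient-boosted disease score
#'
#' Selects gradient-boosting hyperparameters (trees in {50, 100, 200},
#' depth in {1, 2, 3}, learning rate 0.1) by mean log-loss over repeated
#' stratified threefold cross-validation, then produces out-of-fold
#' disease-probability scores from the selected configuration, so no
#' sample is scored by a model that saw its label.
#'
#' @param seed integer seed (fold assignments and model fitting).
#' @param features samples x features numeric matrix (e.g. VST values at
#'   called regions).
#' @param labels per-sample group labels; `"SCZ"` is the positive class.
#' @param folds number of CV folds (default 3).
#' @param repeats CV repeats for hyperparameter selection (default 10).
#' @param grid data.frame with `nrounds`, `max_depth`, `eta`.
#' @return list of class `severity_scores`: `scores` (named, in `[0, 1]`),
#'   `fold` (out-of-fold assignment), `config` (chosen hyperparameters),
#'   `cv` (per-config mean log-loss).
#' @export
fit_boosted_score <- function(seed, features, labels, folds = 3L,
                              repeats = 10L,
                              grid = expand.grid(
                                nrounds = c(50L, 100L, 200L),
                                max_depth = 1:3, eta = 0.1
                              )) {
  y <- as.numeric(labels == "SCZ")
  if (length(unique(y)) < 2L) stop("labels must contain both classes")
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(y))
  train_predict <- function(tr, te, cfg) {
    dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    bst <- xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", max_depth = cfg$max_depth,
        eta = cfg$eta, nthread = 1L
      ),
      data = dtrain, nrounds = cfg$nrounds, verbose = 0
    )
    stats::predict(bst, xgboost::xgb.DMatrix(X[te, , drop = FALSE]))
  }
  with_seed(seed, {
    cv_loss <- matrix(NA_real_, nrow(grid), repeats)
    for (r in seq_len(repeats)) {
      fold <- stratified_folds(y, folds)
      for (g in seq_len(nrow(grid))) {
        pred <- numeric(length(y))
        for (f in seq_len(folds)) {
          te <- fold == f
          pred[te] <- train_predict(which(!te), which(te), grid[g, ])
        }
        cv_loss[g, r] <- log_loss(y, pred)
      }
    }
    mean_loss <- rowMeans(cv_loss)
    best <- which.min(mean_loss)
    cfg <- grid[best, ]
    fold <- stratified_folds(y, folds)
    scores <- numeric(length(y))
    for (f in seq_len(folds)) {
      te <- fold == f
      scores[te] <- train_predict(which(!te), which(te), cfg)
    }
    names(scores) <- rownames(X)
    structure(
      list(
        scores = scores, fold = fold, config = cfg,
        cv = data.frame(grid, mean_logloss = mean_loss)
      ),
      class = "severity_scores"
    )
  })
}

#' @export
print.severity_scores <- function(x, ...) {
  cat(sprintf(
    "boosted disease scores: %d samples, chosen %d trees, depth %d, eta %.2f\n",
    length(x$scores), x$config$nrounds, x$config$max_depth, x$config$eta
  ))
  invisible(x)
}

#' Correlate disease scores with clinical scales
#'
#' Spearman correlation (two-sided, t approximation) of the per-sample
#' disease-probability score with each supplied clinical scale.
#'
#' @param scores named numeric scores.
#' @param clinical data.frame of clinical scales, rownames or `id` column
#'   matching the score names.
#' @return data.frame: `scale, rho, p, n`.
#' @export
correlate_severity <- function(scores, clinical) {
  if (!is.null(clinical$id)) {
    rownames(clinical) <- clinical$id
    clinical$id <- NULL
  }
  shared <- intersect(names(scores), rownames(clinical))
  if (length(shared) < 3L) stop("need at least 3 paired samples")
  rows <- lapply(names(clinical), function(sc) {
    v <- clinical[shared, sc]
    ok <- is.finite(v)
    if (sum(ok) < 3L) stop("need at least 3 paired values per scale")
    ct <- suppressWarnings(stats::cor.test(
      scores[shared][ok], v[ok],
      method = "spearman", exact = FALSE
    ))
    data.frame(
      scale = sc, rho = unname(ct$estimate), p = ct$p.value, n = sum(ok),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
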
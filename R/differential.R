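# Differential-region engine: median-of-ratios size factors, per-window
# method-of-moments dispersion blended with a 1/mu trend, covariate-adjusted
# negative-binomial GLM fits with Wald tests, calling thresholds, a simple
# variance-stabilizing transform, correlation-distance clustering, and the
# noncentral-t region power computation.

ALPHA_MIN <- 1e-8

#' Median-of-ratios size factors
#'
#' `s_j = median_i K_ij / geomean_i` over windows whose counts are positive
#' in every sample, the standard library-size normalization for
#' overdispersed count matrices.
#'
#' @param K windows x samples count matrix.
#' @return per-sample numeric size factors.
#' @export
size_factors <- function(K) {
  logK <- log(K)
  ok <- rowSums(!is.finite(logK)) == 0L
  if (!any(ok)) {
    stop("no window has positive counts in all samples; cannot normalize")
  }
  loggm <- rowMeans(logK[ok, , drop = FALSE])
  s <- apply(logK[ok, , drop = FALSE], 2L, function(col) {
    exp(stats::median(col - loggm))
  })
  unname(s)
}

#' Per-window NB dispersion with trend blending
#'
#' Method-of-moments dispersion on normalized counts,
#' `alpha_hat = max((var - mean) / mean^2, alpha_min)`, blended with a
#' robust `a1/mu + a0` trend fitted across windows: the final estimate is
#' the geometric mean of the window estimate and the trend value at the
#' window's mean, clamped below at `alpha_min`. With fewer than 20 windows
#' the trend is skipped with a warning and raw method-of-moments estimates
#' are returned.
#'
#' @param K windows x samples count matrix.
#' @param s per-sample size factors.
#' @return numeric vector of per-window dispersions.
#' @export
estimate_dispersion <- function(K, s) {
  Q <- sweep(K, 2L, s, "/")
  mu <- rowMeans(Q)
  v <- apply(Q, 1L, stats::var)
  raw <- unname(pmax((v - mu) / mu^2, ALPHA_MIN))
  if (nrow(K) < 20L) {
    warning("fewer than 20 windows; returning raw method-of-moments dispersions")
    return(raw)
  }
  # robust (Huber-weighted) least squares of alpha_hat on 1/mu
  use <- is.finite(raw) & mu > 0
  x <- 1 / mu[use]
  y <- raw[use]
  w <- rep(1, length(y))
  a <- c(stats::median(y), 0)
  for (it in 1:20) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    a_new <- unname(fit$coefficients)
    a_new[is.na(a_new)] <- 0
    r <- drop(y - cbind(1, x) %*% a_new)
    sc <- stats::median(abs(r)) / 0.6745
    if (sc <= 0) sc <- stats::sd(r)
    k <- 1.345 * sc
    w <- ifelse(abs(r) <= k, 1, k / abs(r))
    if (max(abs(a_new - a)) < 1e-10) {
      a <- a_new
      break
    }
    a <- a_new
  }
  trend <- pmax(a[1] + a[2] / mu, ALPHA_MIN)
  unname(pmax(sqrt(raw * trend), ALPHA_MIN))
}

# IRLS fit of one NB GLM row with log link, fixed dispersion and offset
# log(s). Returns natural-log coefficients, covariance of beta, mu, and a
# convergence flag.
nb_irls <- function(y, X, offset, alpha, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- tryCatch(
    stats::qr.solve(X, log(pmax(y, 0.5)) - offset),
    error = function(e) rep(0, p)
  )
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    H <- XtW %*% X
    beta_new <- tryCatch(
      drop(solve(H, XtW %*% z)),
      error = function(e) NULL
    )
    if (is.null(beta_new) || any(!is.finite(beta_new))) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  H <- t(X * w) %*% X
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p, p))
  list(beta = beta, cov = cov, mu = mu, converged = converged)
}

#' Fit one window's negative-binomial GLM
#'
#' Maximizes the NB log-likelihood with log link, fixed dispersion and
#' offset `log(s_j)` by iteratively reweighted least squares; standard
#' errors come from observed Fisher information. Coefficients are reported
#' on the log2 scale.
#'
#' @param y integer counts for one window.
#' @param design model matrix (full column rank), group coefficient
#'   identified by `coef`.
#' @param s per-sample size factors.
#' @param alpha NB dispersion for this window.
#' @param coef name or index of the coefficient of interest (default
#'   `"group"`).
#' @return list with `log2fc`, `lfcSE` (log2 scale), `beta` (all natural-log
#'   coefficients), `base_mean` (mean normalized count), `converged`.
#' @export
fit_nb_glm <- function(y, design, s, alpha, coef = "group") {
  stopifnot(length(y) == nrow(design), length(s) == nrow(design))
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  fit <- nb_irls(y, design, log(s), alpha)
  j <- if (is.character(coef)) match(coef, colnames(design)) else coef
  if (is.na(j)) stop(sprintf("coefficient '%s' not in design", coef))
  se_ln <- sqrt(fit$cov[j, j])
  list(
    log2fc = unname(fit$beta[j]) / log(2),
    lfcSE = unname(se_ln) / log(2),
    beta = unname(fit$beta),
    base_mean = mean(y / s),
    converged = fit$converged && is.finite(se_ln) && se_ln > 0
  )
}

#' Wald test for a log2 fold change
#'
#' @param log2fc estimated log2 fold change.
#' @param lfcSE its standard error (> 0), log2 scale.
#' @return two-sided p-value `2 * (1 - Phi(|log2fc / lfcSE|))`.
#' @export
wald_test <- function(log2fc, lfcSE) {
  if (any(lfcSE <= 0, na.rm = TRUE)) stop("lfcSE must be positive")
  2 * stats::pnorm(-abs(log2fc / lfcSE))
}

#' Build the design matrix for the differential model
#'
#' Intercept, SCZ group indicator, standardized age, gender indicator and —
#' for 5mC only — treatment-coded batch indicators (reference level is the
#' lexicographically first batch).
#'
#' @param cohort a `cohort_design` (or data.frame with `group, age, gender,
#'   batch`).
#' @param modality `"5mC"` (with batch) or `"5hmC"` (without).
#' @return numeric model matrix with a `group` column.
#' @export
design_matrix <- function(cohort, modality = c("5mC", "5hmC")) {
  modality <- match.arg(modality)
  X <- cbind(
    intercept = 1,
    group = as.numeric(cohort$group == "SCZ"),
    age = as.numeric(scale(cohort$age)),
    gender = as.numeric(cohort$gender == "M")
  )
  if (modality == "5mC") {
    bt <- factor(cohort$batch, levels = sort(unique(cohort$batch)))
    if (nlevels(bt) > 1L) {
      B <- stats::model.matrix(~bt)[, -1L, drop = FALSE]
      colnames(B) <- paste0("batch_", levels(bt)[-1L])
      X <- cbind(X, B)
    }
  }
  rownames(X) <- cohort$id
  X
}

#' Differential-region analysis of a count matrix
#'
#' Runs the full engine: size factors, trended dispersion, per-window NB
#' GLM fits, Wald tests and calling at the p-value and |log2FC| thresholds,
#' plus the per-region power at the study's power-analysis significance
#' level.
#'
#' @param K windows x samples count matrix (raw counts).
#' @param design model matrix from [design_matrix()].
#' @param p_thresh calling p-value threshold (default 5e-4).
#' @param lfc_thresh calling |log2FC| threshold (default 0.5).
#' @param power_alpha significance level for the power column (default
#'   0.005).
#' @param adjust also report BH-adjusted p-values (calling still uses raw
#'   p, matching the thresholding convention).
#' @return data.frame with one row per window: `window, base_mean, log2fc,
#'   lfcSE, pvalue, padj, call, power, dispersion, converged`.
#' @export
diff_regions <- function(K, design, p_thresh = 5e-4, lfc_thresh = 0.5,
                         power_alpha = 0.005, adjust = TRUE) {
  s <- size_factors(K)
  alpha <- estimate_dispersion(K, s)
  n1 <- sum(design[, "group"] == 0)
  n2 <- sum(design[, "group"] == 1)
  n_win <- nrow(K)
  log2fc <- lfcSE <- base_mean <- numeric(n_win)
  converged <- logical(n_win)
  off <- log(s)
  for (i in seq_len(n_win)) {
    fit <- nb_irls(K[i, ], design, off, alpha[i])
    se_ln <- sqrt(fit$cov[2L, 2L])
    log2fc[i] <- fit$beta[2L] / log(2)
    lfcSE[i] <- se_ln / log(2)
    base_mean[i] <- mean(K[i, ] / s)
    converged[i] <- fit$converged && is.finite(se_ln) && se_ln > 0
  }
  pvalue <- rep(NA_real_, n_win)
  pvalue[converged] <- wald_test(log2fc[converged], lfcSE[converged])
  res <- data.frame(
    window = rownames(K) %||% sprintf("w%06d", seq_len(n_win)),
    base_mean = base_mean, log2fc = log2fc, lfcSE = lfcSE,
    pvalue = pvalue,
    padj = if (adjust) stats::p.adjust(pvalue, "BH") else NA_real_,
    dispersion = alpha, converged = converged,
    stringsAsFactors = FALSE
  )
  res$call <- call_regions(res, p_thresh, lfc_thresh)
  res$power <- region_power(
    ifelse(is.finite(res$lfcSE) & res$lfcSE > 0,
      abs(res$log2fc) / res$lfcSE, 0
    ),
    n1, n2, power_alpha
  )
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label windows as hyper, hypo or none
#'
#' `hyper` when `pvalue < p_thresh` and `log2fc > lfc_thresh`; `hypo` when
#' `pvalue < p_thresh` and `log2fc < -lfc_thresh`; otherwise `none`.
#' Non-converged fits are never called.
#'
#' @param results data.frame with `pvalue`, `log2fc` (and optionally
#'   `converged`).
#' @param p_thresh,lfc_thresh calling thresholds.
#' @return character vector of calls.
#' @export
call_regions <- function(results, p_thresh = 5e-4, lfc_thresh = 0.5) {
  ok <- !is.na(results$pvalue)
  if (!is.null(results$converged)) ok <- ok & results$converged
  out <- rep("none", nrow(results))
  out[ok & results$pvalue < p_thresh & results$log2fc > lfc_thresh] <- "hyper"
  out[ok & results$pvalue < p_thresh & results$log2fc < -lfc_thresh] <- "hypo"
  out
}

#' Variance-stabilizing transform of normalized counts
#'
#' `log2(K_ij / s_j + 1)`, a monotone transform of normalized counts used
#' for clustering and QC.
#'
#' @param K count matrix.
#' @param s per-sample size factors.
#' @return transformed matrix of the same shape.
#' @export
vst_counts <- function(K, s = size_factors(K)) {
  log2(sweep(K, 2L, s, "/") + 1)
}

#' Cluster samples on called regions
#'
#' Average-linkage hierarchical clustering of samples on
#' `1 - Pearson correlation` distance over the supplied (transformed)
#' region submatrix, cut into two groups.
#'
#' @param x regions x samples matrix (e.g. VST values at called regions),
#'   at least 2 rows.
#' @param k number of cluster labels to return (default 2).
#' @return list with `hclust` and `labels` (named cluster assignment).
#' @export
cluster_samples <- function(x, k = 2L) {
  if (nrow(x) < 2L) stop("need at least 2 called regions to cluster")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) stop("constant sample column; correlation distance undefined")
  d <- stats::as.dist(1 - stats::cor(x))
  hc <- stats::hclust(d, method = "average")
  list(hclust = hc, labels = stats::cutree(hc, k = k))
}

#' Two-sample t-test power at a standardized effect size
#'
#' Power of the two-sided two-sample t-test with noncentrality
#' `d * sqrt(n1 * n2 / (n1 + n2))` and `n1 + n2 - 2` degrees of freedom.
#' At `d = 0` the power equals `alpha` exactly. The effect size used for
#' region power is the Wald ratio `|log2FC| / lfcSE`.
#'
#' @param d standardized effect size(s), >= 0.
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level (default 0.005 for regions).
#' @return power in `[0, 1]`, vectorized over `d`.
#' @export
region_power <- function(d, n1, n2, alpha = 0.005) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n1 < 2L || n2 < 2L) stop("group sizes must be at least 2")
  if (any(d < 0)) stop("effect size must be non-negative")
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  out <- stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  out[d == 0] <- alpha # the null case analytically
  out
}
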
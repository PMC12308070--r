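# Brain structural-measure association: covariate residualization,
# group-difference testing and the all-pairs Spearman screen.

#' Residualize values against covariates
#'
#' Ordinary-least-squares residuals of `values` on the covariate matrix
#' (an intercept is always included), with the median of the raw values
#' added back so the adjusted scores stay on the original scale.
#'
#' @param values numeric vector or samples x variables matrix.
#' @param covariates numeric matrix/data.frame of covariates (full rank).
#' @param add_back_median add the raw median back to residuals (default
#'   TRUE).
#' @return adjusted values with the same shape.
#' @export
residualize <- function(values, covariates, add_back_median = TRUE) {
  X <- cbind(intercept = 1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient")
  one <- function(y) {
    r <- qr.resid(qx, y)
    if (add_back_median) r + stats::median(y) else r
  }
  if (is.matrix(values)) {
    out <- apply(values, 2L, one)
    dimnames(out) <- dimnames(values)
    out
  } else {
    one(values)
  }
}

#' Residualize brain measures with class-specific covariates
#'
#' Cortical thickness (CT) is adjusted for age and gender only; volume and
#' area classes (CV, SA, SV) additionally for intracranial volume. Region
#' modification values are adjusted for age and gender.
#'
#' @param measures samples x measures matrix.
#' @param classes per-measure class in `{CT, CV, SA, SV}`.
#' @param covariates data.frame with `age`, `gender` (`"F"`/`"M"`), `icv`
#'   for the same samples.
#' @return adjusted matrix.
#' @export
residualize_measures <- function(measures, classes, covariates) {
  stopifnot(length(classes) == ncol(measures))
  base <- cbind(
    age = covariates$age,
    gender = as.numeric(covariates$gender == "M")
  )
  with_icv <- cbind(base, icv = covariates$icv)
  out <- measures
  is_ct <- classes == "CT"
  if (any(is_ct)) {
    out[, is_ct] <- residualize(measures[, is_ct, drop = FALSE], base)
  }
  if (any(!is_ct)) {
    out[, !is_ct] <- residualize(measures[, !is_ct, drop = FALSE], with_icv)
  }
  out
}

#' Per-measure group-difference test
#'
#' Two-sided rank-sum test per measure with BH adjustment across measures
#' and the direction of the difference (sign of the SCZ minus HC median).
#' Constant measures get `p = 1` with a warning.
#'
#' @param measures samples x measures matrix (already residualized).
#' @param groups per-sample labels, `"HC"`/`"SCZ"`.
#' @param fdr significance threshold on the adjusted p (default 0.05).
#' @return data.frame: `measure, statistic, p, padj, direction,
#'   significant`.
#' @export
group_difference <- function(measures, groups, fdr = 0.05) {
  scz <- groups == "SCZ"
  if (sum(scz) < 2L || sum(!scz) < 2L) stop("each group needs >= 2 samples")
  nm <- colnames(measures) %||% sprintf("m%03d", seq_len(ncol(measures)))
  stat <- p <- dir <- numeric(ncol(measures))
  for (j in seq_len(ncol(measures))) {
    y <- measures[, j]
    if (stats::sd(y) == 0) {
      warning(sprintf("measure '%s' is constant; p set to 1", nm[j]))
      stat[j] <- NA_real_
      p[j] <- 1
      dir[j] <- 0
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(
      y[scz], y[!scz],
      exact = FALSE, correct = FALSE
    ))
    stat[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
    dir[j] <- sign(stats::median(y[scz]) - stats::median(y[!scz]))
  }
  padj <- stats::p.adjust(p, "BH")
  data.frame(
    measure = nm, statistic = stat, p = p, padj = padj,
    direction = dir, significant = padj < fdr,
    stringsAsFactors = FALSE
  )
}

# Spearman rho matrix between the columns of two matrices sharing rows,
# with the t-approximation p-value (standard for n > ~10).
spearman_matrix <- function(A, B) {
  n <- nrow(A)
  RA <- apply(A, 2L, rank)
  RB <- apply(B, 2L, rank)
  rho <- stats::cor(RA, RB)
  rho_c <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tt <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  list(rho = rho, p = p)
}

#' All-pairs Spearman screen of regions against measures
#'
#' Computes the Spearman correlation and p-value for every region-measure
#' pair, BH-adjusts jointly over all pairs, and retains measures that are
#' significantly associated with at least `count_threshold` regions.
#'
#' @param region_matrix samples x regions matrix (residualized region
#'   values).
#' @param measure_matrix samples x measures matrix (residualized measures),
#'   same samples.
#' @param count_threshold minimum significant-region count for a measure to
#'   be retained (study convention: 5 for 5mC, 10 for 5hmC).
#' @param fdr adjusted-p threshold for a significant pair (default 0.05).
#' @return list of class `screen_result`: `rho`, `p`, `padj` (regions x
#'   measures matrices), `pairs` (data.frame of significant pairs),
#'   `counts` (per-measure significant-region count), `retained` (measure
#'   names), `n_pairs`.
#' @export
spearman_screen <- function(region_matrix, measure_matrix,
                            count_threshold = 5L, fdr = 0.05) {
  if (nrow(region_matrix) != nrow(measure_matrix)) {
    stop("matrices must share samples")
  }
  if (nrow(region_matrix) < 3L) stop("need at least 3 shared samples")
  if (is.null(colnames(region_matrix))) {
    colnames(region_matrix) <- sprintf("region%05d", seq_len(ncol(region_matrix)))
  }
  if (is.null(colnames(measure_matrix))) {
    colnames(measure_matrix) <- sprintf("measure%04d", seq_len(ncol(measure_matrix)))
  }
  sm <- spearman_matrix(region_matrix, measure_matrix)
  padj <- matrix(
    stats::p.adjust(sm$p, "BH"),
    nrow(sm$p), ncol(sm$p), dimnames = dimnames(sm$p)
  )
  sig <- padj < fdr
  counts <- colSums(sig)
  retained <- colnames(padj)[counts >= count_threshold]
  idx <- which(sig, arr.ind = TRUE)
  pairs <- data.frame(
    region = rownames(padj)[idx[, 1L]],
    measure = colnames(padj)[idx[, 2L]],
    rho = sm$rho[idx], p = sm$p[idx], padj = padj[idx],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      rho = sm$rho, p = sm$p, padj = padj, pairs = pairs,
      counts = counts, retained = retained,
      n_pairs = length(sm$p)
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "spearman screen: %d pairs, %d significant, %d retained measures\n",
    x$n_pairs, nrow(x$pairs), length(x$retained)
  ))
  invisible(x)
}

#' Intersect screen, sCCA and atrophy evidence
#'
#' Reliable measures are those retained by the Spearman screen and carrying
#' a nonzero sCCA weight in any component; the reported pairs are the
#' significant screen pairs restricted to reliable measures, and reliable
#' measures that also show group atrophy are flagged.
#'
#' @param screen a `screen_result`.
#' @param scca_measures measure names with nonzero sCCA weight.
#' @param atrophy_set measure names decreased in the group comparison.
#' @return list: `reliable`, `atrophy_flagged`, `pairs` (restricted screen
#'   pairs), `regions` (regions in those pairs).
#' @export
intersect_findings <- function(screen, scca_measures, atrophy_set = character(0)) {
  reliable <- intersect(screen$retained, scca_measures)
  pairs <- screen$pairs[screen$pairs$measure %in% reliable, , drop = FALSE]
  list(
    reliable = reliable,
    atrophy_flagged = intersect(reliable, atrophy_set),
    pairs = pairs,
    regions = sort(unique(pairs$region))
  )
}
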
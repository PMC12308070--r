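# Negative-binomial window-count generator with injected differential
# regions and covariate effects, the ground-truth surface for the
# differential engine.

#' Simulate a window count matrix with known differential regions
#'
#' Counts are drawn from a negative binomial with log-link mean
#' `log mu_ij = baseline_i + group_j * lfc_i * log(2) + covariates_j +
#' log(depth_j)`, so a truth window with `lfc = +1` doubles the expected
#' normalized SCZ mean relative to HC. Variance is `mu + dispersion * mu^2`.
#'
#' Covariate effects on the natural-log mean default to an age slope of
#' 0.005 per year (on centred age), a gender shift of 0.05 (M vs F) and a
#' batch shift of 0.1 (applied only when `modality = "5mC"`, mirroring a
#' batch structure present in one assay only) — small but recoverable.
#'
#' @param seed integer seed.
#' @param cohort a `cohort_design`.
#' @param grid window grid data.frame (`window, chrom, start, end`), or NULL.
#' @param genome optional `genome_spec` used to build the grid when `grid`
#'   is NULL.
#' @param grid_params list with `w`, `s` for grid construction from `genome`.
#' @param n_windows when neither `grid` nor `genome` is given, the number of
#'   abstract windows to simulate (geometry-free engine testing).
#' @param baseline_logmean function of `n` returning per-window baseline
#'   natural-log means.
#' @param dispersion NB dispersion alpha (scalar or per-window), > 0.
#' @param n_true number of windows given a true group effect.
#' @param lfc_magnitude absolute true log2 fold change for truth windows
#'   (signs alternate between hyper and hypo).
#' @param covariate_effects list with `age`, `gender`, `batch` natural-log
#'   effect sizes.
#' @param depth_factors per-sample true depth multipliers (default all 1).
#' @param modality `"5mC"` or `"5hmC"` (controls whether the batch effect
#'   applies).
#' @return list with `counts` (windows x samples integer matrix, window ids
#'   as rownames, sample ids as colnames), `grid`, `truth` (data.frame
#'   `index, window, lfc, direction`), `depth_factors`, `modality`.
#' @export
simulate_counts <- function(seed, cohort,
                            grid = NULL, genome = NULL,
                            grid_params = list(w = 500L, s = 250L),
                            n_windows = 1000L,
                            baseline_logmean = function(n) stats::rnorm(n, log(50), 0.7),
                            dispersion = 0.1,
                            n_true = 0L,
                            lfc_magnitude = 1,
                            covariate_effects = list(age = 0.005, gender = 0.05, batch = 0.1),
                            depth_factors = NULL,
                            modality = c("5mC", "5hmC")) {
  modality <- match.arg(modality)
  if (any(dispersion <= 0)) stop("dispersion must be positive")
  if (is.null(grid) && !is.null(genome)) {
    grid <- make_window_grid(genome, grid_params$w, grid_params$s)
  }
  if (!is.null(grid)) {
    if (nrow(grid) == 0L) stop("window grid yields zero windows")
    n_win <- nrow(grid)
    win_ids <- grid$window
  } else {
    n_win <- as.integer(n_windows)
    if (n_win <= 0L) stop("window grid yields zero windows")
    win_ids <- sprintf("w%06d", seq_len(n_win))
  }
  if (n_true >= n_win) stop("n_true must be smaller than the number of windows")
  n <- nrow(cohort)
  if (is.null(depth_factors)) depth_factors <- rep(1, n)
  stopifnot(length(depth_factors) == n, all(depth_factors > 0))

  with_seed(seed, {
    base <- baseline_logmean(n_win)
    truth_idx <- if (n_true > 0L) sort(sample.int(n_win, n_true)) else integer(0)
    lfc <- numeric(n_win)
    if (n_true > 0L) {
      signs <- rep(c(1, -1), length.out = n_true)
      lfc[truth_idx] <- signs * lfc_magnitude
    }
    grp <- as.numeric(cohort$group == "SCZ")
    cov_eta <- covariate_effects$age * (cohort$age - mean(cohort$age)) +
      covariate_effects$gender * as.numeric(cohort$gender == "M")
    if (modality == "5mC" && !is.null(covariate_effects$batch) &&
      covariate_effects$batch != 0) {
      bt <- factor(cohort$batch)
      if (nlevels(bt) > 1L) {
        # treatment coding against the lexicographically first batch
        cov_eta <- cov_eta +
          covariate_effects$batch * as.numeric(bt != levels(bt)[1L])
      }
    }
    alpha <- rep_len(dispersion, n_win)
    eta <- outer(base, rep(0, n), "+") +
      outer(lfc * log(2), grp) +
      matrix(cov_eta + log(depth_factors), n_win, n, byrow = TRUE)
    mu <- exp(eta)
    K <- matrix(
      as.integer(stats::rnbinom(n_win * n, mu = mu, size = rep(1 / alpha, n))),
      n_win, n
    )
    dimnames(K) <- list(win_ids, cohort$id)
    truth <- data.frame(
      index = truth_idx,
      window = win_ids[truth_idx],
      lfc = lfc[truth_idx],
      direction = ifelse(lfc[truth_idx] > 0, "hyper", "hypo"),
      stringsAsFactors = FALSE
    )
    list(
      counts = K, grid = grid, truth = truth,
      depth_factors = depth_factors, modality = modality
    )
  })
}
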
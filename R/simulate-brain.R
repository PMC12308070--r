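# Brain structural-measure generator: covariate structure, planted group
# atrophy on an affected subset, and latent links to region-level
# modification values for association-recovery testing.

#' Simulate brain structural measures for the imaging subset
#'
#' Measures are generated for samples with `has_imaging = TRUE` as
#' `covariate part + group effect + latent region link + noise` with unit
#' noise SD, so `effect_size` is in SD units. Measure classes follow the
#' Desikan-Killiany-style layout: 68 cortical thickness (CT), 68 cortical
#' volume (CV), 68 surface area (SA) and the remainder subcortical volume
#' (SV). The group effect is a decrease (atrophy) applied to `n_affected`
#' randomly chosen measures in SCZ samples. When a `link_map` and
#' `region_values` are supplied, each linked measure additionally receives
#' `strength * scale(region value)`, creating region-measure correlations
#' with known location.
#'
#' @param seed integer seed.
#' @param cohort a `cohort_design`.
#' @param n_measures total number of measures (default 305).
#' @param n_affected number of atrophic measures (default 22).
#' @param effect_size atrophy magnitude in noise-SD units.
#' @param link_map optional data.frame `region, measure, strength`
#'   (`region` indexes columns of `region_values`, `measure` indexes
#'   measures).
#' @param region_values optional samples x regions matrix (imaging samples,
#'   same order as the imaging subset of `cohort`) supplying the latent
#'   factors shared with linked measures.
#' @param loadings optional list fixing covariate loadings for all measures
#'   (`age`, `gender`, `icv` scalars); by default loadings vary by measure.
#' @return list with `measures` (imaging samples x measures matrix),
#'   `classes` (per-measure class), `samples` (imaging sample ids),
#'   `truth` (list `affected`, `link_map`).
#' @export
simulate_brain_measures <- function(seed, cohort,
                                    n_measures = 305L, n_affected = 22L,
                                    effect_size = 2,
                                    link_map = NULL, region_values = NULL,
                                    loadings = NULL) {
  if (n_affected > n_measures) stop("n_affected must not exceed n_measures")
  sub <- cohort[cohort$has_imaging, , drop = FALSE]
  if (nrow(sub) < 3L) stop("imaging subset too small")
  if (!is.null(link_map)) {
    if (is.null(region_values)) {
      stop("link_map requires region_values")
    }
    if (any(link_map$region < 1L | link_map$region > ncol(region_values))) {
      stop("link_map references absent regions")
    }
    if (any(link_map$measure < 1L | link_map$measure > n_measures)) {
      stop("link_map references absent measures")
    }
    if (nrow(region_values) != nrow(sub)) {
      stop("region_values rows must match the imaging subset")
    }
  }
  n_ct <- min(68L, n_measures)
  n_cv <- min(68L, max(0L, n_measures - 68L))
  n_sa <- min(68L, max(0L, n_measures - 136L))
  n_sv <- max(0L, n_measures - 204L)
  classes <- c(
    rep("CT", n_ct), rep("CV", n_cv),
    rep("SA", n_sa), rep("SV", n_sv)
  )
  with_seed(seed, {
    m <- nrow(sub)
    age_c <- sub$age - mean(sub$age)
    male <- as.numeric(sub$gender == "M")
    icv_z <- as.numeric(scale(sub$icv))
    grp <- as.numeric(sub$group == "SCZ")
    b_age <- if (is.null(loadings)) stats::rnorm(n_measures, 0, 0.02) else rep(loadings$age, n_measures)
    b_gen <- if (is.null(loadings)) stats::rnorm(n_measures, 0, 0.3) else rep(loadings$gender, n_measures)
    b_icv <- if (is.null(loadings)) {
      ifelse(classes == "CT", 0, stats::rnorm(n_measures, 0.4, 0.1))
    } else {
      rep(loadings$icv, n_measures)
    }
    base <- stats::rnorm(n_measures, 10, 2)
    # planted atrophy and planted links live on disjoint measures so each
    # ground-truth set is identifiable
    pool <- setdiff(seq_len(n_measures), link_map$measure)
    if (n_affected > length(pool)) stop("not enough unlinked measures to affect")
    affected <- sort(sample(pool, n_affected))
    M <- matrix(stats::rnorm(m * n_measures), m, n_measures)
    M <- M +
      outer(rep(1, m), base) +
      outer(age_c, b_age) +
      outer(male, b_gen) +
      outer(icv_z, b_icv)
    if (n_affected > 0L && effect_size != 0) {
      M[, affected] <- M[, affected] - effect_size * grp
    }
    if (!is.null(link_map) && nrow(link_map)) {
      for (r in seq_len(nrow(link_map))) {
        z <- as.numeric(scale(region_values[, link_map$region[r]]))
        if (any(!is.finite(z))) z <- rep(0, m)
        M[, link_map$measure[r]] <- M[, link_map$measure[r]] +
          link_map$strength[r] * z
      }
    }
    colnames(M) <- sprintf("%s_%03d", classes, seq_len(n_measures))
    rownames(M) <- sub$id
    list(
      measures = M, classes = classes, samples = sub$id,
      truth = list(affected = affected, link_map = link_map)
    )
  })
}
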
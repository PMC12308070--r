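# cfDNA fragment generator: nucleosome-peaked length mixture, genomic
# placement, out-of-range contaminants to exercise the QC filters, and spike-in
# read counts per modified species.

# Discrete two-sided geometric (discrete Laplace) displacement with a given
# SD: difference of two iid geometric draws with q solving 2q/(1-q)^2 = sd^2.
rdlaplace <- function(n, sd) {
  if (sd <= 0) {
    return(integer(n))
  }
  r <- sd^2
  q <- ((2 * r + 1) - sqrt(8 * r + 1)) / (2 * r)
  stats::rgeom(n, 1 - q) - stats::rgeom(n, 1 - q)
}

default_mixture <- function() {
  list(
    weights = c(short = 0.25, mono = 0.60, long = 0.15),
    means = c(short = 120, mono = 166, long = 332),
    sds = c(short = 25, mono = 15, long = 30),
    # additive weight shift applied to SCZ samples: fewer short, more long
    # fragments, giving a modest negative short-fraction effect
    scz_shift = c(short = -0.03, mono = 0.01, long = 0.02),
    weight_noise_sd = 0.04
  )
}

#' Simulate per-sample cfDNA fragments and spike-in counts
#'
#' Fragment lengths come from a three-component normal mixture:
#' sub-nucleosomal, mono-nucleosomal (centred at 166 bp, DNA around one
#' nucleosome plus linker) and di-nucleosomal (centred at 332 bp). Group
#' weights are injectable; SCZ samples default to slightly fewer short and
#' more long fragments. A configurable fraction of fragments falls outside
#' the 20-1000 bp analysis range or on a non-autosome (`chrX`) so the
#' fragment filter has work to do.
#'
#' @param seed integer seed.
#' @param cohort a `cohort_design`.
#' @param genome a `genome_spec` supplying autosome names and lengths.
#' @param depth fragments per sample.
#' @param mixture list with `weights`, `means`, `sds`, `scz_shift`,
#'   `weight_noise_sd` (see `cfepiscan:::default_mixture`). Weights must sum
#'   to 1 per group.
#' @param outlier_fraction fraction of fragments with out-of-range lengths.
#' @param chrx_fraction fraction of fragments placed on `chrX`.
#' @param spike_total total spike-in reads per sample.
#' @param spike_efficiency named vector: expected fraction of spike-in reads
#'   on the modality-matched species for each library type.
#' @param modality library type, determines the matched spike-in species.
#' @return list with `fragments` (data.frame `sample, chrom, start, end`)
#'   and `spike_in` (data.frame `sample, reads_unmodified, reads_5mC,
#'   reads_5hmC`).
#' @export
simulate_fragments <- function(seed, cohort, genome,
                               depth = 2000L,
                               mixture = default_mixture(),
                               outlier_fraction = 0.01,
                               chrx_fraction = 0.01,
                               spike_total = 10000L,
                               spike_efficiency = c("5mC" = 0.90, "5hmC" = 0.85),
                               modality = c("5mC", "5hmC")) {
  modality <- match.arg(modality)
  if (depth < 0) stop("depth must be non-negative")
  if (abs(sum(mixture$weights) - 1) > 1e-8) {
    stop("mixture weights must sum to 1")
  }
  if (abs(sum(mixture$scz_shift)) > 1e-8) {
    stop("SCZ weight shift must sum to 0")
  }
  chrom_names <- genome$chromosomes$name
  chrom_len <- genome$chromosomes$length
  chrom_prob <- chrom_len / sum(chrom_len)

  with_seed(seed, {
    n <- nrow(cohort)
    frag_list <- vector("list", n)
    spike <- matrix(0L, n, 3L,
      dimnames = list(NULL, c("reads_unmodified", "reads_5mC", "reads_5hmC"))
    )
    for (j in seq_len(n)) {
      w <- mixture$weights
      if (cohort$group[j] == "SCZ") w <- w + mixture$scz_shift
      if (!is.null(mixture$weight_noise_sd) && mixture$weight_noise_sd > 0) {
        w <- w + stats::rnorm(3, 0, mixture$weight_noise_sd)
      }
      w <- pmax(w, 0)
      if (sum(w) <= 0) stop("degenerate mixture weights")
      w <- w / sum(w)
      comp <- sample.int(3L, depth, replace = TRUE, prob = w)
      len <- round(stats::rnorm(depth, mixture$means[comp], mixture$sds[comp]))
      # the mono-nucleosomal peak is sharp in real cfDNA: overlay a discrete
      # two-sided geometric (same SD) for that component
      mono_idx <- which(comp == 2L)
      if (length(mono_idx)) {
        len[mono_idx] <- mixture$means[2L] +
          rdlaplace(length(mono_idx), mixture$sds[2L])
      }
      n_out <- round(outlier_fraction * depth)
      if (n_out > 0L) {
        idx <- sample.int(depth, n_out)
        half <- stats::runif(n_out) < 0.5
        len[idx][half] <- sample(5:19, sum(half), replace = TRUE)
        len[idx][!half] <- sample(1001:1500, sum(!half), replace = TRUE)
      }
      len <- pmax(len, 1L)
      ci <- sample.int(length(chrom_names), depth, replace = TRUE, prob = chrom_prob)
      chrom <- chrom_names[ci]
      n_x <- round(chrx_fraction * depth)
      if (n_x > 0L) chrom[sample.int(depth, n_x)] <- "chrX"
      maxlen <- ifelse(chrom == "chrX", max(chrom_len), chrom_len[match(chrom, chrom_names)])
      len <- pmin(len, maxlen - 1L)
      start <- floor(stats::runif(depth, 0, maxlen - len))
      frag_list[[j]] <- data.frame(
        sample = cohort$id[j], chrom = chrom,
        start = as.integer(start), end = as.integer(start + len),
        stringsAsFactors = FALSE
      )
      eff <- spike_efficiency[[modality]]
      off <- (1 - eff) / 2
      p <- c(off, off, off)
      names(p) <- c("unmodified", "5mC", "5hmC")
      p[modality] <- eff
      p["unmodified"] <- 1 - sum(p[c("5mC", "5hmC")])
      draw <- stats::rmultinom(1L, spike_total, p)[, 1L]
      spike[j, ] <- as.integer(draw)
    }
    list(
      fragments = do.call(rbind, frag_list),
      spike_in = data.frame(sample = cohort$id, spike,
        stringsAsFactors = FALSE
      )
    )
  })
}
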
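# Fragment-level QC: the 20-1000 bp autosome filter, nucleosome length
# fractions, spike-in capture efficiency and group comparisons of fragment
# and concentration statistics.

#' Filter cfDNA fragments
#'
#' Retains fragments on autosomes with lengths in `[min_len, max_len]`
#' (bounds inclusive). Malformed records (`start >= end`) are an error.
#'
#' @param records data.frame with `chrom, start, end` (0-based half-open)
#'   and optionally further columns (e.g. `sample`), which are preserved.
#' @param autosomes character vector of autosome names; by default any
#'   chromosome matching `chr<number>`.
#' @param min_len,max_len inclusive length bounds in bp (defaults 20, 1000).
#' @return list with `fragments` (the retained records) and `removed`
#'   (named counts: `too_short`, `too_long`, `non_autosome`).
#' @export
filter_fragments <- function(records, autosomes = NULL,
                             min_len = 20L, max_len = 1000L) {
  if (nrow(records) == 0L) {
    return(list(
      fragments = records,
      removed = c(too_short = 0L, too_long = 0L, non_autosome = 0L)
    ))
  }
  bad <- which(records$start >= records$end)
  if (length(bad)) {
    stop(sprintf("malformed fragment record at line %d: start >= end", bad[1L]))
  }
  len <- records$end - records$start
  is_auto <- if (is.null(autosomes)) {
    grepl("^chr[0-9]+$", records$chrom)
  } else {
    records$chrom %in% autosomes
  }
  too_short <- len < min_len
  too_long <- len > max_len
  keep <- is_auto & !too_short & !too_long
  list(
    fragments = records[keep, , drop = FALSE],
    removed = c(
      too_short = sum(too_short & is_auto),
      too_long = sum(too_long & is_auto),
      non_autosome = sum(!is_auto)
    )
  )
}

#' Fragment length class fractions
#'
#' Short fragments are `< 166` bp, medial `166-332` bp (inclusive on both
#' ends), long `> 332` bp; 166 bp corresponds to DNA wrapped around one
#' nucleosome plus linker.
#'
#' @param lengths integer fragment lengths (already filtered).
#' @param mono,di class boundaries (defaults 166 and 332 bp).
#' @return named numeric vector `f_short, f_medial, f_long` summing to 1.
#' @export
length_fractions <- function(lengths, mono = 166L, di = 332L) {
  if (length(lengths) == 0L) {
    stop("cannot compute length fractions of an empty fragment set")
  }
  c(
    f_short = mean(lengths < mono),
    f_medial = mean(lengths >= mono & lengths <= di),
    f_long = mean(lengths > di)
  )
}

#' Spike-in capture efficiency
#'
#' Ratio of reads on the modality-matched spike-in species to total
#' spike-in reads.
#'
#' @param spike list or one-row data.frame with `reads_unmodified`,
#'   `reads_5mC`, `reads_5hmC`.
#' @param modality `"5mC"` or `"5hmC"`.
#' @return efficiency in `[0, 1]`.
#' @export
capture_efficiency <- function(spike, modality = c("5mC", "5hmC")) {
  modality <- match.arg(modality)
  total <- spike$reads_unmodified + spike$reads_5mC + spike$reads_5hmC
  if (any(total <= 0)) stop("total spike-in reads must be positive")
  matched <- if (modality == "5mC") spike$reads_5mC else spike$reads_5hmC
  matched / total
}

#' Two-group comparison of a per-sample statistic
#'
#' Two-sided rank-sum (Wilcoxon) test with the tie-corrected normal
#' approximation, a standardized mean difference (Cohen's d with pooled SD,
#' sign = SCZ minus HC), and the post hoc power of a two-sided two-sample
#' t-test at `|d|` and the observed group sizes.
#'
#' @param values_hc,values_scz numeric vectors (each of length >= 2).
#' @param alpha significance level for the power computation.
#' @param exact use the exact rank-sum distribution (small samples, no
#'   ties) instead of the normal approximation.
#' @return list with `statistic` (W), `p`, `d`, `power`, `n_hc`, `n_scz`.
#' @export
compare_groups <- function(values_hc, values_scz, alpha = 0.05, exact = FALSE) {
  n1 <- length(values_hc)
  n2 <- length(values_scz)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  s2p <- ((n1 - 1) * stats::var(values_hc) + (n2 - 1) * stats::var(values_scz)) /
    (n1 + n2 - 2)
  if (s2p <= 0) stop("pooled values are constant; effect size undefined")
  d <- (mean(values_scz) - mean(values_hc)) / sqrt(s2p)
  wt <- suppressWarnings(stats::wilcox.test(
    values_scz, values_hc,
    alternative = "two.sided", exact = exact, correct = FALSE
  ))
  list(
    statistic = unname(wt$statistic),
    p = wt$p.value,
    d = d,
    power = region_power(abs(d), n1, n2, alpha),
    n_hc = n1, n_scz = n2
  )
}

#' Per-sample fragment QC table
#'
#' @param fragments data.frame with `sample, chrom, start, end` (filtered).
#' @param spike_in data.frame with per-sample spike-in counts.
#' @param modality library type for capture efficiency.
#' @return data.frame, one row per sample: `sample, n_fragments,
#'   modal_length, f_short, f_medial, f_long, capture_efficiency`.
#' @export
fragment_qc_table <- function(fragments, spike_in, modality = c("5mC", "5hmC")) {
  modality <- match.arg(modality)
  samples <- unique(fragments$sample)
  rows <- lapply(samples, function(s) {
    len <- with(fragments[fragments$sample == s, ], end - start)
    fr <- length_fractions(len)
    tab <- tabulate(len)
    data.frame(
      sample = s, n_fragments = length(len),
      modal_length = which.max(tab),
      f_short = fr[["f_short"]], f_medial = fr[["f_medial"]],
      f_long = fr[["f_long"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  sp <- spike_in[match(out$sample, spike_in$sample), , drop = FALSE]
  out$capture_efficiency <- capture_efficiency(sp, modality)
  out
}
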
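# Sliding-window grid construction, window-level filters, fragment counting
# and cross-modality correlation.

#' Build a sliding-window tiling of one chromosome
#'
#' Windows are `[k*s, k*s + w)` for `k = 0, 1, ...` while the window fits
#' entirely inside the chromosome; partial terminal windows are dropped so
#' every window has identical width.
#'
#' @param chrom_length chromosome length in bp.
#' @param w window width in bp (default 500).
#' @param s step in bp (default 250).
#' @return data.frame with 0-based half-open `start`, `end`.
#' @export
make_windows <- function(chrom_length, w = 500L, s = 250L) {
  if (w <= 0 || s <= 0) stop("window width and step must be positive")
  if (s > w) stop("step must not exceed window width")
  n <- max(0L, floor((chrom_length - w) / s) + 1L)
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- (seq_len(n) - 1L) * as.integer(s)
  data.frame(start = start, end = start + as.integer(w))
}

#' Build the genome-wide window grid
#'
#' @param genome a `genome_spec`.
#' @param w,s window width and step in bp.
#' @return data.frame `window, chrom, start, end` with one row per window,
#'   `window` a unique `chrom:start-end` id, ordered by chromosome then start.
#' @export
make_window_grid <- function(genome, w = 500L, s = 250L) {
  parts <- lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    wdf <- make_windows(genome$chromosomes$length[i], w, s)
    if (nrow(wdf) == 0L) return(NULL)
    cbind(chrom = genome$chromosomes$name[i], wdf)
  })
  grid <- do.call(rbind, parts)
  if (is.null(grid) || nrow(grid) == 0L) stop("window grid is empty")
  grid <- data.frame(
    window = sprintf("%s:%d-%d", grid$chrom, grid$start, grid$end),
    grid, stringsAsFactors = FALSE
  )
  rownames(grid) <- NULL
  grid
}

#' Mappability and dark-region window filter
#'
#' A window is retained when its base-weighted mean mappability is at least
#' `map_threshold` and it has no overlap (>= 1 bp) with any dark region.
#' Bases not covered by the mappability track score 1.
#'
#' @param grid window grid (`chrom, start, end`).
#' @param mappability_track BED-like data.frame with a `score` column in
#'   `[0, 1]`; intervals must be disjoint and inside chromosome bounds.
#' @param dark_regions BED-like data.frame.
#' @param genome optional `genome_spec` used to validate track bounds.
#' @param map_threshold retention threshold on mean mappability (default 0.9).
#' @return logical mask, TRUE = retained, aligned to `grid` rows.
#' @export
filter_windows <- function(grid, mappability_track, dark_regions,
                           genome = NULL, map_threshold = 0.9) {
  if (!is.null(genome) && nrow(mappability_track)) {
    lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
    bad <- !(mappability_track$chrom %in% names(lens)) |
      mappability_track$start < 0 |
      mappability_track$end > lens[mappability_track$chrom]
    if (any(bad, na.rm = TRUE)) {
      stop("mappability track interval outside chromosome bounds")
    }
  }
  w <- grid$end - grid$start
  gr_win <- bed_to_gr(grid)
  mean_map <- rep(1, nrow(grid))
  if (nrow(mappability_track)) {
    gr_map <- bed_to_gr(mappability_track)
    hits <- GenomicRanges::findOverlaps(gr_win, gr_map)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::pintersect(gr_win[qi], gr_map[si])
      ovw <- GenomicRanges::width(ov)
      score <- mappability_track$score[si]
      # mean = (covered*score + uncovered*1) / width
      deficit <- tapply((1 - score) * ovw, qi, sum)
      idx <- as.integer(names(deficit))
      mean_map[idx] <- 1 - as.numeric(deficit) / w[idx]
    }
  }
  dark_hit <- rep(FALSE, nrow(grid))
  if (nrow(dark_regions)) {
    gr_dark <- bed_to_gr(dark_regions)
    dark_hit <- GenomicRanges::countOverlaps(gr_win, gr_dark) > 0L
  }
  mean_map >= map_threshold & !dark_hit
}

#' Count fragments per window
#'
#' A fragment increments every window it overlaps by at least 1 bp
#' (half-open coordinates), matching `bedtools coverage` read counting.
#'
#' @param grid window grid (`chrom, start, end`).
#' @param fragments BED-like data.frame of fragments.
#' @return integer vector of counts aligned to `grid` rows.
#' @export
count_fragments <- function(grid, fragments) {
  if (nrow(fragments) == 0L) {
    return(integer(nrow(grid)))
  }
  unknown <- setdiff(unique(fragments$chrom), unique(grid$chrom))
  if (length(unknown)) {
    stop(sprintf("unknown chromosome in fragments: %s", unknown[1L]))
  }
  as.integer(GenomicRanges::countOverlaps(bed_to_gr(grid), bed_to_gr(fragments)))
}

#' Low-coverage window filter
#'
#' Retains a window when strictly more than `min_count` counts are observed
#' in at least `min_samples` samples, pooled over both groups.
#'
#' @param K windows x samples count matrix.
#' @param min_count exclusive count threshold (default 3).
#' @param min_samples minimum number of samples exceeding it (default 10).
#' @return logical mask over rows of `K`.
#' @export
low_coverage_filter <- function(K, min_count = 3L, min_samples = 10L) {
  if (ncol(K) < min_samples) {
    stop("fewer samples than the minimum required by the coverage filter")
  }
  rowSums(K > min_count) >= min_samples
}

#' Per-sample cross-modality rank correlation
#'
#' Spearman correlation of the two modalities' counts over shared retained
#' windows, computed per sample, with a per-group median summary.
#'
#' @param K_5mC,K_5hmC count matrices with window ids as rownames and the
#'   same sample columns; windows are intersected first.
#' @param groups optional per-sample group labels for the summary.
#' @return list with `rho` (per sample) and `summary` (median rho, per group
#'   when `groups` is given).
#' @export
modality_correlation <- function(K_5mC, K_5hmC, groups = NULL) {
  shared <- intersect(rownames(K_5mC), rownames(K_5hmC))
  if (length(shared) < 10L) {
    stop("fewer than 10 shared windows between modalities")
  }
  A <- K_5mC[shared, , drop = FALSE]
  B <- K_5hmC[shared, , drop = FALSE]
  stopifnot(ncol(A) == ncol(B))
  rho <- vapply(seq_len(ncol(A)), function(j) {
    stats::cor(A[, j], B[, j], method = "spearman")
  }, numeric(1))
  names(rho) <- colnames(A)
  summary <- if (is.null(groups)) {
    c(all = stats::median(rho))
  } else {
    tapply(rho, groups, stats::median)
  }
  list(rho = rho, summary = summary)
}

#' Genome fraction covered by retained windows
#'
#' @param grid window grid.
#' @param mask logical retention mask aligned to `grid`.
#' @param genome `genome_spec` providing total genome length.
#' @return percentage of genome bases inside the union of retained windows.
#' @export
genome_fraction <- function(grid, mask, genome) {
  stopifnot(length(mask) == nrow(grid))
  kept <- grid[mask, , drop = FALSE]
  total <- sum(as.numeric(genome$chromosomes$length))
  100 * covered_bases(kept) / total
}
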
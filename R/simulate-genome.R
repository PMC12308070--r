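# Synthetic genome and cohort generators.
#
# These emulate the data structure the downstream analysis assumes: a small
# multi-chromosome genome with CpG islands, low-mappability and dark-region
# masks and toy gene models, plus a case-control cohort with demographics,
# clinical scores and an imaging subset.

# Place k disjoint intervals of width L uniformly on [0, len). Stick-breaking
# construction guarantees disjointness and exact total coverage k*L.
place_disjoint <- function(len, k, L) {
  if (k == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  free <- len - k * L
  if (free < 0) stop("requested intervals exceed chromosome length")
  u <- sort(stats::runif(k, 0, free))
  starts <- floor(u) + (seq_len(k) - 1L) * L
  data.frame(start = as.integer(starts), end = as.integer(starts + L))
}

#' Generate a synthetic genome specification
#'
#' Builds a small genome with CpG islands, low-mappability intervals (with
#' per-interval mappability scores below the usual 0.9 retention threshold),
#' dark regions (the analogue of centromere/telomere/excluded-region masks)
#' and toy gene models. Intervals are 0-based half-open.
#'
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param n_chrom number of autosomes (named `chr1..chrN`).
#' @param lengths chromosome lengths in bp (recycled to `n_chrom`); each
#'   must be at least 10 kb.
#' @param island_rate expected CpG islands per bp (default one per 50 kb).
#' @param low_map_fraction fraction of bases covered by low-mappability
#'   intervals, in `[0, 1)`.
#' @param dark_fraction fraction of bases covered by dark regions, in `[0, 1)`.
#' @param gene_rate expected genes per bp (default one per 100 kb).
#' @return an object of class `genome_spec`: a list with `chromosomes`
#'   (name, length), `cpg_islands`, `low_mappability` (with `score`),
#'   `dark_regions`, and `genes` (id, chrom, strand, tss, span, exons,
#'   gene_type).
#' @export
simulate_genome <- function(seed, n_chrom = 2L,
                            lengths = 1e6,
                            island_rate = 1 / 50000,
                            low_map_fraction = 0.05,
                            dark_fraction = 0.02,
                            gene_rate = 1 / 100000) {
  lengths <- as.integer(rep_len(lengths, n_chrom))
  if (any(lengths < 10000L)) stop("chromosome lengths must be >= 10 kb")
  if (low_map_fraction < 0 || low_map_fraction >= 1 ||
    dark_fraction < 0 || dark_fraction >= 1) {
    stop("mask fractions must lie in [0, 1)")
  }
  with_seed(seed, {
    chroms <- data.frame(
      name = paste0("chr", seq_len(n_chrom)),
      length = lengths, stringsAsFactors = FALSE
    )
    islands <- list()
    lowmap <- list()
    dark <- list()
    genes <- list()
    island_len <- 800L
    lowmap_len <- 2000L
    dark_len <- 5000L
    for (i in seq_len(n_chrom)) {
      len <- lengths[i]
      cn <- chroms$name[i]
      k_isl <- max(0L, round(island_rate * len))
      isl <- place_disjoint(len, k_isl, island_len)
      if (nrow(isl)) islands[[cn]] <- cbind(chrom = cn, isl)
      k_lm <- round(low_map_fraction * len / lowmap_len)
      lm <- place_disjoint(len, k_lm, lowmap_len)
      if (nrow(lm)) {
        lm$score <- round(stats::runif(nrow(lm), 0, 0.85), 4)
        lowmap[[cn]] <- cbind(chrom = cn, lm)
      }
      k_dk <- round(dark_fraction * len / dark_len)
      dk <- place_disjoint(len, k_dk, dark_len)
      if (nrow(dk)) dark[[cn]] <- cbind(chrom = cn, dk)
      n_genes <- max(1L, round(gene_rate * len))
      span_len <- pmin(round(stats::runif(n_genes, 10000, 40000)), len %/% 2L)
      span_start <- floor(stats::runif(n_genes, 0, len - span_len))
      strand <- sample(c("+", "-"), n_genes, replace = TRUE)
      gene_type <- sample(c("protein_coding", "lncRNA", "pseudogene"),
        n_genes,
        replace = TRUE, prob = c(0.7, 0.2, 0.1)
      )
      exon_str <- character(n_genes)
      for (g in seq_len(n_genes)) {
        n_ex <- sample(3:6, 1L)
        ex <- place_disjoint(span_len[g], n_ex, max(200L, span_len[g] %/% (4L * n_ex)))
        ex$start <- ex$start + span_start[g]
        ex$end <- ex$end + span_start[g]
        exon_str[g] <- paste(sprintf("%d-%d", ex$start, ex$end), collapse = ",")
      }
      genes[[cn]] <- data.frame(
        id = sprintf("%s_g%03d", cn, seq_len(n_genes)),
        chrom = cn, strand = strand,
        tss = ifelse(strand == "+", span_start, span_start + span_len - 1L),
        span_start = as.integer(span_start),
        span_end = as.integer(span_start + span_len),
        exons = exon_str, gene_type = gene_type,
        stringsAsFactors = FALSE
      )
    }
    bind0 <- function(lst, empty) {
      if (length(lst)) do.call(rbind, unname(lst)) else empty
    }
    empty_bed <- data.frame(
      chrom = character(0), start = integer(0),
      end = integer(0), stringsAsFactors = FALSE
    )
    out <- list(
      chromosomes = chroms,
      cpg_islands = bind0(islands, empty_bed),
      low_mappability = bind0(lowmap, cbind(empty_bed, score = numeric(0))),
      dark_regions = bind0(dark, empty_bed),
      genes = do.call(rbind, unname(genes))
    )
    rownames(out$cpg_islands) <- NULL
    rownames(out$low_mappability) <- NULL
    rownames(out$dark_regions) <- NULL
    rownames(out$genes) <- NULL
    class(out) <- "genome_spec"
    out
  })
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "genome_spec: %d chromosome(s), %.2f Mb total\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6
  ))
  cat(sprintf(
    "  CpG islands: %d | low-mappability: %d | dark: %d | genes: %d\n",
    nrow(x$cpg_islands), nrow(x$low_mappability),
    nrow(x$dark_regions), nrow(x$genes)
  ))
  invisible(x)
}

#' Generate a synthetic case-control cohort
#'
#' Emulates a schizophrenia (SCZ) versus healthy-control (HC) cohort:
#' demographics, batch labels, intracranial volume, cfDNA concentration,
#' an imaging subset, and PANSS-like / BACS-like clinical scores generated
#' as monotone noisy functions of a per-sample latent disease severity
#' (so severity-score correlations have known sign: positive for the
#' symptom scale, negative for the cognition scale).
#'
#' @param seed integer seed.
#' @param n_hc,n_scz group sizes (defaults 77 and 66).
#' @param n_imaging_hc,n_imaging_scz imaging-subset sizes (defaults 68, 59).
#' @param n_batch number of sequencing batches.
#' @param conc_severity_slope slope of log cfDNA concentration on latent
#'   severity (yields a modest case-control concentration difference).
#' @return a data.frame of class `cohort_design` with one row per sample:
#'   `id, group, age, gender, batch, icv, has_imaging, cfdna_conc,
#'   panss_total, bacs_z, severity`.
#' @export
simulate_cohort <- function(seed, n_hc = 77L, n_scz = 66L,
                            n_imaging_hc = 68L, n_imaging_scz = 59L,
                            n_batch = 2L,
                            conc_severity_slope = 0.08) {
  if (n_imaging_hc > n_hc || n_imaging_scz > n_scz) {
    stop("imaging subset cannot exceed group size")
  }
  with_seed(seed, {
    n <- n_hc + n_scz
    group <- c(rep("HC", n_hc), rep("SCZ", n_scz))
    age <- round(pmin(pmax(stats::rnorm(n, 32.1, 10.4), 17), 65), 1)
    gender <- ifelse(stats::runif(n) < 0.64, "F", "M")
    batch <- sample(paste0("b", seq_len(n_batch)), n, replace = TRUE)
    icv <- round(stats::rnorm(n, 1.45e6, 1.4e5))
    severity <- stats::rnorm(n, mean = ifelse(group == "SCZ", 2, 0), sd = 1)
    cfdna_conc <- round(exp(log(10) + conc_severity_slope * severity +
      stats::rnorm(n, 0, 0.30)), 3)
    panss_total <- pmax(30, round(31 + 6 * pmax(severity, 0) +
      stats::rnorm(n, 0, 3)))
    bacs_z <- round(-0.2 - 0.8 * severity + stats::rnorm(n, 0, 0.8), 3)
    has_imaging <- logical(n)
    has_imaging[sample(which(group == "HC"), n_imaging_hc)] <- TRUE
    has_imaging[sample(which(group == "SCZ"), n_imaging_scz)] <- TRUE
    out <- data.frame(
      id = sprintf("S%03d", seq_len(n)),
      group = group, age = age, gender = gender, batch = batch,
      icv = icv, has_imaging = has_imaging, cfdna_conc = cfdna_conc,
      panss_total = panss_total, bacs_z = bacs_z,
      severity = round(severity, 4),
      stringsAsFactors = FALSE
    )
    class(out) <- c("cohort_design", "data.frame")
    out
  })
}
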
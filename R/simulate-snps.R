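# GWAS locus and variant-call generator: lead SNPs optionally planted
# inside differential regions, plus per-cohort variant-call tables with
# SCZ-exclusive calls for the specificity filter.

# Complement of the masked bases (dark regions plus low-mappability
# intervals) as a BED-like data.frame.
genome_unmasked <- function(genome) {
  full <- GenomicRanges::GRanges(
    seqnames = genome$chromosomes$name,
    ranges = IRanges::IRanges(1L, genome$chromosomes$length)
  )
  mask <- rbind(
    genome$dark_regions[, c("chrom", "start", "end")],
    genome$low_mappability[, c("chrom", "start", "end")]
  )
  allowed <- if (nrow(mask)) {
    GenomicRanges::setdiff(full, bed_to_gr(mask))
  } else {
    full
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(allowed)),
    start = GenomicRanges::start(allowed) - 1L,
    end = GenomicRanges::end(allowed),
    stringsAsFactors = FALSE
  )
}

# Sample n positions uniformly over the bases of a BED-like interval set.
sample_positions <- function(intervals, n) {
  widths <- intervals$end - intervals$start
  total <- sum(as.numeric(widths))
  if (total <= 0) stop("no unmasked bases to sample from")
  u <- floor(stats::runif(n, 0, total))
  cw <- cumsum(as.numeric(widths))
  idx <- findInterval(u, c(0, cw), rightmost.closed = FALSE)
  offset <- u - c(0, cw)[idx]
  data.frame(
    chrom = intervals$chrom[idx],
    pos = as.integer(intervals$start[idx] + offset),
    stringsAsFactors = FALSE
  )
}

#' Simulate GWAS loci, lead SNPs and per-cohort variant calls
#'
#' A fraction of lead SNPs is planted inside supplied regions (distance 0);
#' the rest are placed uniformly over unmasked bases, i.e. from the same
#' distribution the randomization null uses, so an unplanted configuration
#' is calibrated under the proximity test. Variant-call tables carry QUAL
#' and depth; a chosen number of lead SNPs get high-quality SCZ-exclusive
#' calls, and decoy calls (low quality, or present in both cohorts) are
#' added to exercise the specificity rules.
#'
#' @param seed integer seed.
#' @param genome a `genome_spec`.
#' @param regions BED-like data.frame of differential regions (required when
#'   `planted_fraction > 0`).
#' @param n_loci number of loci (one lead SNP per locus).
#' @param planted_fraction fraction of lead SNPs planted inside regions,
#'   in `[0, 1]`.
#' @param locus_width width of each locus interval in bp.
#' @param n_scz_exclusive number of lead SNPs given SCZ-exclusive calls.
#' @param exclusive_qual,exclusive_depth QUAL/depth of those calls.
#' @param n_background shared background calls per cohort.
#' @return list with `loci` (`chrom, start, end, lead_pos, ref, alt, label`),
#'   `calls_scz`, `calls_hc` (`chrom, pos, ref, alt, qual, depth`), and
#'   `truth` (`label, planted, scz_exclusive`).
#' @export
simulate_snp_loci <- function(seed, genome, regions = NULL,
                              n_loci = 30L, planted_fraction = 0.5,
                              locus_width = 20000L,
                              n_scz_exclusive = 3L,
                              exclusive_qual = 50, exclusive_depth = 40,
                              n_background = 50L) {
  if (planted_fraction < 0 || planted_fraction > 1) {
    stop("planted_fraction must lie in [0, 1]")
  }
  n_planted <- round(planted_fraction * n_loci)
  if (n_planted > 0L && (is.null(regions) || nrow(regions) == 0L)) {
    stop("planting lead SNPs requires a non-empty region set")
  }
  chrom_len <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
  unmasked <- genome_unmasked(genome)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    planted <- rep(FALSE, n_loci)
    planted[seq_len(n_planted)] <- TRUE
    chrom <- character(n_loci)
    pos <- integer(n_loci)
    if (n_planted > 0L) {
      ridx <- sample.int(nrow(regions), n_planted, replace = TRUE)
      chrom[planted] <- regions$chrom[ridx]
      pos[planted] <- as.integer(floor(stats::runif(
        n_planted, regions$start[ridx], regions$end[ridx]
      )))
    }
    if (n_planted < n_loci) {
      free <- sample_positions(unmasked, n_loci - n_planted)
      chrom[!planted] <- free$chrom
      pos[!planted] <- free$pos
    }
    half <- locus_width %/% 2L
    start <- pmax(0L, pos - half)
    end <- pmin(chrom_len[chrom], pos + half + 1L)
    ref <- sample(bases, n_loci, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    loci <- data.frame(
      chrom = chrom, start = as.integer(start), end = as.integer(end),
      lead_pos = pos, ref = ref, alt = unname(alt),
      label = sprintf("locus%03d", seq_len(n_loci)),
      stringsAsFactors = FALSE
    )
    # variant calls
    excl_idx <- if (n_scz_exclusive > 0L) sample.int(n_loci, n_scz_exclusive) else integer(0)
    mk_bg <- function(n) {
      p <- sample_positions(unmasked, n)
      r <- sample(bases, n, replace = TRUE)
      a <- vapply(r, function(x) sample(setdiff(bases, x), 1L), character(1))
      data.frame(
        chrom = p$chrom, pos = p$pos, ref = r, alt = unname(a),
        qual = round(stats::runif(n, 31, 90), 1),
        depth = sample(31:120, n, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    shared <- mk_bg(n_background)
    scz_excl <- loci[excl_idx, c("chrom", "lead_pos", "ref", "alt")]
    names(scz_excl)[2] <- "pos"
    if (nrow(scz_excl)) {
      scz_excl$qual <- exclusive_qual
      scz_excl$depth <- exclusive_depth
    } else {
      scz_excl$qual <- numeric(0)
      scz_excl$depth <- integer(0)
    }
    # decoys: one lead call failing the quality gate, one present in both
    decoy_idx <- setdiff(seq_len(n_loci), excl_idx)
    lowq <- both <- shared[0, ]
    if (length(decoy_idx) >= 2L) {
      d1 <- decoy_idx[1L]
      lowq <- data.frame(
        chrom = loci$chrom[d1], pos = loci$lead_pos[d1],
        ref = loci$ref[d1], alt = loci$alt[d1],
        qual = 20, depth = 20, stringsAsFactors = FALSE
      )
      d2 <- decoy_idx[2L]
      both <- data.frame(
        chrom = loci$chrom[d2], pos = loci$lead_pos[d2],
        ref = loci$ref[d2], alt = loci$alt[d2],
        qual = 60, depth = 60, stringsAsFactors = FALSE
      )
    }
    calls_scz <- rbind(shared, scz_excl, lowq, both)
    calls_hc <- rbind(shared, both)
    rownames(calls_scz) <- rownames(calls_hc) <- NULL
    truth <- data.frame(
      label = loci$label, planted = planted,
      scz_exclusive = seq_len(n_loci) %in% excl_idx,
      stringsAsFactors = FALSE
    )
    list(loci = loci, calls_scz = calls_scz, calls_hc = calls_hc, truth = truth)
  })
}
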
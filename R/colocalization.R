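# GWAS-locus colocalization: positional overlap, region-SNP distances, a
# randomized-SNP proximity null and the SCZ-specific variant rules.

#' Colocalize regions with GWAS loci
#'
#' A (region, locus) pair is colocalized when the region overlaps the locus
#' interval by at least 1 bp (half-open coordinates).
#'
#' @param regions BED-like data.frame with a `window` id column (added if
#'   absent).
#' @param loci locus data.frame (`chrom, start, end, lead_pos, label`).
#' @return list with `pairs` (data.frame `window, label, lead_pos`),
#'   `n_regions` (distinct colocalized regions), `n_snps` (distinct lead
#'   SNPs).
#' @export
colocalize <- function(regions, loci) {
  if (is.null(regions$window)) {
    regions$window <- sprintf(
      "%s:%d-%d", regions$chrom, regions$start, regions$end
    )
  }
  if (nrow(regions) == 0L || nrow(loci) == 0L) {
    return(list(
      pairs = data.frame(
        window = character(0), label = character(0),
        lead_pos = integer(0), stringsAsFactors = FALSE
      ),
      n_regions = 0L, n_snps = 0L
    ))
  }
  hits <- GenomicRanges::findOverlaps(bed_to_gr(regions), bed_to_gr(loci))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(
    window = regions$window[qi],
    label = loci$label[si],
    lead_pos = loci$lead_pos[si],
    stringsAsFactors = FALSE
  )
  list(
    pairs = pairs,
    n_regions = length(unique(pairs$window)),
    n_snps = length(unique(pairs$label))
  )
}

#' Distance between a region and a SNP position
#'
#' Zero when the 0-based position lies inside the half-open region,
#' otherwise the gap in bp. Vectorized over regions.
#'
#' @param start,end region coordinates (0-based half-open).
#' @param pos SNP position (0-based).
#' @return distance(s) in bp.
#' @export
region_snp_distance <- function(start, end, pos) {
  pmax(start - pos, pos - (end - 1L), 0L)
}

# Distance from each SNP to its nearest same-chromosome region; Inf when a
# SNP's chromosome carries no region.
snp_nearest_region <- function(snps, regions) {
  out <- rep(Inf, nrow(snps))
  for (cn in unique(snps$chrom)) {
    reg <- regions[regions$chrom == cn, , drop = FALSE]
    idx <- which(snps$chrom == cn)
    if (nrow(reg) == 0L) next
    P <- snps$pos[idx]
    D <- pmax(
      outer(reg$start, P, "-"),
      outer(-(reg$end - 1L), P, "+"),
      0
    )
    out[idx] <- apply(D, 2L, min)
  }
  out
}

#' Randomized-SNP proximity null
#'
#' Each replicate places `n_snps` positions uniformly over the genome's
#' unmasked bases (outside dark regions and low-mappability intervals) and
#' records each simulated SNP's distance to its nearest region. All
#' replicates are pooled into one null sample.
#'
#' @param seed integer seed (deterministic output per seed).
#' @param genome a `genome_spec`.
#' @param n_snps SNPs per replicate (match the observed lead-SNP count).
#' @param regions BED-like data.frame of differential regions.
#' @param reps number of replicates (default 1000).
#' @return list with `distances` (pooled null distances), `reps`, `n_snps`,
#'   `positions` (last replicate's placements, for auditing).
#' @export
simulate_snp_null <- function(seed, genome, n_snps, regions, reps = 1000L) {
  unmasked <- genome_unmasked(genome)
  if (sum(as.numeric(unmasked$end - unmasked$start)) <= 0) {
    stop("genome has no unmasked bases")
  }
  with_seed(seed, {
    all_d <- vector("list", reps)
    last <- NULL
    for (r in seq_len(reps)) {
      snps <- sample_positions(unmasked, n_snps)
      all_d[[r]] <- snp_nearest_region(snps, regions)
      last <- snps
    }
    list(
      distances = unlist(all_d), reps = reps, n_snps = n_snps,
      positions = last
    )
  })
}

#' One-sided proximity test against the randomization null
#'
#' Rank-sum test of whether the observed distances are stochastically
#' smaller than the pooled null distances (tie-corrected normal
#' approximation). Infinite distances (chromosomes without regions) are
#' dropped symmetrically.
#'
#' @param observed observed distances (e.g. lead SNP to nearest region).
#' @param null pooled null distances from [simulate_snp_null()].
#' @return list with `p` (one-sided), `n_observed`, `n_null`,
#'   `median_observed`, `median_null`.
#' @export
test_proximity <- function(observed, null) {
  observed <- observed[is.finite(observed)]
  null <- null[is.finite(null)]
  if (length(observed) == 0L || length(null) == 0L) {
    stop("both distance samples must be non-empty")
  }
  wt <- suppressWarnings(stats::wilcox.test(
    observed, null,
    alternative = "less", exact = FALSE, correct = FALSE
  ))
  list(
    p = wt$p.value,
    n_observed = length(observed), n_null = length(null),
    median_observed = stats::median(observed),
    median_null = stats::median(null)
  )
}

#' Observed lead-SNP proximity to regions
#'
#' Default direction matches the null: each lead SNP's distance to its
#' nearest region. The reverse direction (each region to its nearest lead
#' SNP) is also available.
#'
#' @param regions BED-like data.frame.
#' @param loci locus data.frame with `chrom`, `lead_pos`.
#' @param direction `"snp_to_region"` (default) or `"region_to_snp"`.
#' @return numeric distances.
#' @export
proximity_distances <- function(regions, loci,
                                direction = c("snp_to_region", "region_to_snp")) {
  direction <- match.arg(direction)
  if (direction == "snp_to_region") {
    snps <- data.frame(chrom = loci$chrom, pos = loci$lead_pos)
    snp_nearest_region(snps, regions)
  } else {
    out <- rep(Inf, nrow(regions))
    for (cn in unique(regions$chrom)) {
      pos <- loci$lead_pos[loci$chrom == cn]
      idx <- which(regions$chrom == cn)
      if (length(pos) == 0L) next
      for (i in idx) {
        out[i] <- min(region_snp_distance(
          regions$start[i], regions$end[i], pos
        ))
      }
    }
    out
  }
}

#' SCZ-specific variant filter
#'
#' Keeps variant calls with `qual > qual_min` and `depth > depth_min`
#' (strict) whose position, reference and alternate allele exactly match a
#' lead SNP, that are present in the SCZ cohort calls and absent (same
#' chrom/pos/ref/alt) from the HC cohort calls.
#'
#' @param calls_scz,calls_hc data.frames (`chrom, pos, ref, alt, qual,
#'   depth`).
#' @param lead_snps data.frame (`chrom`, `lead_pos` or `pos`, `ref`, `alt`).
#' @param qual_min,depth_min strict lower bounds (defaults 30).
#' @return the retained rows of `calls_scz`.
#' @export
specific_variants <- function(calls_scz, calls_hc, lead_snps,
                              qual_min = 30, depth_min = 30) {
  if (any(!nzchar(calls_scz$ref) | !nzchar(calls_scz$alt))) {
    stop("malformed alleles in SCZ calls")
  }
  pos_col <- if ("lead_pos" %in% names(lead_snps)) "lead_pos" else "pos"
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  lead_keys <- key(
    lead_snps$chrom, lead_snps[[pos_col]], lead_snps$ref, lead_snps$alt
  )
  hc_keys <- key(calls_hc$chrom, calls_hc$pos, calls_hc$ref, calls_hc$alt)
  scz_keys <- key(calls_scz$chrom, calls_scz$pos, calls_scz$ref, calls_scz$alt)
  keep <- calls_scz$qual > qual_min & calls_scz$depth > depth_min &
    scz_keys %in% lead_keys & !(scz_keys %in% hc_keys)
  calls_scz[keep, , drop = FALSE]
}
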
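# Region annotation against CpG-island rings and gene models, and
# region-to-gene mapping.

# Parse the comma-separated "start-end" exon string of a gene model row.
parse_exons <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  data.frame(
    start = as.integer(vapply(parts, `[`, character(1), 1L)),
    end = as.integer(vapply(parts, `[`, character(1), 2L))
  )
}

#' CpG annotation of regions
#'
#' Classifies each region as `island` (any overlap with a CpG island),
#' `shore` (region midpoint within 2 kb of an island edge), `shelf`
#' (midpoint within 2-4 kb) or `interCGI`. Island overlap takes precedence;
#' boundary-spanning regions are resolved by the midpoint distance.
#'
#' @param regions BED-like data.frame (`chrom, start, end`).
#' @param islands BED-like data.frame of non-overlapping CpG islands.
#' @param shore_bp,shelf_bp ring widths in bp (defaults 2000 and 4000,
#'   measured from the island edge).
#' @return character vector of classes aligned to `regions` rows.
#' @export
cpg_annotate <- function(regions, islands, shore_bp = 2000L, shelf_bp = 4000L) {
  n <- nrow(regions)
  if (n == 0L) return(character(0))
  out <- rep("interCGI", n)
  if (nrow(islands) == 0L) return(out)
  gr_reg <- bed_to_gr(regions)
  gr_isl <- bed_to_gr(islands)
  overlaps <- GenomicRanges::countOverlaps(gr_reg, gr_isl) > 0L
  out[overlaps] <- "island"
  mid <- floor((regions$start + regions$end) / 2)
  gr_mid <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(mid + 1L, mid + 1L)
  )
  dn <- GenomicRanges::distanceToNearest(gr_mid, gr_isl)
  d <- rep(NA_real_, n)
  d[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance
  shore <- !overlaps & !is.na(d) & d > 0 & d <= shore_bp
  shelf <- !overlaps & !is.na(d) & d > shore_bp & d <= shelf_bp
  # midpoint inside an island of another interval while region itself does
  # not overlap cannot happen for disjoint islands; d == 0 without overlap
  # means the midpoint touches the island edge: treat as shore
  shore <- shore | (!overlaps & !is.na(d) & d == 0)
  out[shore] <- "shore"
  out[shelf] <- "shelf"
  out
}

# Promoter interval of one gene, strand-aware, 0-based half-open:
# [TSS - len, TSS) on '+', (TSS, TSS + len] -> [TSS + 1, TSS + 1 + len) on '-'.
promoter_interval <- function(tss, strand, len = 1000L) {
  if (strand == "+") {
    c(max(0L, tss - len), tss)
  } else {
    c(tss + 1L, tss + 1L + len)
  }
}

#' Genic annotation of regions
#'
#' A region can carry several classes: `promoter` (overlap with the
#' strand-aware 1 kb upstream of a TSS), `exon` (overlap with an exon),
#' `intron` (overlap with a gene body outside its exons); a region hitting
#' nothing is `intergenic`. Overlapping gene ids are reported.
#'
#' @param regions BED-like data.frame.
#' @param genes gene-model data.frame as produced by [simulate_genome()]
#'   (`id, chrom, strand, tss, span_start, span_end, exons, gene_type`).
#' @param genome optional `genome_spec` used to validate TSS positions.
#' @param promoter_len promoter length in bp (default 1000).
#' @return data.frame aligned to `regions`: `classes` (comma-separated),
#'   `genes` (comma-separated ids), `primary` (precedence promoter > exon >
#'   intron > intergenic).
#' @export
genic_annotate <- function(regions, genes, genome = NULL, promoter_len = 1000L) {
  if (!is.null(genome)) {
    lens <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
    if (any(genes$tss < 0 | genes$tss >= lens[genes$chrom])) {
      stop("gene TSS outside chromosome bounds")
    }
  }
  n <- nrow(regions)
  empty <- data.frame(
    classes = character(0), genes = character(0),
    primary = character(0), stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)
  gr_reg <- bed_to_gr(regions)

  prom <- t(mapply(promoter_interval, genes$tss, genes$strand,
    MoreArgs = list(len = promoter_len)
  ))
  prom_df <- data.frame(
    chrom = genes$chrom, start = prom[, 1L], end = prom[, 2L], gene = genes$id
  )
  body_df <- data.frame(
    chrom = genes$chrom, start = genes$span_start, end = genes$span_end,
    gene = genes$id
  )
  exon_list <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- parse_exons(genes$exons[i])
    if (nrow(ex) == 0L) return(NULL)
    data.frame(chrom = genes$chrom[i], ex, gene = genes$id[i])
  })
  exon_df <- do.call(rbind, exon_list)

  hit_sets <- function(df) {
    res <- vector("list", n)
    if (is.null(df) || nrow(df) == 0L) return(res)
    hits <- GenomicRanges::findOverlaps(gr_reg, bed_to_gr(df))
    if (length(hits)) {
      sp <- split(
        df$gene[S4Vectors::subjectHits(hits)],
        S4Vectors::queryHits(hits)
      )
      res[as.integer(names(sp))] <- lapply(sp, unique)
    }
    res
  }
  prom_hits <- hit_sets(prom_df)
  exon_hits <- hit_sets(exon_df)
  body_hits <- hit_sets(body_df)

  classes <- character(n)
  gene_ids <- character(n)
  primary <- character(n)
  for (i in seq_len(n)) {
    cl <- character(0)
    if (length(prom_hits[[i]])) cl <- c(cl, "promoter")
    if (length(exon_hits[[i]])) cl <- c(cl, "exon")
    intron_genes <- setdiff(body_hits[[i]], exon_hits[[i]])
    # a region may lie in an exon of one gene and an intron of another; an
    # intron also applies when the region touches intronic bases of the
    # same gene, i.e. body overlap wider than its exon overlap -- here we
    # use gene-level resolution: body hit without exon hit for that gene
    if (length(intron_genes)) cl <- c(cl, "intron")
    g <- unique(c(prom_hits[[i]], body_hits[[i]]))
    if (length(cl) == 0L) cl <- "intergenic"
    classes[i] <- paste(cl, collapse = ",")
    gene_ids[i] <- paste(g, collapse = ",")
    primary[i] <- intersect(
      c("promoter", "exon", "intron", "intergenic"), cl
    )[1L]
  }
  data.frame(
    classes = classes, genes = gene_ids, primary = primary,
    stringsAsFactors = FALSE
  )
}

#' Map regions to the genes they hit
#'
#' Unique gene ids whose body or promoter overlaps at least one region.
#' When a second region set is supplied, the genes carrying both region
#' types are also reported.
#'
#' @param regions BED-like data.frame.
#' @param genes gene models (see [genic_annotate()]).
#' @param regions2 optional second region set (e.g. the other modality).
#' @param promoter_len promoter length in bp.
#' @return list with `genes` (character vector), and when `regions2` is
#'   given also `genes2` and `shared`.
#' @export
regions_to_genes <- function(regions, genes, regions2 = NULL,
                             promoter_len = 1000L) {
  one <- function(reg) {
    if (nrow(reg) == 0L) return(character(0))
    ann <- genic_annotate(reg, genes, promoter_len = promoter_len)
    ids <- unlist(strsplit(ann$genes[nzchar(ann$genes)], ",", fixed = TRUE))
    sort(unique(ids))
  }
  g1 <- one(regions)
  if (is.null(regions2)) {
    return(list(genes = g1))
  }
  g2 <- one(regions2)
  list(genes = g1, genes2 = g2, shared = intersect(g1, g2))
}
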
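# Hypergeometric gene-set enrichment, Fisher tissue enrichment and the
# set-overlap test.

# Upper-tail hypergeometric probability P(X >= k) for overlap k between a
# query of size q and a set of size m inside a universe of size N.
hyper_upper <- function(k, q, m, N) {
  stats::phyper(k - 1, m, N - m, q, lower.tail = FALSE)
}

hyper_two_sided <- function(k, q, m, N) {
  up <- hyper_upper(k, q, m, N)
  lo <- stats::phyper(k, m, N - m, q)
  pmin(1, 2 * pmin(up, lo))
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation in the query by the
#' upper-tail hypergeometric probability `P(X >= k)`; a two-sided version
#' (doubled smaller tail, capped at 1) is available. P-values are BH
#' adjusted across sets.
#'
#' @param query_genes character vector (must lie in the universe).
#' @param gene_sets named list of character vectors (subsets of the
#'   universe).
#' @param universe character vector of all genes, or a single integer
#'   universe size (then set/query membership is taken at face value).
#' @param alternative `"greater"` (default, over-representation) or
#'   `"two.sided"`.
#' @return data.frame: `set, overlap, query_size, set_size, universe, p,
#'   padj`, ordered as supplied.
#' @export
hypergeom_enrich <- function(query_genes, gene_sets, universe,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.character(universe)) {
    if (!all(query_genes %in% universe)) {
      stop("query genes must be contained in the universe")
    }
    N <- length(unique(universe))
  } else {
    N <- as.integer(universe)
  }
  q <- length(unique(query_genes))
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(gene_sets[[nm]])
    m <- length(set)
    if (m > N) stop(sprintf("gene set '%s' larger than the universe", nm))
    k <- length(intersect(unique(query_genes), set))
    p <- if (alternative == "greater") {
      hyper_upper(k, q, m, N)
    } else {
      hyper_two_sided(k, q, m, N)
    }
    data.frame(
      set = nm, overlap = k, query_size = q, set_size = m,
      universe = N, p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, "BH")
  out
}

#' Fisher's exact tissue enrichment
#'
#' One 2x2 Fisher's exact test per tissue panel (upper tail:
#' over-representation of panel genes in the query), with the sample odds
#' ratio and BH adjustment across tissues. Empty panels are skipped with a
#' warning.
#'
#' @param query_genes character vector.
#' @param tissue_panels named list of character vectors.
#' @param universe character vector of background genes (panels must be
#'   subsets).
#' @return data.frame: `tissue, overlap, panel_size, query_size, universe,
#'   odds_ratio, p, padj`.
#' @export
fisher_tissue_enrich <- function(query_genes, tissue_panels, universe) {
  N <- length(unique(universe))
  query <- unique(query_genes)
  q <- length(query)
  rows <- lapply(names(tissue_panels), function(nm) {
    panel <- unique(tissue_panels[[nm]])
    if (length(panel) == 0L) {
      warning(sprintf("empty tissue panel '%s' skipped", nm))
      return(NULL)
    }
    m <- length(panel)
    k <- length(intersect(query, panel))
    tab <- matrix(c(k, m - k, q - k, N - m - q + k), 2L)
    ft <- stats::fisher.test(tab, alternative = "greater")
    or <- (k * (N - m - q + k)) / ((m - k) * (q - k))
    data.frame(
      tissue = nm, overlap = k, panel_size = m, query_size = q,
      universe = N, odds_ratio = or, p = ft$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$padj <- stats::p.adjust(out$p, "BH")
  out
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail probability of observing at least the seen intersection of
#' two gene lists drawn from a common universe.
#'
#' @param genes_a,genes_b character vectors.
#' @param universe_size integer universe size.
#' @return list with `overlap`, `p`.
#' @export
overlap_test <- function(genes_a, genes_b, universe_size) {
  a <- unique(genes_a)
  b <- unique(genes_b)
  k <- length(intersect(a, b))
  list(
    overlap = k,
    p = hyper_upper(k, length(a), length(b), universe_size)
  )
}
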
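# CpG/genic annotation, region-to-gene mapping, hypergeometric and Fisher
# enrichment.

test_that("CpG classes follow island/shore/shelf rings by midpoint distance", {
  islands <- data.frame(chrom = "chr1", start = 10000L, end = 10500L)
  regions <- data.frame(
    chrom = "chr1",
    start = c(10200L, 11000L, 13000L, 30000L),
    end = c(10400L, 11200L, 13100L, 30200L)
  )
  expect_identical(
    cpg_annotate(regions, islands),
    c("island", "shore", "shelf", "interCGI")
  )
  # no islands at all
  expect_identical(
    cpg_annotate(regions, islands[0, ]),
    rep("interCGI", 4)
  )
  # annotation independent of region order
  perm <- c(3, 1, 4, 2)
  expect_identical(
    cpg_annotate(regions[perm, ], islands),
    cpg_annotate(regions, islands)[perm]
  )
})

test_that("genic annotation is strand-aware and supports multiple classes", {
  genes <- data.frame(
    id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
    tss = c(5000L, 20000L),
    span_start = c(5000L, 12000L), span_end = c(9000L, 20001L),
    exons = c("5000-5400,7000-7400", "12000-12500,19500-20001"),
    gene_type = "protein_coding", stringsAsFactors = FALSE
  )
  regions <- data.frame(
    chrom = "chr1",
    start = c(4200L, 6000L, 5100L, 50000L, 20500L),
    end = c(4600L, 6400L, 5200L, 50200L, 20700L)
  )
  ann <- genic_annotate(regions, genes)
  expect_identical(ann$primary[1], "promoter") # upstream of + TSS
  expect_identical(ann$primary[2], "intron") # body, no exon
  expect_identical(ann$primary[3], "exon")
  expect_identical(ann$primary[4], "intergenic")
  expect_identical(ann$primary[5], "promoter") # downstream of - TSS
  expect_identical(ann$genes[2], "gA")
  expect_identical(ann$genes[4], "")

  g <- small_genome()
  bad <- genes
  bad$tss[1] <- 1e9
  expect_error(genic_annotate(regions, bad, genome = g), "TSS")
})

test_that("regions map to unique genes with shared-set reporting", {
  genes <- data.frame(
    id = c("gA", "gB", "gC"), chrom = "chr1", strand = "+",
    tss = c(1000L, 20000L, 40000L),
    span_start = c(1000L, 20000L, 40000L),
    span_end = c(5000L, 25000L, 45000L),
    exons = c("1000-1200", "20000-20200", "40000-40200"),
    gene_type = "protein_coding", stringsAsFactors = FALSE
  )
  dmr <- data.frame(
    chrom = "chr1", start = c(1500L, 2500L, 21000L), end = c(1600L, 2600L, 21100L)
  )
  dhmr <- data.frame(chrom = "chr1", start = c(22000L, 41000L), end = c(22100L, 41100L))
  out <- regions_to_genes(dmr, genes, regions2 = dhmr)
  expect_identical(out$genes, c("gA", "gB")) # gA once despite two regions
  expect_identical(out$genes2, c("gB", "gC"))
  expect_identical(out$shared, "gB")
  expect_identical(regions_to_genes(dmr[0, ], genes)$genes, character(0))
})

# exhaustive hypergeometric tail by enumeration (oracle for small N)
enum_upper_tail <- function(k, q, m, N) {
  sum(vapply(k:min(q, m), function(i) {
    choose(m, i) * choose(N - m, q - i)
  }, numeric(1))) / choose(N, q)
}

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # worked case: N=20, set 5, query 4, overlap 3 -> 155/4845
  expect_equal(enum_upper_tail(3, 4, 5, 20), 155 / 4845)
  universe <- sprintf("g%02d", 1:20)
  sets <- list(s1 = universe[1:5])
  query <- c(universe[1:3], universe[10])
  res <- hypergeom_enrich(query, sets, universe)
  expect_equal(res$p, 155 / 4845)
  expect_identical(res$overlap, 3L)

  # random instances vs enumeration for N <= 30
  set.seed(141)
  for (i in 1:20) {
    N <- sample(10:30, 1)
    uni <- sprintf("x%02d", 1:N)
    m <- sample(2:(N - 2), 1)
    q <- sample(2:(N - 2), 1)
    set <- sample(uni, m)
    qry <- sample(uni, q)
    k <- length(intersect(set, qry))
    res <- hypergeom_enrich(qry, list(a = set), uni)
    expect_equal(res$p, enum_upper_tail(k, q, m, N), tolerance = 1e-12)
  }

  # zero overlap with a tiny set: p near 1
  r0 <- hypergeom_enrich(universe[6:9], list(s = universe[1:2]), universe)
  expect_gt(r0$p, 0.5)
  # query = universe: k = set size, upper tail = 1
  rall <- hypergeom_enrich(universe, list(s = universe[1:5]), universe)
  expect_identical(rall$overlap, 5L)
  expect_equal(rall$p, 1)
  expect_error(
    hypergeom_enrich(universe[1:2], list(s = c(universe, "zz")), universe),
    "larger than the universe"
  )
})

test_that("Fisher tissue enrichment reports the sample odds ratio", {
  universe <- sprintf("g%03d", 1:100)
  query <- universe[1:5]
  panel <- list(brain = universe[c(1:3, 20:26)]) # 3 of 5 in a 10-gene panel
  res <- fisher_tissue_enrich(query, panel, universe)
  expect_equal(res$odds_ratio, (3 * 88) / (2 * 7), tolerance = 1e-12)
  expect_equal(res$p, enum_upper_tail(3, 5, 10, 100), tolerance = 1e-9)

  # disjoint query: depleted direction
  res0 <- fisher_tissue_enrich(universe[50:54], panel, universe)
  expect_lt(res0$odds_ratio, 1)
  expect_gte(res0$p, 0.5)

  # enlarging the universe with irrelevant genes sharpens the enrichment
  res_big <- fisher_tissue_enrich(
    query, panel, c(universe, sprintf("h%03d", 1:100))
  )
  expect_lt(res_big$p, res$p)

  expect_warning(
    fisher_tissue_enrich(query, list(empty = character(0)), universe),
    "empty"
  )
})

test_that("overlap test and BH adjustment behave as step-up from scratch", {
  universe <- sprintf("g%02d", 1:20)
  a <- universe[1:5]
  b <- universe[c(1:3, 10)]
  expect_equal(overlap_test(a, b, 20)$p, 155 / 4845)
  expect_equal(overlap_test(a, a, 20)$overlap, 5L)
  big <- sprintf("u%04d", 1:5000)
  expect_gt(overlap_test(big[1:5], big[100:104], 5000)$p, 0.99)

  # BH equals the step-up formula recomputed by hand
  set.seed(142)
  p <- runif(25)
  bh <- p.adjust(p, "BH")
  o <- order(p)
  manual <- rev(cummin(rev(p[o] * 25 / seq_len(25))))
  expect_equal(bh[o], pmin(manual, 1))
  expect_true(all(bh >= p))
})
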
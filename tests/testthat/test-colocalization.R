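# Overlap with GWAS loci, region-SNP distances, randomized-SNP null and
# the SCZ-specific variant rules.

test_that("colocalization uses half-open 1 bp overlap semantics", {
  loci <- data.frame(
    chrom = "chr1", start = c(550L, 600L), end = c(800L, 800L),
    lead_pos = c(600L, 700L), label = c("l1", "l2")
  )
  region <- data.frame(chrom = "chr1", start = 100L, end = 600L)
  out <- colocalize(region, loci)
  expect_identical(out$pairs$label, "l1") # [100,600) misses [600,800)
  expect_identical(out$n_regions, 1L)

  # one region inside two overlapping loci: two pairs, one distinct region
  loci2 <- data.frame(
    chrom = "chr1", start = c(0L, 50L), end = c(1000L, 900L),
    lead_pos = c(10L, 60L), label = c("a", "b")
  )
  out2 <- colocalize(region, loci2)
  expect_identical(nrow(out2$pairs), 2L)
  expect_identical(out2$n_regions, 1L)
})

test_that("region-SNP distance matches the brute-force base-level minimum", {
  expect_identical(region_snp_distance(1000L, 1500L, 1200L), 0L)
  expect_identical(region_snp_distance(1000L, 1500L, 1600L), 101L)
  expect_identical(region_snp_distance(1000L, 1500L, 999L), 1L)

  set.seed(151)
  for (i in 1:1000) {
    st <- sample.int(10000, 1)
    en <- st + sample.int(500, 1)
    pos <- sample.int(11000, 1)
    brute <- min(abs(seq(st, en - 1L) - pos))
    expect_identical(as.integer(region_snp_distance(st, en, pos)), brute)
  }
})

test_that("null placement is deterministic, respects masks and matches the
           closed-form mean distance", {
  g <- small_genome()
  regions <- data.frame(chrom = "chr1", start = 50000L, end = 51000L)
  n1 <- simulate_snp_null(3, g, 20, regions, reps = 2)
  n2 <- simulate_snp_null(3, g, 20, regions, reps = 2)
  expect_identical(n1, n2)

  # no simulated SNP lands in masked bases
  mask <- rbind(
    g$dark_regions[, c("chrom", "start", "end")],
    g$low_mappability[, c("chrom", "start", "end")]
  )
  nl <- simulate_snp_null(4, g, 200, regions, reps = 1)
  pos <- nl$positions
  for (i in seq_len(nrow(mask))) {
    inside <- pos$chrom == mask$chrom[i] &
      pos$pos >= mask$start[i] & pos$pos < mask$end[i]
    expect_false(any(inside))
  }

  # closed-form expected distance on an unmasked 1 Mb chromosome with one
  # 1 kb region: integrate distance over uniform placement
  g1 <- simulate_genome(5,
    n_chrom = 1L, lengths = 1e6,
    low_map_fraction = 0, dark_fraction = 0
  )
  reg <- data.frame(chrom = "chr1", start = 400000L, end = 401000L)
  # left flank distances 1..400000, right flank 1..599000, inside 0
  L <- 1e6
  exact <- (sum(as.numeric(1:400000)) + sum(as.numeric(1:599000))) / L
  nl2 <- simulate_snp_null(6, g1, 10000, reg, reps = 1)
  expect_equal(mean(nl2$distances), exact, tolerance = 0.05 * exact)

  # regions tiling the genome give all-zero distances
  tile <- data.frame(chrom = "chr1", start = 0L, end = 1e6)
  expect_true(all(simulate_snp_null(7, g1, 50, tile, reps = 2)$distances == 0))
})

test_that("proximity test separates planted SNPs and stays calibrated", {
  # extreme separation
  pt <- test_proximity(rep(0, 40), rpois(200, 5000) + 1)
  expect_lt(pt$p, 1e-6)

  # observed equal to the null sample: p about one half
  set.seed(161)
  null <- rexp(500, 1 / 1000)
  pt2 <- test_proximity(null, null)
  expect_equal(pt2$p, 0.5, tolerance = 0.05)

  # observed drawn from the null distribution: uniform p
  rejections <- vapply(1:200, function(i) {
    obs <- sample(null, 30)
    test_proximity(obs, null)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.01)
  expect_lte(mean(rejections), 0.09)

  expect_error(test_proximity(numeric(0), null), "non-empty")
})

test_that("specific variant rules enforce quality, identity and exclusivity", {
  lead <- data.frame(chrom = "chr1", lead_pos = 100L, ref = "C", alt = "T")
  scz <- data.frame(
    chrom = "chr1", pos = c(100L, 100L, 100L, 200L),
    ref = c("C", "C", "C", "C"), alt = c("T", "T", "T", "T"),
    qual = c(50, 20, 50, 50), depth = c(40, 40, 20, 40)
  )
  hc <- scz[0, ]
  out <- specific_variants(scz, hc, lead)
  expect_identical(nrow(out), 1L) # only the qual>30, depth>30, lead-matching call
  expect_identical(out$pos, 100L)

  # same call in HC excludes it
  out2 <- specific_variants(scz, scz[1, ], lead)
  expect_identical(nrow(out2), 0L)

  # strict thresholds: qual or depth exactly 30 are excluded
  border <- data.frame(
    chrom = "chr1", pos = 100L, ref = "C", alt = "T", qual = 30, depth = 31
  )
  expect_identical(nrow(specific_variants(border, hc, lead)), 0L)

  expect_error(
    specific_variants(
      data.frame(chrom = "chr1", pos = 1L, ref = "", alt = "T", qual = 50, depth = 50),
      hc, lead
    ),
    "malformed"
  )
})

test_that("planted lead SNPs are detected and unplanted ones are calibrated", {
  g <- small_genome()
  regions <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 5),
    start = rep(seq(20000, 180000, length.out = 5), 2)
  )
  regions$start <- as.integer(regions$start)
  regions$end <- regions$start + 500L

  sn1 <- simulate_snp_loci(21, g, regions = regions, n_loci = 25, planted_fraction = 1)
  obs1 <- proximity_distances(regions, sn1$loci)
  null <- simulate_snp_null(22, g, 25, regions, reps = 200)
  expect_lt(test_proximity(obs1, null$distances)$p, 0.01)

  hits <- vapply(1:20, function(s) {
    sn0 <- simulate_snp_loci(100 + s, g,
      regions = regions, n_loci = 25,
      planted_fraction = 0
    )
    obs0 <- proximity_distances(regions, sn0$loci)
    test_proximity(obs0, null$distances)$p > 0.05
  }, logical(1))
  expect_gte(sum(hits), 16L)
})
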
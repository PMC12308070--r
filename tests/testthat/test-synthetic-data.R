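# Generator contracts: determinism, masked fractions, injected effects.

test_that("genome generation is deterministic and respects mask fractions", {
  g1 <- simulate_genome(1, n_chrom = 1L, lengths = 1e6, dark_fraction = 0)
  g2 <- simulate_genome(1, n_chrom = 1L, lengths = 1e6, dark_fraction = 0)
  expect_identical(g1, g2)
  expect_identical(nrow(g1$dark_regions), 0L)

  g <- simulate_genome(2, n_chrom = 1L, lengths = 5e6, low_map_fraction = 0.1)
  frac <- sum(g$low_mappability$end - g$low_mappability$start) / 5e6
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)

  expect_error(simulate_genome(1, lengths = -5), "10 kb")
})

test_that("genome intervals are within bounds and islands disjoint", {
  g <- small_genome()
  lens <- setNames(g$chromosomes$length, g$chromosomes$name)
  for (trk in list(g$cpg_islands, g$low_mappability, g$dark_regions)) {
    expect_true(all(trk$start >= 0))
    expect_true(all(trk$end <= lens[trk$chrom]))
    expect_true(all(trk$end > trk$start))
  }
  isl <- g$cpg_islands[order(g$cpg_islands$chrom, g$cpg_islands$start), ]
  same <- isl$chrom[-1] == isl$chrom[-nrow(isl)]
  expect_true(all(isl$start[-1][same] >= isl$end[-nrow(isl)][same]))
  # exons inside gene span
  for (i in seq_len(nrow(g$genes))) {
    ex <- cfepiscan:::parse_exons(g$genes$exons[i])
    expect_true(all(ex$start >= g$genes$span_start[i]))
    expect_true(all(ex$end <= g$genes$span_end[i]))
  }
})

test_that("cohort has the study layout and severity-linked scores", {
  co <- simulate_cohort(5)
  expect_identical(sum(co$group == "HC"), 77L)
  expect_identical(sum(co$group == "SCZ"), 66L)
  expect_identical(sum(co$has_imaging & co$group == "HC"), 68L)
  expect_identical(sum(co$has_imaging & co$group == "SCZ"), 59L)
  expect_true(all(co$age > 0))
  # monotone construction gives known correlation signs
  expect_gt(cor(co$severity, co$panss_total, method = "spearman"), 0)
  expect_lt(cor(co$severity, co$bacs_z, method = "spearman"), 0)
  expect_error(simulate_cohort(1, n_hc = 5, n_imaging_hc = 10), "imaging")
})

test_that("count generator hits its injected group effects", {
  co <- full_cohort()
  # null generator: per-window group-mean ratios concentrate at 1
  sim0 <- simulate_counts(21, co,
    n_windows = 400, n_true = 0, lfc_magnitude = 0
  )
  grp <- co$group == "SCZ"
  ratio <- rowMeans(sim0$counts[, grp]) / rowMeans(sim0$counts[, !grp])
  expect_gt(median(ratio), 0.95)
  expect_lt(median(ratio), 1.05)

  # truth windows with lfc +1 double the group mean (Monte-Carlo over draws)
  ratios <- vapply(1:200, function(s) {
    sim <- simulate_counts(s, co,
      n_windows = 5, n_true = 4, lfc_magnitude = 1,
      covariate_effects = list(age = 0, gender = 0, batch = 0)
    )
    up <- sim$truth$window[sim$truth$lfc > 0]
    mean(rowMeans(sim$counts[up, grp, drop = FALSE]) /
      rowMeans(sim$counts[up, !grp, drop = FALSE]))
  }, numeric(1))
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)

  # method-of-moments dispersion recovers the generating value
  simd <- simulate_counts(22, co,
    n_windows = 2000, n_true = 0,
    dispersion = 0.2,
    covariate_effects = list(age = 0, gender = 0, batch = 0)
  )
  Q <- simd$counts
  mom <- (apply(Q, 1, var) - rowMeans(Q)) / rowMeans(Q)^2
  expect_gt(median(mom), 0.15)
  expect_lt(median(mom), 0.25)

  expect_error(
    simulate_counts(1, co, n_windows = 10, n_true = 10),
    "n_true"
  )
  expect_error(simulate_counts(1, co, n_windows = 0), "zero windows")
})

test_that("fragment generator peaks at the mono-nucleosomal length", {
  co <- small_cohort()
  g <- small_genome()
  mx <- cfepiscan:::default_mixture()

  # degenerate mixture: all mass on the 166 bp component with zero spread
  mx0 <- mx
  mx0$weights <- c(short = 0, mono = 1, long = 0)
  mx0$sds <- c(short = 0, mono = 0, long = 0)
  mx0$scz_shift <- c(short = 0, mono = 0, long = 0)
  mx0$weight_noise_sd <- 0
  fr0 <- simulate_fragments(31, co, g,
    depth = 200, mixture = mx0,
    outlier_fraction = 0, chrx_fraction = 0
  )
  expect_true(all(fr0$fragments$end - fr0$fragments$start == 166))

  # default mixture: pooled histogram argmax at 166
  fr <- simulate_fragments(32, co, g, depth = 4000)
  len <- with(filter_fragments(fr$fragments)$fragments, end - start)
  expect_equal(which.max(tabulate(len)), 166)

  # per-sample fragment count equals requested depth
  expect_true(all(table(fr$fragments$sample) == 4000))

  # lowering the SCZ short weight flips the group fraction difference sign
  mx2 <- mx
  mx2$scz_shift <- c(short = -0.05, mono = 0.025, long = 0.025)
  fr2 <- simulate_fragments(33, co, g, depth = 4000, mixture = mx2)
  filt <- filter_fragments(fr2$fragments)$fragments
  fs <- vapply(split(filt$end - filt$start, filt$sample), function(l) {
    length_fractions(l)[["f_short"]]
  }, numeric(1))
  grp <- co$group[match(names(fs), co$id)]
  expect_lt(mean(fs[grp == "SCZ"]) - mean(fs[grp == "HC"]), 0)

  expect_error(simulate_fragments(1, co, g, depth = -5), "depth")
})

test_that("brain measure generator plants atrophy and latent links", {
  co <- full_cohort()
  img <- co[co$has_imaging, ]

  # zero effect: group test flags at about the nominal rate
  bm0 <- simulate_brain_measures(41, co, n_measures = 100, effect_size = 0)
  adj <- residualize_measures(
    bm0$measures, bm0$classes,
    img[, c("age", "gender", "icv")]
  )
  raw_p <- vapply(seq_len(ncol(adj)), function(j) {
    suppressWarnings(wilcox.test(
      adj[img$group == "SCZ", j], adj[img$group == "HC", j],
      exact = FALSE
    ))$p.value
  }, numeric(1))
  expect_lte(mean(raw_p < 0.05), 0.1)

  # zero link strength: region-measure correlations are null
  rv <- matrix(rnorm(nrow(img) * 5), nrow(img))
  lm0 <- data.frame(region = 1:5, measure = 1:5, strength = 0)
  bml <- simulate_brain_measures(42, co,
    n_measures = 50, effect_size = 0,
    link_map = lm0, region_values = rv
  )
  rho <- abs(cor(rv, bml$measures, method = "spearman"))
  expect_lt(median(rho), 0.1)

  # pure ICV loading: residualization removes nearly all variance
  bmi <- simulate_brain_measures(43, co,
    n_measures = 20, n_affected = 0, effect_size = 0,
    loadings = list(age = 0, gender = 0, icv = 10)
  )
  adj2 <- residualize(
    bmi$measures[, 1], cbind(icv = img$icv),
    add_back_median = FALSE
  )
  expect_gte(1 - var(adj2) / var(bmi$measures[, 1]), 0.95)

  expect_error(
    simulate_brain_measures(1, co,
      n_measures = 10, n_affected = 22
    ),
    "n_affected"
  )
  expect_error(
    simulate_brain_measures(1, co,
      link_map = data.frame(region = 9, measure = 1, strength = 1),
      region_values = matrix(0, nrow(img), 2)
    ),
    "absent regions"
  )
})

test_that("snp locus generator plants leads and exclusive variants", {
  g <- small_genome()
  regions <- data.frame(
    chrom = "chr1", start = c(10000, 50000, 90000),
    end = c(10500, 50500, 90500)
  )
  sn <- simulate_snp_loci(51, g,
    regions = regions, n_loci = 12,
    planted_fraction = 1, n_scz_exclusive = 3
  )
  d <- proximity_distances(regions, sn$loci)
  # every lead SNP sits inside a region
  obs <- cfepiscan:::snp_nearest_region(
    data.frame(chrom = sn$loci$chrom, pos = sn$loci$lead_pos), regions
  )
  expect_true(all(obs == 0))
  expect_true(all(sn$loci$lead_pos >= sn$loci$start &
    sn$loci$lead_pos < sn$loci$end))

  sv <- specific_variants(sn$calls_scz, sn$calls_hc, sn$loci)
  expect_identical(nrow(sv), 3L)

  expect_error(
    simulate_snp_loci(1, g, planted_fraction = 1.5),
    "planted_fraction"
  )
})

test_that("generators are byte-deterministic for a fixed seed", {
  co <- small_cohort()
  g <- small_genome()
  expect_identical(
    simulate_fragments(7, co, g, depth = 100),
    simulate_fragments(7, co, g, depth = 100)
  )
  expect_identical(
    simulate_counts(7, co, n_windows = 50, n_true = 5),
    simulate_counts(7, co, n_windows = 50, n_true = 5)
  )
  expect_identical(
    simulate_brain_measures(7, co, n_measures = 30),
    simulate_brain_measures(7, co, n_measures = 30)
  )
})
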
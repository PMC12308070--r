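# End-to-end orchestration of the synthetic benchmark: generate a bundle,
# run every analysis stage in dependency order, and write a reproducible
# report directory with a manifest.

#' Default pipeline configuration
#'
#' All randomness is funneled through one master seed; per-stage seeds are
#' derived deterministically from it. Sizes default to a desk-scale bundle
#' (two 0.6 Mb chromosomes, about 4,800 windows per modality, 2,000
#' fragments per sample) that preserves the statistical structure of the
#' full design: 77 HC vs 66 SCZ, imaging subset 68/59, 60 injected
#' differential windows per modality, 305 brain measures with 22 atrophic
#' ones and 5 linked region-measure blocks, 30 GWAS loci half planted in
#' 5hmC regions.
#'
#' @param seed master seed.
#' @param out_dir output directory for the report bundle.
#' @param ... named overrides of top-level config entries (lists are
#'   replaced wholesale).
#' @return config list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("cfepiscan_"), ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    genome = list(
      n_chrom = 2L, lengths = 6e5, island_rate = 1 / 50000,
      low_map_fraction = 0.05, dark_fraction = 0.02
    ),
    cohort = list(
      n_hc = 77L, n_scz = 66L, n_imaging_hc = 68L, n_imaging_scz = 59L
    ),
    fragments = list(depth = 2000L, outlier_fraction = 0.01, chrx_fraction = 0.01),
    counts = list(
      n_true = 60L, lfc_magnitude = 1, dispersion = 0.1,
      covariate_effects = list(age = 0.005, gender = 0.05, batch = 0.1)
    ),
    windows = list(
      w = 500L, s = 250L, map_threshold = 0.9,
      min_count = 3L, min_samples = 10L
    ),
    calling = list(p_thresh = 5e-4, lfc_thresh = 0.5, power_alpha = 0.005),
    coloc = list(
      n_loci = 30L, planted_fraction = 0.5, reps = 200L,
      n_scz_exclusive = 3L
    ),
    brain = list(
      n_measures = 305L, n_affected = 22L, effect_size = 2,
      n_blocks = 5L, block_regions = 6L, link_strength = 1.5,
      count_threshold = c("5mC" = 5L, "5hmC" = 10L), fdr = 0.05
    ),
    scca = list(K = 3L, n_perm = 10L, grid_fractions = c(0.3, 0.5, 0.7)),
    severity = list(folds = 3L, repeats = 10L),
    stages = c(
      "synthetic_data", "fragments_qc", "window_counts", "differential",
      "annotation_enrichment", "colocalization", "brain_association",
      "severity_model"
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

pipe_log <- function(...) message(sprintf(...))

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic-benchmark pipeline
#'
#' Executes the stages in dependency order (synthetic data, fragment QC,
#' window counting, differential calling per modality, annotation and
#' enrichment, GWAS-locus colocalization, brain association, severity
#' model), writing tables and JSON summaries under `config$out_dir` plus a
#' manifest. Identical config and seed produce byte-identical numeric
#' outputs. If the cohort has no imaging samples the brain-association
#' stage is skipped with an explicit log line.
#'
#' @param config list from [pipeline_config()].
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- Sys.time()
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(
    package = "cfepiscan",
    version = as.character(utils::packageVersion("cfepiscan")),
    seed = seed, stages = list()
  )
  res <- list()
  stage_done <- function(name, counts) {
    manifest$stages[[name]] <<- counts
    pipe_log("[%s] done", name)
  }

  ## ---- synthetic_data ----------------------------------------------------
  pipe_log("[synthetic_data] generating bundle (seed %d)", seed)
  genome <- do.call(simulate_genome, c(
    list(seed = derive_seed(seed, "genome")), config$genome
  ))
  cohort <- do.call(simulate_cohort, c(
    list(seed = derive_seed(seed, "cohort")), config$cohort
  ))
  grid <- make_window_grid(genome, config$windows$w, config$windows$s)
  mask_md <- filter_windows(
    grid, genome$low_mappability, genome$dark_regions,
    genome = genome, map_threshold = config$windows$map_threshold
  )
  grid_kept <- grid[mask_md, , drop = FALSE]
  modalities <- c("5mC", "5hmC")
  frags <- list()
  counts <- list()
  for (mod in modalities) {
    frags[[mod]] <- simulate_fragments(
      seed = derive_seed(seed, paste0("frags_", mod)),
      cohort = cohort, genome = genome,
      depth = config$fragments$depth,
      outlier_fraction = config$fragments$outlier_fraction,
      chrx_fraction = config$fragments$chrx_fraction,
      modality = mod
    )
    counts[[mod]] <- simulate_counts(
      seed = derive_seed(seed, paste0("counts_", mod)),
      cohort = cohort, grid = grid_kept,
      dispersion = config$counts$dispersion,
      n_true = config$counts$n_true,
      lfc_magnitude = config$counts$lfc_magnitude,
      covariate_effects = config$counts$covariate_effects,
      modality = mod
    )
    write_bed(frags[[mod]]$fragments[, c("chrom", "start", "end", "sample")],
      file.path(out, sprintf("fragments_%s.bed", mod))
    )
    write_counts(counts[[mod]]$counts, grid_kept,
      file.path(out, sprintf("counts_%s.tsv", mod))
    )
    write_tsv(counts[[mod]]$truth, file.path(out, sprintf("truth_%s.tsv", mod)))
  }
  write_tsv(as.data.frame(cohort), file.path(out, "metadata.tsv"))
  write_bed(genome$cpg_islands, file.path(out, "cpg_islands.bed"))
  write_bed(genome$dark_regions, file.path(out, "dark_regions.bed"))
  write_bed(genome$low_mappability, file.path(out, "low_mappability.bed"))
  res$genome <- genome
  res$cohort <- cohort
  res$counts <- counts
  res$fragments <- frags
  stage_done("synthetic_data", list(
    samples = nrow(cohort), windows = nrow(grid_kept),
    fragments = nrow(frags[["5mC"]]$fragments)
  ))

  ## ---- fragments_qc ------------------------------------------------------
  qc <- list()
  for (mod in modalities) {
    filt <- filter_fragments(frags[[mod]]$fragments)
    tab <- fragment_qc_table(filt$fragments, frags[[mod]]$spike_in, mod)
    grp <- cohort$group[match(tab$sample, cohort$id)]
    cmp <- list(
      f_short = compare_groups(
        tab$f_short[grp == "HC"], tab$f_short[grp == "SCZ"]
      ),
      f_long = compare_groups(
        tab$f_long[grp == "HC"], tab$f_long[grp == "SCZ"]
      )
    )
    qc[[mod]] <- list(table = tab, removed = filt$removed, comparisons = cmp)
    write_tsv(tab, file.path(out, sprintf("qc_%s.tsv", mod)))
  }
  conc_cmp <- compare_groups(
    cohort$cfdna_conc[cohort$group == "HC"],
    cohort$cfdna_conc[cohort$group == "SCZ"]
  )
  write_json_file(
    list(
      concentration = conc_cmp,
      f_short_5mC = qc[["5mC"]]$comparisons$f_short,
      f_long_5mC = qc[["5mC"]]$comparisons$f_long,
      f_short_5hmC = qc[["5hmC"]]$comparisons$f_short,
      f_long_5hmC = qc[["5hmC"]]$comparisons$f_long
    ),
    file.path(out, "group_comparisons.json")
  )
  res$qc <- qc
  res$concentration <- conc_cmp
  stage_done("fragments_qc", list(
    samples = nrow(qc[["5mC"]]$table),
    removed_5mC = sum(qc[["5mC"]]$removed)
  ))

  ## ---- window_counts -----------------------------------------------------
  wc <- list()
  for (mod in modalities) {
    filt <- filter_fragments(frags[[mod]]$fragments)$fragments
    by_sample <- split(filt, filt$sample)
    Kf <- vapply(
      cohort$id,
      function(sid) {
        f <- by_sample[[sid]]
        if (is.null(f)) integer(nrow(grid_kept)) else count_fragments(grid_kept, f)
      },
      integer(nrow(grid_kept))
    )
    rownames(Kf) <- grid_kept$window
    lowcov <- low_coverage_filter(
      Kf, config$windows$min_count, config$windows$min_samples
    )
    wc[[mod]] <- list(counts = Kf, lowcov_mask = lowcov)
  }
  modcor <- modality_correlation(
    wc[["5mC"]]$counts, wc[["5hmC"]]$counts,
    groups = cohort$group
  )
  gfrac <- genome_fraction(grid, mask_md, genome)
  write_json_file(
    list(
      genome_fraction_windows = gfrac,
      modality_rho_median = as.list(modcor$summary),
      lowcov_retained_5mC = sum(wc[["5mC"]]$lowcov_mask),
      lowcov_retained_5hmC = sum(wc[["5hmC"]]$lowcov_mask)
    ),
    file.path(out, "window_summary.json")
  )
  res$window_counts <- wc
  res$modality_correlation <- modcor
  stage_done("window_counts", list(
    windows = nrow(grid_kept),
    retained_5mC = sum(wc[["5mC"]]$lowcov_mask)
  ))

  ## ---- differential ------------------------------------------------------
  diff <- list()
  regions <- list()
  for (mod in modalities) {
    X <- design_matrix(cohort, mod)
    dr <- diff_regions(
      counts[[mod]]$counts, X,
      p_thresh = config$calling$p_thresh,
      lfc_thresh = config$calling$lfc_thresh,
      power_alpha = config$calling$power_alpha
    )
    gi <- match(dr$window, grid_kept$window)
    dr$chrom <- grid_kept$chrom[gi]
    dr$start <- grid_kept$start[gi]
    dr$end <- grid_kept$end[gi]
    called <- dr[dr$call != "none", , drop = FALSE]
    diff[[mod]] <- dr
    regions[[mod]] <- called
    write_tsv(
      dr[, c(
        "window", "chrom", "start", "end", "base_mean", "log2fc",
        "lfcSE", "pvalue", "padj", "call", "power"
      )],
      file.path(out, sprintf("diff_%s.tsv", mod))
    )
  }
  stage_done("differential", list(
    called_5mC = nrow(regions[["5mC"]]), called_5hmC = nrow(regions[["5hmC"]])
  ))
  res$diff <- diff
  res$regions <- regions

  ## ---- annotation_enrichment ---------------------------------------------
  ann <- list()
  gene_lists <- list()
  for (mod in modalities) {
    reg <- regions[[mod]]
    if (nrow(reg)) {
      a <- data.frame(
        window = reg$window,
        cpg_class = cpg_annotate(reg, genome$cpg_islands),
        genic_annotate(reg, genome$genes, genome = genome),
        stringsAsFactors = FALSE
      )
    } else {
      a <- data.frame(
        window = character(0), cpg_class = character(0),
        classes = character(0), genes = character(0), primary = character(0)
      )
    }
    ann[[mod]] <- a
    write_tsv(a, file.path(out, sprintf("annotation_%s.tsv", mod)))
  }
  r2g <- regions_to_genes(
    regions[["5mC"]], genome$genes,
    regions2 = regions[["5hmC"]]
  )
  gene_lists <- r2g
  universe <- genome$genes$id
  # toy functional sets: gene-type panels plus chromosome panels
  gene_sets <- split(genome$genes$id, genome$genes$gene_type)
  enr <- hypergeom_enrich(r2g$genes, gene_sets, universe)
  tissue_panels <- split(genome$genes$id, genome$genes$chrom)
  tiss <- fisher_tissue_enrich(r2g$genes, tissue_panels, universe)
  ov <- overlap_test(r2g$genes, r2g$genes2, length(universe))
  write_tsv(enr, file.path(out, "enrichment_sets.tsv"))
  write_tsv(tiss, file.path(out, "enrichment_tissues.tsv"))
  res$annotation <- ann
  res$gene_lists <- gene_lists
  res$enrichment <- list(sets = enr, tissues = tiss, overlap = ov)
  stage_done("annotation_enrichment", list(
    genes_5mC = length(r2g$genes), genes_5hmC = length(r2g$genes2),
    shared = length(r2g$shared)
  ))

  ## ---- colocalization ----------------------------------------------------
  loci_regions <- if (nrow(regions[["5hmC"]])) regions[["5hmC"]] else grid_kept[1:10, ]
  snps <- simulate_snp_loci(
    seed = derive_seed(seed, "snps"), genome = genome,
    regions = loci_regions[, c("chrom", "start", "end")],
    n_loci = config$coloc$n_loci,
    planted_fraction = config$coloc$planted_fraction,
    n_scz_exclusive = config$coloc$n_scz_exclusive
  )
  coloc <- list()
  for (mod in modalities) {
    reg <- regions[[mod]]
    cl <- colocalize(reg, snps$loci)
    observed <- proximity_distances(reg, snps$loci)
    null <- simulate_snp_null(
      seed = derive_seed(seed, paste0("null_", mod)),
      genome = genome, n_snps = nrow(snps$loci),
      regions = reg[, c("chrom", "start", "end")],
      reps = config$coloc$reps
    )
    prox <- test_proximity(observed, null$distances)
    coloc[[mod]] <- list(pairs = cl, proximity = prox)
  }
  spec_var <- specific_variants(snps$calls_scz, snps$calls_hc, snps$loci)
  write_json_file(
    list(
      proximity_5mC = coloc[["5mC"]]$proximity,
      proximity_5hmC = coloc[["5hmC"]]$proximity,
      n_coloc_regions_5mC = coloc[["5mC"]]$pairs$n_regions,
      n_coloc_regions_5hmC = coloc[["5hmC"]]$pairs$n_regions,
      n_specific_variants = nrow(spec_var)
    ),
    file.path(out, "colocalization.json")
  )
  res$snps <- snps
  res$coloc <- coloc
  res$specific_variants <- spec_var
  stage_done("colocalization", list(
    loci = nrow(snps$loci), specific_variants = nrow(spec_var)
  ))

  ## ---- brain_association -------------------------------------------------
  if (!any(cohort$has_imaging)) {
    pipe_log("[brain_association] skipped: no imaging samples in cohort")
    manifest$stages[["brain_association"]] <- list(skipped = TRUE)
    res$brain <- NULL
  } else {
    img <- cohort[cohort$has_imaging, , drop = FALSE]
    s5 <- size_factors(counts[["5mC"]]$counts)
    vst5 <- vst_counts(counts[["5mC"]]$counts, s5)
    truth5 <- counts[["5mC"]]$truth
    n_link <- config$brain$n_blocks * config$brain$block_regions
    hyper <- truth5$window[truth5$lfc > 0]
    link_windows <- hyper[seq_len(min(n_link, length(hyper)))]
    region_vals_link <- t(vst5[link_windows, img$id, drop = FALSE])
    link_map <- data.frame(
      region = seq_along(link_windows),
      measure = rep(seq_len(config$brain$n_blocks),
        each = config$brain$block_regions
      )[seq_along(link_windows)],
      strength = config$brain$link_strength
    )
    bm <- simulate_brain_measures(
      seed = derive_seed(seed, "brain"),
      cohort = cohort,
      n_measures = config$brain$n_measures,
      n_affected = config$brain$n_affected,
      effect_size = config$brain$effect_size,
      link_map = link_map, region_values = region_vals_link
    )
    covs <- img[, c("age", "gender", "icv")]
    adj_meas <- residualize_measures(bm$measures, bm$classes, covs)
    gd <- group_difference(adj_meas, img$group, fdr = config$brain$fdr)
    atrophy <- gd$measure[gd$significant & gd$direction < 0]
    brain <- list(measures = bm, group_diff = gd, atrophy = atrophy)
    for (mod in modalities) {
      reg <- regions[[mod]]
      if (nrow(reg) < 2L) next
      vstm <- vst_counts(counts[[mod]]$counts)
      Xr <- t(vstm[reg$window, img$id, drop = FALSE])
      keep <- apply(Xr, 2L, stats::sd) > 0
      Xr <- residualize(
        Xr[, keep, drop = FALSE],
        cbind(age = img$age, gender = as.numeric(img$gender == "M"))
      )
      screen <- spearman_screen(
        Xr, adj_meas,
        count_threshold = config$brain$count_threshold[[mod]],
        fdr = config$brain$fdr
      )
      tune <- scca_tune(
        seed = derive_seed(seed, paste0("scca_", mod)),
        X = Xr, Z = adj_meas,
        grid = expand.grid(
          c1 = pmax(1, config$scca$grid_fractions * sqrt(ncol(Xr))),
          c2 = pmax(1, config$scca$grid_fractions * sqrt(ncol(adj_meas)))
        ),
        n_perm = config$scca$n_perm
      )
      fit <- pmd_scca(Xr, adj_meas,
        c1 = tune$c1, c2 = tune$c2,
        K = config$scca$K
      )
      inter <- intersect_findings(screen, fit$active_z, atrophy)
      brain[[mod]] <- list(
        screen = screen, tune = tune, scca = fit, intersection = inter
      )
      write_tsv(screen$pairs, file.path(out, sprintf("screen_pairs_%s.tsv", mod)))
      write_json_file(
        list(
          retained = screen$retained, scca_active = fit$active_z,
          reliable = inter$reliable, atrophy_flagged = inter$atrophy_flagged,
          penalties = list(c1 = tune$c1, c2 = tune$c2, z = tune$z)
        ),
        file.path(out, sprintf("brain_association_%s.json", mod))
      )
    }
    write_tsv(gd, file.path(out, "brain_group_diff.tsv"))
    res$brain <- brain
    stage_done("brain_association", list(
      imaging_samples = nrow(img),
      atrophy_measures = length(atrophy),
      reliable_5mC = length(brain[["5mC"]]$intersection$reliable %||% character(0))
    ))
  }

  ## ---- severity_model ----------------------------------------------------
  sev <- list()
  clinical <- data.frame(
    id = cohort$id,
    panss = cohort$panss_total,
    bacs_norm = residualize(
      cohort$bacs_z,
      cbind(age = cohort$age, gender = as.numeric(cohort$gender == "M"))
    )
  )
  for (mod in modalities) {
    reg <- regions[[mod]]
    if (nrow(reg) < 2L) next
    vstm <- vst_counts(counts[[mod]]$counts)
    feats <- t(vstm[reg$window, , drop = FALSE])
    fb <- fit_boosted_score(
      seed = derive_seed(seed, paste0("sev_", mod)),
      features = feats, labels = cohort$group,
      folds = config$severity$folds, repeats = config$severity$repeats
    )
    corr <- correlate_severity(fb$scores, clinical)
    sev[[mod]] <- list(model = fb, correlations = corr)
    write_tsv(
      data.frame(sample = names(fb$scores), score = unname(fb$scores)),
      file.path(out, sprintf("severity_scores_%s.tsv", mod))
    )
    write_tsv(corr, file.path(out, sprintf("severity_correlations_%s.tsv", mod)))
  }
  res$severity <- sev
  stage_done("severity_model", list(
    modalities = length(sev)
  ))

  manifest$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  write_json_file(manifest[c("package", "version", "seed", "stages")],
    file.path(out, "manifest.json")
  )
  res$manifest <- manifest
  pipe_log("pipeline complete: %d stages, %.1f s", length(manifest$stages),
    manifest$elapsed_sec)
  invisible(res)
}
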
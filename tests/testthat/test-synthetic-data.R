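test_that("identical config and seed reproduce both cohorts exactly", {
  cfg <- tiny_config(seed = 11)
  a <- generate_phenotype_cohort(cfg)
  b <- generate_phenotype_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$samples, b$samples)
  da <- generate_development_cohort(cfg)
  db <- generate_development_cohort(cfg)
  expect_identical(da$expression, db$expression)
})

test_that("zero noise with one cell type and constant fractions gives the deterministic profile", {
  cfg <- simulation_config(n_genes = 50, n_celltypes = 1,
                           signatures_per_celltype = 10, noise_sd = 0,
                           phenotype_effect = 0, seed = 2)
  out <- generate_phenotype_cohort(cfg)
  # a single cell type has fraction 1 in every sample, so the driver is zero
  # and every gene row is exactly its baseline, constant across samples
  expect_true(all(apply(out$expression, 1L, function(x) diff(range(x)) == 0)))
  dv <- generate_development_cohort(simulation_config(
    n_genes = 50, n_celltypes = 3, signatures_per_celltype = 10, noise_sd = 0,
    genotype_offsets = list(), seed = 2))
  # zero noise: group means equal the configured stage profiles exactly
  prof <- dv$truth$stage_profiles
  ct <- dv$truth$celltype_of_gene
  g <- names(ct)[ct == "fibroblast_ecm"][1]
  for (s in c("60dpc", "birth", "25mo")) {
    ids <- dv$samples$sample_id[dv$samples$stage == s]
    vals <- dv$expression[g, ids] - mean(dv$expression[g, ]) # remove baseline
    centered_prof <- prof["fibroblast_ecm", s] - mean(prof["fibroblast_ecm", ])
    expect_equal(unname(vals), rep(centered_prof, length(ids)), tolerance = 1e-12)
  }
})

test_that("generator rejects invalid configurations", {
  expect_error(simulation_config(phenotype_effect = 1), "0.999")
  expect_error(simulation_config(n_genes = -5), "n_genes")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
  expect_error(simulation_config(n_genes = 10, n_celltypes = 3,
                                 signatures_per_celltype = 10), "exceeds")
  bad_stages <- default_stages()
  bad_stages$age_days[3] <- -300
  expect_error(simulation_config(stages = bad_stages), "increasing")
})

test_that("per-sample latent fractions sum to one", {
  cfg <- tiny_config(seed = 3)
  ph <- generate_phenotype_cohort(cfg)
  expect_equal(unname(rowSums(ph$truth$true_fractions)),
               rep(1, nrow(ph$truth$true_fractions)), tolerance = 1e-12)
  dv <- generate_development_cohort(cfg)
  expect_equal(unname(rowSums(dv$truth$true_fractions)),
               rep(1, nrow(dv$truth$true_fractions)), tolerance = 1e-12)
})

test_that("signature genes reach the target phenotype correlation on average", {
  # Monte-Carlo oracle: mean empirical r of growth-program genes over
  # replicate cohorts should sit within +/- 0.05 of the 0.7 target
  rs <- vapply(1:200, function(s) {
    cfg <- simulation_config(n_genes = 60, n_celltypes = 3,
                             signatures_per_celltype = 10,
                             phenotype_effect = 0.7, noise_sd = 0.5, seed = s)
    out <- generate_phenotype_cohort(cfg)
    sig <- names(out$truth$celltype_of_gene)[
      out$truth$celltype_of_gene == out$truth$growth_celltype]
    y <- out$samples$adg_per_kg
    mean(apply(out$expression[sig, ], 1L, function(x) cor(x, y)))
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.7), 0.05)
})

test_that("configured genotype offsets are recovered as group mean differences", {
  diffs <- vapply(1:100, function(s) {
    cfg <- simulation_config(
      n_genes = 40, n_celltypes = 2, signatures_per_celltype = 10,
      noise_sd = 0.5, seed = s,
      genotype_offsets = list(fibroblast_ecm = c("12mo" = 1, "25mo" = 1)))
    dv <- generate_development_cohort(cfg)
    ct <- dv$truth$celltype_of_gene
    sig <- names(ct)[ct == "fibroblast_ecm"]
    sel_hi <- dv$samples$stage %in% c("12mo", "25mo") &
      dv$samples$genotype == "highmarble"
    sel_lo <- dv$samples$stage %in% c("12mo", "25mo") &
      dv$samples$genotype == "highmuscle"
    mean(dv$expression[sig, dv$samples$sample_id[sel_hi]]) -
      mean(dv$expression[sig, dv$samples$sample_id[sel_lo]])
  }, numeric(1))
  expect_equal(mean(diffs), 1, tolerance = 0.05)
})

test_that("zero offsets leave the genotypes symmetric in expectation", {
  diffs <- vapply(1:60, function(s) {
    cfg <- simulation_config(n_genes = 40, n_celltypes = 2,
                             signatures_per_celltype = 10, noise_sd = 0.5,
                             genotype_offsets = list(), seed = s)
    dv <- generate_development_cohort(cfg)
    hi <- dv$samples$genotype == "highmarble"
    mean(dv$expression[, dv$samples$sample_id[hi]]) -
      mean(dv$expression[, dv$samples$sample_id[!hi]])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("raising noise never raises the expected signature-gene correlation", {
  grid_mean_r <- vapply(c(0.3, 0.8, 1.5), function(sd) {
    mean(vapply(1:100, function(s) {
      cfg <- simulation_config(n_genes = 30, n_celltypes = 2,
                               signatures_per_celltype = 8,
                               phenotype_effect = 0.85, noise_sd = sd, seed = s)
      out <- suppressWarnings(generate_phenotype_cohort(cfg))
      sig <- names(out$truth$celltype_of_gene)[
        out$truth$celltype_of_gene == out$truth$growth_celltype]
      mean(apply(out$expression[sig, ], 1L, function(x) cor(x, out$samples$adg_per_kg)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(grid_mean_r) <= 0.02))
})

test_that("annotation terms mirror the planted programs and background terms stay null", {
  cfg <- tiny_config(seed = 5)
  ph <- generate_phenotype_cohort(cfg)
  ann0 <- generate_annotation(ph$truth, n_background_terms = 0)
  expect_length(ann0, 3)
  expect_length(unique(unlist(ann0)), sum(lengths(ann0)))  # disjoint
  ct <- ph$truth$celltype_of_gene
  for (t in setdiff(unique(ct), "background")) {
    expect_setequal(ann0[[paste0("PROG_", t)]], names(ct)[ct == t])
  }
  ann <- generate_annotation(ph$truth, n_background_terms = 20)
  planted <- names(ct)[ct != "background"]
  bg_terms <- ann[grepl("^BG", names(ann))]
  expect_false(any(unlist(bg_terms) %in% planted))
  expect_error(generate_annotation(ph$truth, term_size_range = c(5, 1e5)),
               "universe")
})

test_that("background terms do not enrich in ranked lists", {
  # simulation oracle across seeds: the median of the best background-term
  # p-value stays well above any significance threshold
  min_bg_p <- vapply(1:50, function(s) {
    cfg <- simulation_config(n_genes = 150, n_celltypes = 2,
                             signatures_per_celltype = 15, seed = s)
    ph <- generate_phenotype_cohort(cfg)
    ann <- generate_annotation(ph$truth, n_background_terms = 8,
                               term_size_range = c(5, 15))
    rk <- rank_by_correlation(ph$expression, ph$samples$adg_per_kg)
    en <- enrich_ranked_list(rk, ann, seed = s)
    bg <- en[grepl("^BG", en$term), ]
    min(bg$p)
  }, numeric(1))
  expect_gt(median(min_bg_p), 0.01)
})
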
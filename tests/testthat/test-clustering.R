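make_dev <- function(seed = 1, ...) {
  cfg <- tiny_config(seed = seed, ...)
  list(cfg = cfg, dv = generate_development_cohort(cfg))
}

test_that("the loose filter applies both sign rules", {
  x <- make_dev(seed = 31, n_genes = 400, n_celltypes = 2,
                signatures_per_celltype = 100, noise_sd = 0.4)
  dv <- x$dv
  # a flat zero-noise gene fails the strict decrease
  flat <- dv$expression
  flat["g00399", ] <- 5
  expect_false("g00399" %in% loose_coexpression_filter(flat, dv$samples))
  # a gene constructed to decrease after birth with positive offsets passes
  built <- dv$expression
  age <- dv$samples$age_days
  built["g00400", ] <- 8 - 0.002 * pmax(age, 0) +
    0.5 * (dv$samples$genotype == "highmarble" & dv$samples$stage %in% c("12mo", "25mo"))
  expect_true("g00400" %in% loose_coexpression_filter(built, dv$samples))
  expect_error(loose_coexpression_filter(dv$expression, dv$samples,
                                         stages_of_interest = "99mo"), "missing")
})

test_that("the loose filter recovers the planted ECM program", {
  x <- make_dev(seed = 33, n_genes = 800, n_celltypes = 4,
                signatures_per_celltype = 75)
  dv <- x$dv
  passed <- loose_coexpression_filter(dv$expression, dv$samples)
  ct <- dv$truth$celltype_of_gene
  ecm <- names(ct)[ct == "fibroblast_ecm"]
  # independent re-application of the two sign rules
  s <- dv$samples
  mean_at <- function(stage, genotype = NULL) {
    sel <- s$stage == stage
    if (!is.null(genotype)) sel <- sel & s$genotype == genotype
    rowMeans(dv$expression[, s$sample_id[sel], drop = FALSE])
  }
  oracle <- rownames(dv$expression)[
    mean_at("birth") > mean_at("30mo") &
      mean_at("12mo", "highmarble") > mean_at("12mo", "highmuscle") &
      mean_at("25mo", "highmarble") > mean_at("25mo", "highmuscle")]
  expect_setequal(passed, oracle)
  expect_gte(mean(ecm %in% passed), 0.9)
  # the pass set enriches for the planted ECM term
  ann <- generate_annotation(dv$truth, n_background_terms = 10)
  en <- enrich_cluster(intersect(passed, rownames(dv$expression)), ann,
                       rownames(dv$expression))
  expect_lt(en$q[en$term == "PROG_fibroblast_ecm"], 0.01)
})

test_that("estimate_k finds well-separated profile groups and handles degeneracy", {
  prof <- rbind(matrix(rep(c(2, 1, 0, -1), each = 10), nrow = 10, byrow = FALSE),
                matrix(rep(c(-2, 0, 2, 0), each = 10), nrow = 10, byrow = FALSE),
                matrix(rep(c(0, -1, 0, 1), each = 10), nrow = 10, byrow = FALSE))
  prof <- prof + matrix(rnorm(120, sd = 1e-6), nrow = 30)  # break exact ties
  rownames(prof) <- sprintf("g%02d", 1:30)
  expect_equal(estimate_k(prof, k_range = c(2, 6)), 3L)
  same <- matrix(1, nrow = 30, ncol = 4, dimnames = list(sprintf("g%02d", 1:30), NULL))
  expect_warning(k0 <- estimate_k(same, k_range = c(2, 6)), "identical")
  expect_equal(k0, 2L)
  expect_error(estimate_k(prof[1:5, ], k_range = c(2, 6)), "at least")
})

test_that("estimate_k recovers ten planted programs across seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 150, n_celltypes = 10,
                             signatures_per_celltype = 15, noise_sd = 0.3,
                             genotype_offsets = list(), seed = s)
    dv <- generate_development_cohort(cfg)
    z <- zscore_standardize(dv$expression)
    prof <- stage_profiles(z, dv$samples)
    estimate_k(prof, k_range = c(8, 13)) == 10L
  }, logical(1))
  expect_gte(sum(hits), 16)
})

test_that("k-means analyses partition the genes deterministically", {
  x <- make_dev(seed = 35)
  dv <- x$dv
  z <- zscore_standardize(dv$expression)
  a1 <- run_kmeans_analyses(z, dv$samples, ks = c(10, 13), seed = 4)
  a2 <- run_kmeans_analyses(z, dv$samples, ks = c(10, 13), seed = 4)
  expect_identical(lapply(a1, `[[`, "labels"), lapply(a2, `[[`, "labels"))
  expect_length(a1, 4)
  for (an in a1) {
    expect_setequal(names(an$labels), rownames(z))  # a partition
    expect_lte(max(an$labels), an$k)
  }
  # k = 1 puts every gene in a single cluster
  a3 <- run_kmeans_analyses(z, dv$samples, ks = 1, windows = "all", seed = 4)
  expect_true(all(a3[[1]]$labels == 1L))
})

test_that("zero-noise clustering recovers the planted grouping exactly", {
  cfg <- simulation_config(n_genes = 60, n_celltypes = 4,
                           signatures_per_celltype = 15, noise_sd = 0,
                           genotype_offsets = list(), seed = 37)
  dv <- generate_development_cohort(cfg)
  # all genes are signatures: 4 distinct noiseless profiles
  z <- zscore_standardize(dv$expression)
  an <- run_kmeans_analyses(z, dv$samples, ks = 4, windows = "all", seed = 6)[[1]]
  truth <- dv$truth$celltype_of_gene[names(an$labels)]
  expect_equal(adjusted_rand_index(an$labels, truth), 1)
})

test_that("adjusted Rand index matches the independent mclust oracle", {
  skip_if_not_installed("mclust")
  set.seed(39)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:5, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("cluster annotation keeps planted terms and drops random clusters", {
  x <- make_dev(seed = 41, n_genes = 500, n_celltypes = 4,
                signatures_per_celltype = 50, noise_sd = 0.3)
  dv <- x$dv
  ann <- generate_annotation(dv$truth, n_background_terms = 10)
  z <- zscore_standardize(dv$expression)
  analyses <- run_kmeans_analyses(z, dv$samples, seed = 8)
  annotated <- annotate_analyses(analyses, ann)
  # every planted program's term is retained in some cluster of each analysis
  for (i in seq_along(annotated)) {
    enriched_terms <- unlist(annotated[[i]]$enriched)
    expect_true(all(paste0("PROG_", c("fibroblast_ecm", "fap_cellcycle")) %in%
                      enriched_terms))
  }
  expect_warning(annotate_analyses(analyses, structure(list(), class = "gene_annotation")),
                 "empty")
})

test_that("consensus lists follow support counting and are monotone in min_support", {
  # hand-built annotated fixture: 4 analyses, term T enriched in specific clusters
  genes <- sprintf("g%d", 1:6)
  mk_analysis <- function(id, labels) {
    list(analysis_id = id, k = 2L, window = "all",
         labels = stats::setNames(labels, genes), centers = NULL,
         iterations = 1L, seed = 0L)
  }
  analyses <- list(
    A1 = mk_analysis("A1", c(1, 1, 1, 2, 2, 2)),
    A2 = mk_analysis("A2", c(1, 1, 1, 1, 2, 2)),
    A3 = mk_analysis("A3", c(1, 1, 2, 2, 2, 2)),
    A4 = mk_analysis("A4", c(1, 1, 1, 2, 2, 2)))
  annotated <- lapply(analyses, function(an) {
    list(analysis_id = an$analysis_id,
         enriched = list("1" = "T", "2" = character(0)), tables = list())
  })
  attr(annotated, "analyses") <- analyses
  ann <- structure(list(T = c("g1", "g2", "g3", "g4")),
                   descriptions = c(T = "term T"), class = "gene_annotation")
  # exhaustive support by hand: g1, g2 in cluster-1 all 4 times; g3: 3; g4: 1
  cg3 <- consensus_genes(annotated, ann, "T", min_support = 3)
  expect_setequal(as.character(cg3), c("g1", "g2", "g3"))
  expect_equal(unname(attr(cg3, "support")), c(4L, 4L, 3L, 1L))
  cg4 <- consensus_genes(annotated, ann, "T", min_support = 4)
  expect_setequal(as.character(cg4), c("g1", "g2"))
  expect_true(all(as.character(cg4) %in% as.character(cg3)))  # monotone
  # term enriched nowhere
  ann2 <- structure(list(U = c("g5", "g6")), descriptions = c(U = "u"),
                    class = "gene_annotation")
  expect_warning(cg0 <- consensus_genes(annotated, ann2, "U"), "no analysis")
  expect_length(cg0, 0)
})

test_that("markers are attributed to their planted programs", {
  cfg <- simulation_config(n_genes = 600, n_celltypes = 6,
                           signatures_per_celltype = 40, noise_sd = 0.5,
                           genotype_offsets = list(), seed = 43)
  dv <- generate_development_cohort(cfg)
  ann <- generate_annotation(dv$truth, n_background_terms = 10)
  z <- zscore_standardize(dv$expression)
  analyses <- run_kmeans_analyses(z, dv$samples, seed = 10)
  annotated <- annotate_analyses(analyses, ann)
  markers <- growthsets:::marker_table_from_truth(dv$truth)
  att <- attribute_markers(annotated, markers, min_support = 3)
  ok <- att$status == "attributed" & att$term == paste0("PROG_", att$cell_type)
  acc <- mean(vapply(split(ok, att$marker), any, logical(1)))
  expect_gte(acc, 0.9)
  # a marker absent from the clustered universe is reported unattributed
  att2 <- attribute_markers(annotated, data.frame(gene = "ABSENT1",
                                                  cell_type = "fap"))
  expect_equal(att2$status, "absent")
  # support counts are invariant to analysis ordering
  annotated_rev <- annotated[rev(seq_along(annotated))]
  attr(annotated_rev, "analyses") <- attr(annotated, "analyses")[rev(seq_along(analyses))]
  att_rev <- attribute_markers(annotated_rev, markers, min_support = 3)
  key <- function(d) d[order(d$marker, d$term), c("marker", "term", "support")]
  expect_equal(key(att_rev), key(att), ignore_attr = TRUE)
})
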
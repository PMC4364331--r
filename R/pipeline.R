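#' Build and validate a pipeline configuration
#'
#' A pipeline run is configured by a flat list (readable from YAML) naming the
#' synthesis parameters (or input paths), the analysis thresholds and every
#' seed. Validation is performed up front so no stage starts on a bad config.
#'
#' @param config a named list or the path to a YAML file.
#' @return The validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    simulation = list(), phenotype = "adg_per_kg",
    min_term_size = 5, max_term_size = 2000, enrich_q = 0.05,
    set_size = 5, coexpr_min = 0.6, n_draws = 1e5,
    ks = c(10, 13), windows = c("all", "postnatal"),
    min_support = 3, cluster_q = 0.05, contrast_stages = c("12mo", "25mo"),
    seed = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stopf("config must set an explicit seed")
  assert_count(cfg$seed, "seed", min = 0L)
  assert_count(cfg$n_draws, "n_draws")
  assert_count(cfg$set_size, "set_size")
  if (cfg$coexpr_min < -1 || cfg$coexpr_min > 1) stopf("coexpr_min must be in [-1, 1]")
  if (cfg$enrich_q <= 0 || cfg$enrich_q > 1) stopf("enrich_q must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the full discovery pipeline on a synthetic cohort pair
#'
#' Executes, in dependency order: cohort synthesis, phenotype-correlation
#' ranking, ranked-list enrichment, 5-gene-set construction, set scoring with
#' the random-set empirical null, loose co-expression filtering, the k-means
#' clustering panel with GO annotation, consensus lists and marker
#' attribution, and the treatment/genotype contrasts. Every artifact is
#' written under `out_dir` and recorded in a manifest with md5 checksums;
#' identical configs yield identical checksums.
#'
#' @param config a [pipeline_config()] (or list / YAML path coercible to one).
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly: a list with `config`, per-stage seeds and
#'   row counts, headline results and the file checksum table.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  sim_cfg <- do.call(simulation_config, utils::modifyList(
    cfg$simulation, list(seed = cfg$seed)))
  pheno <- generate_phenotype_cohort(sim_cfg)
  dev <- generate_development_cohort(sim_cfg)
  annotation <- generate_annotation(pheno$truth)
  note("synthesize: %d genes, %d phenotype samples, %d development samples, %d terms",
       nrow(pheno$expression), ncol(pheno$expression), ncol(dev$expression),
       length(annotation))
  write_expression(pheno$expression, file.path(out_dir, "phenotype_expression.tsv"))
  write_sample_table(pheno$samples, file.path(out_dir, "phenotype_samples.csv"))
  write_expression(dev$expression, file.path(out_dir, "development_expression.tsv"))
  write_sample_table(dev$samples, file.path(out_dir, "development_samples.csv"))
  write_gmt(annotation, file.path(out_dir, "annotation.gmt"))
  jsonlite::write_json(
    list(celltype_of_gene = as.list(pheno$truth$celltype_of_gene),
         growth_celltype = pheno$truth$growth_celltype, seed = cfg$seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

  phenotype <- stats::setNames(pheno$samples[[cfg$phenotype]],
                               pheno$samples$sample_id)
  ranked <- rank_by_correlation(pheno$expression, phenotype,
                                phenotype_name = cfg$phenotype)
  utils::write.table(ranked, file.path(out_dir, "ranked.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("rank: %d genes ranked by correlation with %s", nrow(ranked), cfg$phenotype)

  enrichment <- enrich_ranked_list(ranked, annotation,
                                   min_term_size = cfg$min_term_size,
                                   max_term_size = cfg$max_term_size,
                                   seed = cfg$seed + 10L)
  utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  top_terms <- enrichment$term[enrichment$q <= cfg$enrich_q]
  note("enrich: %d terms tested, %d at q <= %g", nrow(enrichment),
       length(top_terms), cfg$enrich_q)

  pheno_z <- zscore_standardize(pheno$expression)
  dev_z <- zscore_standardize(dev$expression)
  dev_profiles <- stage_profiles(dev_z, dev$samples, window = "all",
                                 stage_levels = sim_cfg$stages$stage)

  sets <- list()
  nulls <- list()
  for (term in top_terms) {
    sel <- try(select_top_genes(annotation[[term]], ranked, dev_profiles,
                                k = cfg$set_size, coexpr_min = cfg$coexpr_min),
               silent = TRUE)
    if (inherits(sel, "try-error")) {
      note("build-set: %s skipped (%s)", term, trimws(attr(sel, "condition")$message))
      next
    }
    sets[[term]] <- sel$genes
    nulls[[term]] <- empirical_null_pvalue(pheno_z, phenotype, sel$genes,
                                           n_draws = cfg$n_draws,
                                           seed = cfg$seed + 20L)
    note("build-set: %s -> {%s}, r = %.3f, empirical p = %.3g", term,
         paste(sel$genes, collapse = ", "), nulls[[term]]$observed_r,
         nulls[[term]]$p_empirical)
  }
  if (length(sets)) {
    write_gmt(structure(sets, descriptions = stats::setNames(names(sets), names(sets))),
              file.path(out_dir, "gene_sets.gmt"))
    jsonlite::write_json(nulls, file.path(out_dir, "empirical_null.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  filtered <- loose_coexpression_filter(dev$expression, dev$samples)
  writeLines(filtered, file.path(out_dir, "filtered_genes.txt"))
  note("filter: %d of %d genes pass the loose co-expression rules",
       length(filtered), nrow(dev$expression))

  clustered_genes <- intersect(filtered, rownames(dev_z))
  analyses <- run_kmeans_analyses(dev_z, dev$samples, genes = clustered_genes,
                                  ks = cfg$ks, windows = cfg$windows,
                                  seed = cfg$seed + 30L,
                                  stage_levels = sim_cfg$stages$stage)
  labels_tab <- do.call(rbind, lapply(analyses, function(an) {
    data.frame(analysis = an$analysis_id, gene = names(an$labels),
               cluster = unname(an$labels), stringsAsFactors = FALSE)
  }))
  utils::write.table(labels_tab, file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  annotated <- annotate_analyses(analyses, annotation, q_threshold = cfg$cluster_q)
  note("cluster: %d analyses over %d genes", length(analyses), length(clustered_genes))

  consensus <- list()
  for (term in names(annotation)) {
    cg <- suppressWarnings(consensus_genes(annotated, annotation, term,
                                           min_support = cfg$min_support))
    if (length(cg)) consensus[[term]] <- cg
  }
  cons_tab <- do.call(rbind, lapply(names(consensus), function(term) {
    sup <- attr(consensus[[term]], "support")
    data.frame(term = term, gene = consensus[[term]],
               support = as.integer(sup[consensus[[term]]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cons_tab)) {
    cons_tab <- data.frame(term = character(0), gene = character(0),
                           support = integer(0))
  }
  utils::write.table(cons_tab, file.path(out_dir, "consensus.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  markers <- marker_table_from_truth(dev$truth)
  attribution <- attribute_markers(annotated, markers,
                                   min_support = cfg$min_support)
  utils::write.table(attribution, file.path(out_dir, "attribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("attribute: %d markers, %d attributed", nrow(markers),
       sum(attribution$status == "attributed"))

  contrasts <- list()
  for (term in names(sets)) {
    contrasts[[paste0(term, "_HGP")]] <-
      unclass(treatment_set_test(pheno_z, sets[[term]], pheno$samples))
    for (stage in cfg$contrast_stages) {
      contrasts[[paste0(term, "_", stage)]] <-
        unclass(genotype_set_test(dev_z, sets[[term]], dev$samples, stage))
    }
  }
  jsonlite::write_json(contrasts, file.path(out_dir, "contrasts.json"),
                       auto_unbox = TRUE, digits = NA)

  truth_labels <- dev$truth$celltype_of_gene
  recovery <- list()
  planted_clustered <- clustered_genes[truth_labels[clustered_genes] != "background"]
  if (length(planted_clustered) >= 2) {
    recovery$ari <- stats::setNames(
      vapply(analyses, function(an) {
        adjusted_rand_index(an$labels[planted_clustered],
                            truth_labels[planted_clustered])
      }, numeric(1)), names(analyses))
  }
  attributed <- attribution[attribution$status == "attributed", , drop = FALSE]
  if (nrow(attributed)) {
    correct <- attributed$term == paste0("PROG_", attributed$cell_type)
    recovery$marker_accuracy <- mean(
      vapply(split(correct, attributed$marker), any, logical(1)))
  }

  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("growthsets")),
    config = unclass(cfg), log = log_lines,
    sets = sets,
    empirical_p = lapply(nulls, `[[`, "p_empirical"),
    observed_r = lapply(nulls, `[[`, "observed_r"),
    n_filtered = length(filtered),
    consensus_sizes = lapply(consensus, length),
    recovery = recovery,
    checksums = as.list(file_checksums(file.path(out_dir, files), root = out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Marker table derived from simulation truth: the first few signature genes of
# each planted program, labelled with their true cell type.
marker_table_from_truth <- function(truth, per_celltype = 5) {
  cts <- setdiff(unique(truth$celltype_of_gene), "background")
  rows <- lapply(cts, function(ct) {
    g <- names(truth$celltype_of_gene)[truth$celltype_of_gene == ct]
    data.frame(gene = utils::head(g, per_celltype), cell_type = ct,
               sign = "+", source = "synthetic_truth", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a pipeline run
#'
#' Renders a human-readable, byte-stable summary of a manifest (or of a run
#' directory containing `manifest.json`): discovered sets with their
#' empirical p-values, filter and consensus counts, and — when simulation
#' truth was available — the clustering ARI and marker-attribution accuracy.
#'
#' @param manifest a manifest list from [run_pipeline()], or a run directory.
#' @return Character vector of report lines (also printed).
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(file.path(manifest, "manifest.json"),
                                    simplifyVector = TRUE)
  }
  lines <- c("growthsets pipeline report",
             sprintf("seed: %s", manifest$config$seed),
             sprintf("loose filter pass count: %d", manifest$n_filtered))
  if (length(manifest$sets)) {
    for (term in names(manifest$sets)) {
      lines <- c(lines, sprintf(
        "set %s: {%s} r = %.3f, empirical p = %.3g", term,
        paste(unlist(manifest$sets[[term]]), collapse = ", "),
        manifest$observed_r[[term]], manifest$empirical_p[[term]]))
    }
  } else {
    lines <- c(lines, "no gene sets passed selection")
  }
  for (term in names(manifest$consensus_sizes)) {
    lines <- c(lines, sprintf("consensus %s: %d genes", term,
                              manifest$consensus_sizes[[term]]))
  }
  if (!is.null(manifest$recovery$ari)) {
    ari <- unlist(manifest$recovery$ari)
    lines <- c(lines, sprintf("clustering ARI vs truth (median): %.3f",
                              stats::median(ari)))
  }
  if (!is.null(manifest$recovery$marker_accuracy)) {
    lines <- c(lines, sprintf("marker attribution accuracy: %.3f",
                              manifest$recovery$marker_accuracy))
  }
  if (is.null(manifest$recovery$ari) && is.null(manifest$recovery$marker_accuracy)) {
    lines <- c(lines, "no simulation truth available; recovery metrics omitted")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
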
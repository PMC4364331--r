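#' Loose co-expression filter for the ECM-like developmental pattern
#'
#' Sign-only ("loose") selection of genes whose developmental expression
#' resembles the ECM program: (a) the pooled-genotype mean at birth exceeds
#' the pooled mean at the final stage (expression decreasing after birth), and
#' (b) the high-marbling genotype mean exceeds the high-muscling mean at each
#' stage of interest (default 12 and 25 months). No significance threshold is
#' applied — the rules are deliberately weak so the pass set is large and is
#' refined downstream by clustering.
#'
#' @param dev_matrix development expression matrix (raw log2 scale; the rules
#'   are sign-only so any per-gene affine rescaling gives the same answer).
#' @param samples development sample table (`stage`, `genotype`).
#' @param stages_of_interest stages at which the genotype contrast must hold.
#' @param high_genotype,low_genotype genotype labels contrasted in rule (b).
#' @param birth_stage,final_stage stages compared in rule (a); `final_stage`
#'   defaults to the oldest stage present.
#' @return Character vector of passing genes.
#' @export
loose_coexpression_filter <- function(dev_matrix, samples,
                                      stages_of_interest = c("12mo", "25mo"),
                                      high_genotype = "highmarble",
                                      low_genotype = "highmuscle",
                                      birth_stage = "birth",
                                      final_stage = NULL) {
  samples <- samples[match(colnames(dev_matrix), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stopf("sample table does not cover the matrix")
  if (is.null(final_stage)) {
    final_stage <- samples$stage[which.max(samples$age_days)]
  }
  need <- unique(c(stages_of_interest, birth_stage, final_stage))
  miss <- setdiff(need, samples$stage)
  if (length(miss)) stopf("required stage(s) missing from the cohort: %s",
                          paste(miss, collapse = ", "))
  for (g in c(high_genotype, low_genotype)) {
    if (!g %in% samples$genotype) stopf("genotype '%s' absent from the cohort", g)
  }
  stage_mean <- function(stage, genotype = NULL) {
    sel <- samples$stage == stage
    if (!is.null(genotype)) sel <- sel & samples$genotype == genotype
    rowMeans(dev_matrix[, sel, drop = FALSE])
  }
  decreasing <- stage_mean(birth_stage) > stage_mean(final_stage)
  higher <- rep(TRUE, nrow(dev_matrix))
  for (s in stages_of_interest) {
    higher <- higher & (stage_mean(s, high_genotype) > stage_mean(s, low_genotype))
  }
  rownames(dev_matrix)[decreasing & higher]
}

#' Estimate the number of expression-profile clusters
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' stage-mean profiles, choosing k within `k_range` at the largest relative
#' merge-height gap — i.e. the partition whose next merge would join clusters
#' at a disproportionately larger height.
#'
#' @param z_profiles genes x profile-point matrix (see [stage_profiles()]).
#' @param k_range inclusive candidate range (default 8-13).
#' @return The selected k. Degenerate inputs (all profiles identical) return
#'   the lower bound with a warning.
#' @export
estimate_k <- function(z_profiles, k_range = c(8, 13)) {
  n <- nrow(z_profiles)
  if (n < 2 * k_range[2]) {
    stopf("need at least %d profiles for k up to %d", 2 * k_range[2], k_range[2])
  }
  hc <- stats::hclust(stats::dist(z_profiles), method = "average")
  h <- hc$height  # increasing; cutting to k clusters crosses h[n-k] .. h[n-k+1]
  if (max(h) == 0) {
    warnf("estimate_k: all profiles identical; returning the lower bound")
    return(as.integer(k_range[1]))
  }
  ks <- seq(k_range[1], k_range[2])
  gaps <- vapply(ks, function(k) {
    lower <- h[n - k]
    upper <- h[n - k + 1]
    if (lower <= 0) return(Inf)
    upper / lower
  }, numeric(1))
  as.integer(ks[which.max(gaps)])
}

#' Run the panel of k-means clustering analyses
#'
#' Clusters genes on their stage-by-genotype mean z-score profiles for every
#' combination of k values and developmental windows (default k in \{10, 13\}
#' over the full course and the postnatal stages — four analyses). k-means
#' uses Euclidean distance with `nstart` random restarts, keeping the best
#' within-cluster sum of squares; each analysis is seeded deterministically
#' from `seed`.
#'
#' @param z z-score matrix of the development cohort (all genes to cluster).
#' @param samples development sample table.
#' @param genes genes to cluster (default: all rows of `z`).
#' @param ks k values (default `c(10, 13)`).
#' @param windows developmental windows (subset of `c("all", "postnatal")`).
#' @param nstart random restarts per analysis (default 10).
#' @param seed integer seed.
#' @param stage_levels ordered stage vocabulary passed to [stage_profiles()].
#' @return List of analyses; each has `analysis_id` (`k<k>_<window>`), `k`,
#'   `window`, `labels` (named integer vector over `genes`), `centers`,
#'   `iterations` and `seed`.
#' @export
run_kmeans_analyses <- function(z, samples, genes = rownames(z),
                                ks = c(10, 13), windows = c("all", "postnatal"),
                                nstart = 10, seed = 1L,
                                stage_levels = unique(samples$stage)) {
  windows <- match.arg(windows, c("all", "postnatal"), several.ok = TRUE)
  miss <- setdiff(genes, rownames(z))
  if (length(miss)) stopf("gene(s) absent from z: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  grid <- expand.grid(k = ks, window = windows, stringsAsFactors = FALSE)
  analyses <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]
    window <- grid$window[i]
    prof <- stage_profiles(z[genes, , drop = FALSE], samples, window = window,
                           stage_levels = stage_levels)
    if (ncol(prof) < 2) stopf("window '%s' has fewer than 2 stages", window)
    if (k > nrow(prof)) stopf("k = %d exceeds the gene count %d", k, nrow(prof))
    analysis_seed <- as.integer(seed) + i
    fit <- with_seed(analysis_seed, {
      if (k == 1L) {
        list(cluster = stats::setNames(rep(1L, nrow(prof)), rownames(prof)),
             centers = matrix(colMeans(prof), nrow = 1,
                              dimnames = list("1", colnames(prof))),
             iter = 0L)
      } else {
        km <- stats::kmeans(prof, centers = k, nstart = nstart, iter.max = 100)
        list(cluster = km$cluster, centers = km$centers, iter = km$iter)
      }
    })
    analyses[[i]] <- list(
      analysis_id = sprintf("k%d_%s", k, window), k = as.integer(k),
      window = window, labels = fit$cluster, centers = fit$centers,
      iterations = fit$iter, seed = analysis_seed)
  }
  names(analyses) <- vapply(analyses, `[[`, character(1), "analysis_id")
  analyses
}

#' Annotate every cluster of every analysis with its enriched GO terms
#'
#' Applies [enrich_cluster()] to each cluster of each k-means analysis, with
#' the clustered genes as the universe, and retains terms at `q <=
#' q_threshold`.
#'
#' @param analyses output of [run_kmeans_analyses()].
#' @param annotation named list of term member vectors.
#' @param q_threshold BH FDR cutoff (default 0.05).
#' @return A list per analysis with `enriched` (cluster id -> character vector
#'   of enriched term ids) and `tables` (cluster id -> full enrichment
#'   data.frame); carries the input analyses as attribute `analyses`.
#' @export
annotate_analyses <- function(analyses, annotation, q_threshold = 0.05) {
  if (length(annotation) == 0) {
    warnf("annotate_analyses: empty annotation; no cluster can be annotated")
  }
  out <- lapply(analyses, function(an) {
    universe <- names(an$labels)
    clusters <- sort(unique(an$labels))
    enriched <- list()
    tables <- list()
    for (cl in clusters) {
      members <- universe[an$labels == cl]
      tab <- if (length(annotation)) {
        enrich_cluster(members, annotation, universe)
      } else {
        data.frame(term = character(0), q = numeric(0))
      }
      tables[[as.character(cl)]] <- tab
      enriched[[as.character(cl)]] <- tab$term[tab$q <= q_threshold]
    }
    list(analysis_id = an$analysis_id, enriched = enriched, tables = tables)
  })
  attr(out, "analyses") <- analyses
  out
}

# Per-gene count of analyses in which the gene's cluster is enriched for
# `term`; genes outside an analysis count 0 there.
term_support_counts <- function(annotated, term, genes) {
  analyses <- attr(annotated, "analyses")
  support <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_along(annotated)) {
    an <- analyses[[i]]
    enriched_clusters <- names(annotated[[i]]$enriched)[
      vapply(annotated[[i]]$enriched, function(ts) term %in% ts, logical(1))]
    if (!length(enriched_clusters)) next
    in_cluster <- names(an$labels)[an$labels %in% as.integer(enriched_clusters)]
    hit <- genes %in% in_cluster
    support[hit] <- support[hit] + 1L
  }
  support
}

#' Consensus gene list for a term across clustering analyses
#'
#' Returns the term's member genes whose containing cluster is enriched for
#' that same term in at least `min_support` of the analyses — the
#' cross-analysis consensus that identifies the stable core of a process.
#'
#' @param annotated output of [annotate_analyses()].
#' @param annotation the term annotation (for the member list).
#' @param term term id.
#' @param min_support minimum number of supporting analyses (default 3, the
#'   3-of-4 rule; 4 gives the strict all-analyses reading).
#' @return Character vector of consensus genes, with the full per-gene support
#'   counts as attribute `support`. Empty (with a warning) when the term is
#'   enriched in no analysis.
#' @export
consensus_genes <- function(annotated, annotation, term, min_support = 3) {
  if (!term %in% names(annotation)) stopf("unknown term '%s'", term)
  members <- annotation[[term]]
  support <- term_support_counts(annotated, term, members)
  if (all(support == 0)) {
    warnf("term '%s' is enriched in no analysis", term)
    return(structure(character(0), support = support))
  }
  structure(names(support)[support >= min_support], support = support)
}

#' Attribute marker genes to processes via their co-clustered GO terms
#'
#' For each marker gene, records the enriched terms of the cluster containing
#' it in every analysis, and attributes the marker to each term reaching
#' `min_support` analyses. A marker co-clustered with, say, the angiogenesis
#' term in three of four analyses is attributed to angiogenesis; ties (several
#' terms at or above support) are all reported, not broken. Markers absent
#' from the clustered universe are reported unattributed.
#'
#' @param annotated output of [annotate_analyses()].
#' @param markers marker table (`gene`, `cell_type`, ...) or character vector
#'   of marker genes.
#' @param min_support minimum supporting analyses (default 3).
#' @return data.frame with one row per (marker, attributed term): columns
#'   `marker`, `cell_type` (claimed, NA if unknown), `term` (NA when
#'   unattributed or absent), `support`, `n_analyses`, `status`
#'   (attributed/unattributed/absent).
#' @export
attribute_markers <- function(annotated, markers, min_support = 3) {
  if (is.character(markers)) {
    markers <- data.frame(gene = markers, cell_type = NA_character_,
                          stringsAsFactors = FALSE)
  }
  analyses <- attr(annotated, "analyses")
  universe <- unique(unlist(lapply(analyses, function(a) names(a$labels))))
  all_terms <- unique(unlist(lapply(annotated, function(x) unlist(x$enriched))))
  rows <- list()
  for (i in seq_len(nrow(markers))) {
    g <- markers$gene[i]
    ct <- markers$cell_type[i]
    if (!g %in% universe) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = g, cell_type = ct, term = NA_character_, support = 0L,
        n_analyses = length(analyses), status = "absent", stringsAsFactors = FALSE)
      next
    }
    support <- stats::setNames(integer(length(all_terms)), all_terms)
    clustered_in <- 0L
    for (j in seq_along(annotated)) {
      an <- analyses[[j]]
      if (!g %in% names(an$labels)) next
      clustered_in <- clustered_in + 1L
      terms_here <- annotated[[j]]$enriched[[as.character(an$labels[[g]])]]
      support[terms_here] <- support[terms_here] + 1L
    }
    hit <- names(support)[support >= min_support]
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = g, cell_type = ct, term = hit,
        support = as.integer(support[hit]), n_analyses = clustered_in,
        status = "attributed", stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        marker = g, cell_type = ct, term = NA_character_,
        support = if (length(support)) max(support) else 0L,
        n_analyses = clustered_in, status = "unattributed",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
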
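#' Z-score standardization of an expression matrix
#'
#' Rescales each gene to mean 0 and standard deviation 1 across a declared
#' sample universe, so expression values from different genes can be combined
#' into a single set score. The default divisor is the sample standard
#' deviation (n - 1); the population form (n) is available via `sd_type`.
#' Genes constant over the universe are excluded with a warning.
#'
#' @param matrix expression matrix (genes x samples).
#' @param universe_samples sample IDs defining the standardization universe
#'   (default: all samples). At least two required.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @return The z-score matrix restricted to `universe_samples` and to
#'   non-constant genes.
#' @export
zscore_standardize <- function(matrix, universe_samples = colnames(matrix),
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  miss <- setdiff(universe_samples, colnames(matrix))
  if (length(miss)) stopf("unknown sample(s): %s", paste(miss, collapse = ", "))
  if (length(universe_samples) < 2) stopf("z-scores need at least 2 samples")
  m <- matrix[, universe_samples, drop = FALSE]
  mu <- rowMeans(m)
  centered <- m - mu
  n <- ncol(m)
  denom <- if (sd_type == "sample") n - 1 else n
  sds <- sqrt(rowSums(centered^2) / denom)
  constant <- sds == 0
  if (any(constant)) {
    warnf("zscore_standardize: excluded %d constant gene(s)", sum(constant))
  }
  centered[!constant, , drop = FALSE] / sds[!constant]
}

#' Average z-score of a gene set, per sample
#'
#' The score of a gene set in a sample is the arithmetic mean of the members'
#' z-scores in that sample; a set of five genes gives the "5 gene set" signature
#' value tracked against phenotype and across development.
#'
#' @param z z-score matrix from [zscore_standardize()].
#' @param genes character vector of member genes; all must be rows of `z`.
#' @return Named numeric vector of per-sample scores, with attribute `n_genes`
#'   giving the contributing gene count.
#' @export
set_score <- function(z, genes) {
  miss <- setdiff(genes, rownames(z))
  if (length(miss)) stopf("gene(s) absent from the z-matrix: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(genes)) stopf("gene set has duplicate members")
  score <- colMeans(z[genes, , drop = FALSE])
  attr(score, "n_genes") <- length(genes)
  score
}

#' Per-gene developmental profiles (stage x genotype mean z-scores)
#'
#' Averages each gene's z-scores over the animals in every stage-by-genotype
#' cell, giving the profile vectors on which co-expression is judged and
#' clustering is run. Columns are ordered stage-major with genotypes in sorted
#' order, and restricted to the requested window.
#'
#' @param z z-score matrix for the development cohort.
#' @param samples sample table with `stage` and `genotype` columns.
#' @param window `"all"` (every stage) or `"postnatal"` (birth onwards).
#' @param stage_levels ordered stage vocabulary; defaults to the order of first
#'   appearance in `samples`.
#' @return Matrix genes x (stage, genotype) cell means, columns named
#'   `<stage>.<genotype>`.
#' @export
stage_profiles <- function(z, samples, window = c("all", "postnatal"),
                           stage_levels = unique(samples$stage)) {
  window <- match.arg(window)
  samples <- samples[match(colnames(z), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) stopf("sample table does not cover the z-matrix")
  stages <- stage_levels
  if (window == "postnatal") {
    if (!"age_days" %in% names(samples)) {
      stopf("postnatal window needs an age_days column")
    }
    post <- unique(samples$stage[samples$age_days >= 0])
    stages <- stages[stages %in% post]
  }
  if (length(stages) < 2) stopf("window contains fewer than 2 stages")
  genotypes <- sort(unique(samples$genotype))
  cols <- expand.grid(genotype = genotypes, stage = stages,
                      stringsAsFactors = FALSE)[, c("stage", "genotype")]
  prof <- vapply(seq_len(nrow(cols)), function(i) {
    sel <- samples$stage == cols$stage[i] & samples$genotype == cols$genotype[i]
    if (!any(sel)) stopf("no samples for stage %s, genotype %s",
                         cols$stage[i], cols$genotype[i])
    rowMeans(z[, sel, drop = FALSE])
  }, numeric(nrow(z)))
  colnames(prof) <- paste(cols$stage, cols$genotype, sep = ".")
  rownames(prof) <- rownames(z)
  prof
}

#' Select the top co-expressed genes of a term into a signature set
#'
#' Walks the term's member genes in phenotype-correlation rank order and builds
#' a set of `k` genes that are both highly ranked and co-expressed through
#' development: the first (best-ranked) gene is always accepted, and each
#' subsequent gene is accepted only if the correlation of its developmental
#' profile with the running mean profile of the already-accepted genes is at
#' least `coexpr_min`. Selection stops at `k` members.
#'
#' @param term_genes member genes of the term.
#' @param ranked ranking from [rank_by_correlation()].
#' @param dev_profiles developmental profile matrix from [stage_profiles()].
#' @param k target set size (default 5).
#' @param coexpr_min minimum profile correlation with the running set mean
#'   (default 0.6).
#' @return A list with `genes` (the selected members, in acceptance order) and
#'   `provenance` (a data.frame recording every accept/reject with the profile
#'   correlation at the time of the decision).
#' @export
select_top_genes <- function(term_genes, ranked, dev_profiles, k = 5,
                             coexpr_min = 0.6) {
  assert_count(k, "k")
  candidates <- ranked$gene[ranked$gene %in% term_genes]
  candidates <- candidates[candidates %in% rownames(dev_profiles)]
  if (length(candidates) < k) {
    stopf("term has only %d member(s) present in both universes; %d required",
          length(candidates), k)
  }
  accepted <- character(0)
  prov <- list()
  running <- NULL
  for (g in candidates) {
    if (length(accepted) == 0) {
      accepted <- g
      running <- dev_profiles[g, ]
      prov[[length(prov) + 1L]] <- data.frame(
        gene = g, action = "accept", profile_r = NA_real_, stringsAsFactors = FALSE)
    } else {
      r <- pearson_r(dev_profiles[g, ], running / length(accepted))
      ok <- r >= coexpr_min
      prov[[length(prov) + 1L]] <- data.frame(
        gene = g, action = if (ok) "accept" else "reject", profile_r = r,
        stringsAsFactors = FALSE)
      if (ok) {
        accepted <- c(accepted, g)
        running <- running + dev_profiles[g, ]
      }
    }
    if (length(accepted) == k) break
  }
  if (length(accepted) < k) {
    stopf("only %d of %d required genes passed the co-expression walk",
          length(accepted), k)
  }
  list(genes = accepted, provenance = do.call(rbind, prov))
}

#' Empirical random-gene-set null for a set-phenotype correlation
#'
#' Calibrates the correlation between a gene set's average z-score and a
#' phenotype against sets of the same size drawn uniformly at random (without
#' replacement, from the full gene universe of the z-matrix). The p-value uses
#' the standard permutation estimator p = (exceedances + 1) / (draws + 1) with
#' strict exceedance (r_draw > r_observed), one-sided for higher correlation.
#'
#' @param z z-score matrix.
#' @param phenotype per-sample phenotype vector aligned to `z` columns.
#' @param set_genes the observed gene set.
#' @param n_draws number of random sets (default 100000).
#' @param seed RNG seed; draws are fully reproducible.
#' @param chunk internal draw block size.
#' @return A list with `observed_r`, `n_draws`, `n_exceeding`, `p_empirical`,
#'   `set_size` and `seed`.
#' @export
empirical_null_pvalue <- function(z, phenotype, set_genes, n_draws = 1e5,
                                  seed = 1L, chunk = 20000L) {
  assert_count(n_draws, "n_draws")
  size <- length(set_genes)
  n_genes <- nrow(z)
  if (size > n_genes) stopf("set size exceeds the gene universe")
  if (length(phenotype) != ncol(z)) stopf("phenotype does not match z columns")
  observed_r <- pearson_r(set_score(z, set_genes), phenotype)
  yc <- phenotype - mean(phenotype)
  y_ss <- sqrt(sum(yc^2))
  n_exceeding <- 0L
  with_seed(seed, {
    done <- 0L
    while (done < n_draws) {
      m <- min(chunk, n_draws - done)
      idx <- vapply(seq_len(m), function(i) sample.int(n_genes, size),
                    integer(size))
      scores <- rowsum(z[as.vector(idx), , drop = FALSE],
                       group = rep(seq_len(m), each = size), reorder = FALSE) / size
      sc <- scores - rowMeans(scores)
      r <- as.vector(sc %*% yc) / (sqrt(rowSums(sc^2)) * y_ss)
      n_exceeding <- n_exceeding + sum(r > observed_r)
      done <- done + m
    }
  })
  list(observed_r = observed_r, n_draws = as.integer(n_draws),
       n_exceeding = as.integer(n_exceeding),
       p_empirical = (n_exceeding + 1) / (n_draws + 1),
       set_size = as.integer(size), seed = as.integer(seed))
}
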
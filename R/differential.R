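#' Welch two-sample t-test
#'
#' Two-tailed t-test assuming unequal variances (Welch-Satterthwaite degrees
#' of freedom), the contrast test used for all genotype and treatment
#' comparisons of genes and gene sets.
#'
#' @param a,b numeric value vectors, each of length >= 2.
#' @param label contrast label stored with the result.
#' @return A list of class `contrast_result` with `contrast`, `statistic`,
#'   `df`, `p`, `means` and `sizes`.
#' @export
welch_ttest <- function(a, b, label = "a vs b") {
  if (length(a) < 2 || length(b) < 2) stopf("each group needs at least 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stopf("non-finite values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: both groups constant; equal means give t = 0, p = 1
    if (mean(a) == mean(b)) {
      return(structure(list(contrast = label, statistic = 0, df = NA_real_,
                            p = 1, means = c(mean(a), mean(b)),
                            sizes = c(length(a), length(b))),
                       class = "contrast_result"))
    }
    stopf("both groups constant with different means; t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  structure(list(contrast = label, statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 means = c(mean(a), mean(b)),
                 sizes = c(length(a), length(b))),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("Contrast %s: t = %.4g (df = %.2f), p = %.3g; means %.4g vs %.4g (n = %d, %d)\n",
              x$contrast, x$statistic, x$df, x$p, x$means[1], x$means[2],
              x$sizes[1], x$sizes[2]))
  invisible(x)
}

group_samples <- function(samples, column, value, stage = NULL) {
  sel <- samples[[column]] == value
  if (!is.null(stage)) sel <- sel & samples$stage == stage
  samples$sample_id[sel]
}

#' Genotype contrast of a gene set at one developmental stage
#'
#' Welch t-test comparing the two genotypes at a stage. By default the test
#' pools the member z-scores (set-size x animals values per group); the
#' per-animal set-score variant is available via `mode = "score"`.
#'
#' @param z z-score matrix of the development cohort.
#' @param set_genes member genes of the set.
#' @param samples development sample table.
#' @param stage stage label at which to contrast.
#' @param genotypes the two genotype labels (first minus second).
#' @param mode `"pooled"` (member z-values) or `"score"` (per-animal set
#'   scores).
#' @return A `contrast_result`.
#' @export
genotype_set_test <- function(z, set_genes, samples, stage,
                              genotypes = c("highmarble", "highmuscle"),
                              mode = c("pooled", "score")) {
  mode <- match.arg(mode)
  ids1 <- group_samples(samples, "genotype", genotypes[1], stage)
  ids2 <- group_samples(samples, "genotype", genotypes[2], stage)
  if (!length(ids1) || !length(ids2)) {
    stopf("stage '%s' lacks samples for one of the genotypes", stage)
  }
  vals <- set_group_values(z, set_genes, ids1, ids2, mode)
  welch_ttest(vals$a, vals$b,
              label = sprintf("%s vs %s @ %s", genotypes[1], genotypes[2], stage))
}

#' HGP-treatment contrast of a gene set in the phenotype cohort
#'
#' Welch t-test of treated vs control animals, pooling member z-scores by
#' default (switchable to per-animal set scores).
#'
#' @param z z-score matrix of the phenotype cohort.
#' @param set_genes member genes of the set.
#' @param samples phenotype sample table with a `treatment` column.
#' @param treatments the two treatment labels (first minus second).
#' @inheritParams genotype_set_test
#' @return A `contrast_result`.
#' @export
treatment_set_test <- function(z, set_genes, samples,
                               treatments = c("HGP", "control"),
                               mode = c("pooled", "score")) {
  mode <- match.arg(mode)
  present <- intersect(treatments, unique(samples$treatment))
  if (length(present) < 2) stopf("cohort has a single treatment group")
  ids1 <- group_samples(samples, "treatment", treatments[1])
  ids2 <- group_samples(samples, "treatment", treatments[2])
  vals <- set_group_values(z, set_genes, ids1, ids2, mode)
  welch_ttest(vals$a, vals$b,
              label = sprintf("%s vs %s", treatments[1], treatments[2]))
}

set_group_values <- function(z, set_genes, ids1, ids2, mode) {
  miss <- setdiff(set_genes, rownames(z))
  if (length(miss)) stopf("gene(s) absent from z: %s", paste(miss, collapse = ", "))
  if (mode == "pooled") {
    list(a = as.vector(z[set_genes, ids1, drop = FALSE]),
         b = as.vector(z[set_genes, ids2, drop = FALSE]))
  } else {
    list(a = set_score(z[, ids1, drop = FALSE], set_genes),
         b = set_score(z[, ids2, drop = FALSE], set_genes))
  }
}

#' Single-gene significance against the all-gene empirical interval
#'
#' Tests whether one gene's between-genotype mean difference at a stage is
#' extreme relative to the empirical distribution of the same difference over
#' all genes: the gene is flagged when its difference falls outside the
#' central `coverage` interval (linear-interpolated quantiles) of all genes'
#' differences at that stage. This sidesteps per-gene variance estimation by
#' using the transcriptome itself as the null.
#'
#' @param dev_matrix development expression matrix (or z-matrix; the flag is
#'   invariant to adding a constant to all genes at the stage).
#' @param samples development sample table.
#' @param gene query gene.
#' @param stage stage label.
#' @param coverage central interval mass (default 0.95).
#' @param genotypes the two genotype labels (first minus second).
#' @param min_genes minimum number of genes for a stable empirical interval.
#' @return A list with `significant`, `percentile` (mid-rank, in \[0, 100\]),
#'   `difference`, `interval` and `n_genes`.
#' @export
single_gene_interval_test <- function(dev_matrix, samples, gene, stage,
                                      coverage = 0.95,
                                      genotypes = c("highmarble", "highmuscle"),
                                      min_genes = 1000) {
  if (!gene %in% rownames(dev_matrix)) stopf("unknown gene '%s'", gene)
  if (nrow(dev_matrix) < min_genes) {
    stopf("only %d genes; at least %d needed for a stable empirical interval",
          nrow(dev_matrix), min_genes)
  }
  ids1 <- group_samples(samples, "genotype", genotypes[1], stage)
  ids2 <- group_samples(samples, "genotype", genotypes[2], stage)
  if (!length(ids1) || !length(ids2)) {
    stopf("stage '%s' lacks samples for one of the genotypes", stage)
  }
  diffs <- rowMeans(dev_matrix[, ids1, drop = FALSE]) -
    rowMeans(dev_matrix[, ids2, drop = FALSE])
  qs <- stats::quantile(diffs, probs = c((1 - coverage) / 2, (1 + coverage) / 2),
                        type = 7, names = FALSE)
  d <- diffs[[gene]]
  percentile <- 100 * (sum(diffs < d) + (sum(diffs == d) + 1) / 2 - 0.5) /
    length(diffs)
  list(significant = d < qs[1] || d > qs[2], percentile = percentile,
       difference = d, interval = qs, n_genes = length(diffs))
}

#' Normality diagnostic for a value vector
#'
#' One-sample Kolmogorov-Smirnov check of standardized values against the
#' standard normal. Reported as a diagnostic alongside t-tests, never as a
#' gate.
#'
#' @param x numeric values (length >= 3, non-constant).
#' @return A list with `statistic` and `p`.
#' @export
normality_diagnostic <- function(x) {
  if (length(x) < 3 || stats::sd(x) == 0) stopf("need >= 3 non-constant values")
  ks <- suppressWarnings(stats::ks.test(scale(x)[, 1], "pnorm"))
  list(statistic = unname(ks$statistic), p = ks$p.value)
}
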
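#' Size-normalized growth rate (ADG per kg liveweight)
#'
#' Average daily gain divided by the average of the liveweights at the two
#' bounding time points (e.g. implant and slaughter), giving a growth rate per
#' unit body mass (1/day). This is the phenotype against which all gene
#' rankings are computed.
#'
#' @param adg average daily gain over the interval, kg/day.
#' @param weight_start,weight_end liveweight at the start and end of the
#'   interval, kg; both must be positive.
#' @return ADG/kg liveweight, 1/day.
#' @examples
#' compute_adg_per_kg(1.0, 400, 500)  # 1/450
#' @export
compute_adg_per_kg <- function(adg, weight_start, weight_end) {
  if (any(weight_start <= 0) || any(weight_end <= 0)) {
    stopf("liveweights must be positive")
  }
  adg / ((weight_start + weight_end) / 2)
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper used throughout the package for gene-phenotype and
#' profile-profile correlations.
#'
#' @param x,y numeric vectors of equal length (at least 3), neither constant.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3) stopf("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}

#' Rank all genes by correlation with a phenotype
#'
#' Computes the Pearson correlation of every gene's expression with a per-sample
#' phenotype (typically ADG/kg liveweight) and returns the genes sorted by
#' correlation. Genes with constant expression have undefined correlation and
#' are excluded (their count is reported in a message) rather than given an
#' arbitrary rank. Ties in r are broken by gene ID, ascending, so the ranking is
#' deterministic.
#'
#' @param matrix expression matrix (genes x samples).
#' @param phenotype numeric per-sample vector; if named, names are matched
#'   against the matrix sample IDs.
#' @param phenotype_name label stored with the result.
#' @param by `"signed"` (default) ranks by r descending; `"absolute"` ranks by
#'   |r| descending.
#' @return A data.frame with columns `gene`, `r`, `rank` (1-based, consecutive),
#'   carrying attributes `phenotype` and `n_samples`.
#' @export
rank_by_correlation <- function(matrix, phenotype,
                                phenotype_name = "adg_per_kg",
                                by = c("signed", "absolute")) {
  by <- match.arg(by)
  validate_expression(matrix)
  if (!is.null(names(phenotype))) {
    miss <- setdiff(colnames(matrix), names(phenotype))
    if (length(miss)) stopf("phenotype missing for sample(s): %s",
                            paste(miss, collapse = ", "))
    phenotype <- phenotype[colnames(matrix)]
  }
  if (length(phenotype) != ncol(matrix)) {
    stopf("phenotype length (%d) does not match sample count (%d)",
          length(phenotype), ncol(matrix))
  }
  if (ncol(matrix) < 3) stopf("need at least 3 samples to rank by correlation")
  if (stats::sd(phenotype) == 0) stopf("phenotype is constant; ranking undefined")
  sds <- apply(matrix, 1L, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sprintf("rank_by_correlation: excluded %d constant gene(s)", sum(constant)))
  }
  kept <- matrix[!constant, , drop = FALSE]
  r <- as.vector(stats::cor(t(kept), phenotype))
  key <- if (by == "signed") r else abs(r)
  ord <- order(-key, rownames(kept))
  out <- data.frame(gene = rownames(kept)[ord], r = r[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "phenotype") <- phenotype_name
  attr(out, "n_samples") <- ncol(matrix)
  out
}
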
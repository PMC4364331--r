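#' Upper-tail hypergeometric probability
#'
#' P(X >= b) where X counts term members among the first `n` genes drawn from a
#' universe of `N` genes of which `B` belong to the term. Accumulated in log
#' space (via `phyper(log.p = TRUE)`) so that enrichment tails of order 1e-17
#' do not underflow.
#'
#' @param b observed hits among the drawn genes.
#' @param N universe size.
#' @param B term (annotated set) size.
#' @param n number of genes drawn (list prefix length).
#' @return The one-sided over-representation probability in (0, 1\].
#' @export
hypergeometric_tail <- function(b, N, B, n) {
  if (any(B > N) || any(n > N) || any(b > pmin(n, B)) || any(b < 0)) {
    stopf("inconsistent hypergeometric counts (b=%s, N=%s, B=%s, n=%s)",
          toString(b), toString(N), toString(B), toString(n))
  }
  exp(stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE, log.p = TRUE))
}

#' Minimum hypergeometric (mHG) scan statistic for a ranked list
#'
#' Given a gene list ranked by association with a phenotype and a binary
#' membership vector for a term, scans every prefix length n = 1..N and
#' computes the hypergeometric upper tail of the hit count in that prefix; the
#' statistic is the minimum tail over all prefixes, i.e. the enrichment at the
#' data-driven optimal cutoff. Because the cutoff is chosen to minimize, the
#' statistic itself is not a p-value — see [mhg_exact_pvalue()].
#'
#' @param ranked_membership binary (0/1 or logical) vector over the ranked
#'   universe, 1 marking term members, best rank first.
#' @return A list with `mhg` (the minimum tail), `n_star` (earliest minimizing
#'   prefix length) and `b_star` (hits at that prefix). An all-zero vector
#'   yields `list(mhg = 1, n_star = 0, b_star = 0)`.
#' @export
mhg_statistic <- function(ranked_membership) {
  v <- as.integer(ranked_membership)
  if (any(is.na(v)) || any(v < 0 | v > 1)) stopf("membership must be binary")
  N <- length(v)
  if (N < 1) stopf("empty ranked list")
  B <- sum(v)
  if (B == 0) return(list(mhg = 1, n_star = 0L, b_star = 0L))
  b <- cumsum(v)
  n <- seq_len(N)
  tails <- exp(stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE, log.p = TRUE))
  n_star <- which.min(tails)  # which.min returns the earliest minimizer
  list(mhg = tails[n_star], n_star = n_star, b_star = b[n_star])
}

#' Exact p-value of the mHG scan statistic
#'
#' Probability, under a uniformly random ranking of the universe, that the
#' minimum hypergeometric statistic is as small or smaller than the observed
#' `mhg`. Computed by a dynamic program over the lattice of (prefix length,
#' hit count) states: the rank order of the B term members is an exchangeable
#' path from (0, 0) to (N, B), and the DP accumulates the probability mass of
#' paths that never enter a cell whose hypergeometric tail is <= `mhg`; the
#' p-value is one minus the surviving mass. When the state lattice exceeds
#' `cap` cells the DP is replaced by a seeded Monte-Carlo permutation estimate.
#'
#' @param mhg observed minimum hypergeometric statistic.
#' @param N universe size.
#' @param B term size.
#' @param cap maximum N*B lattice size for the exact DP (default 1e7).
#' @param n_perm permutations for the Monte-Carlo fallback.
#' @param seed seed for the fallback; ignored by the exact route.
#' @return The exact (or estimated) p-value in (0, 1\].
#' @export
mhg_exact_pvalue <- function(mhg, N, B, cap = 1e7, n_perm = 20000, seed = 1L) {
  assert_count(N, "N")
  assert_count(B, "B", min = 0L)
  if (B > N) stopf("B cannot exceed N")
  if (B == 0 || mhg >= 1) return(1)
  if (as.double(N) * as.double(B) > cap) {
    return(mhg_permutation_pvalue(mhg, N, B, n_perm = n_perm, seed = seed))
  }
  # Relative tolerance so ties at the observed statistic count as hits.
  thr <- mhg * (1 + 1e-9)
  # b_crit[n]: smallest hit count at prefix n whose tail is <= mhg (flagged).
  # log-space tails, vectorized per prefix.
  b_crit <- rep.int(B + 1L, N)
  for (n in seq_len(N)) {
    b_max <- min(n, B)
    b_min <- max(0L, n - (N - B))
    bs <- b_min:b_max
    tails <- exp(stats::phyper(bs - 1, B, N - B, n, lower.tail = FALSE, log.p = TRUE))
    hit <- which(tails <= thr)
    if (length(hit)) b_crit[n] <- bs[hit[1]]
  }
  # prob[b + 1] = P(prefix of length n has b hits and never entered a flagged
  # cell). Transitions follow the exchangeable draw-without-replacement chain.
  prob <- numeric(B + 1L)
  prob[1L] <- 1
  removed <- 0  # mass entering flagged cells = P(scan minimum <= mhg)
  for (n in seq_len(N)) {
    remaining <- N - n + 1L
    b_prev <- 0:B
    p_hit <- pmax(B - b_prev, 0) / remaining
    new <- prob * (1 - p_hit)
    new[-1L] <- new[-1L] + prob[-(B + 1L)] * p_hit[-(B + 1L)]
    flagged <- (0:B) >= b_crit[n]
    removed <- removed + sum(new[flagged])
    new[flagged] <- 0
    prob <- new
  }
  min(max(removed, 0), 1)
}

mhg_permutation_pvalue <- function(mhg, N, B, n_perm, seed) {
  with_seed(seed, {
    thr <- mhg * (1 + 1e-9)
    hits <- 0L
    base <- c(rep(1L, B), rep(0L, N - B))
    for (i in seq_len(n_perm)) {
      stat <- mhg_statistic(sample(base))$mhg
      if (stat <= thr) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up FDR adjustment mapped back to the input order, as used for every
#' multiple-testing correction in the package.
#'
#' @param pvalues numeric vector of p-values, each in (0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Ranked-list GO enrichment via the mHG statistic
#'
#' For each annotation term, builds the binary membership vector over the
#' ranked gene universe, computes the minimum hypergeometric statistic at the
#' data-driven optimal cutoff, converts it to an exact p-value and applies BH
#' FDR across the tested terms. This is the ranked-list (threshold-free)
#' enrichment used to find biological processes concentrated at the top of the
#' phenotype-correlation ranking.
#'
#' @param ranked a ranking as returned by [rank_by_correlation()], or a
#'   character vector of genes in rank order.
#' @param annotation a named list of member-gene vectors (see [read_gmt()]).
#' @param min_term_size,max_term_size term-size bounds after harmonization to
#'   the ranked universe.
#' @param cap,n_perm,seed passed to [mhg_exact_pvalue()].
#' @return A data.frame sorted by p ascending with columns `term`, `name`, `N`,
#'   `B`, `n_star`, `b_star`, `mhg`, `p`, `q`.
#' @export
enrich_ranked_list <- function(ranked, annotation, min_term_size = 5,
                               max_term_size = 2000, cap = 1e7,
                               n_perm = 20000, seed = 1L) {
  genes <- if (is.data.frame(ranked)) ranked$gene else as.character(ranked)
  if (anyDuplicated(genes)) stopf("ranked list contains duplicate genes")
  N <- length(genes)
  descs <- attr(annotation, "descriptions")
  if (length(annotation) == 0) {
    warnf("enrich_ranked_list: empty annotation")
    return(data.frame(term = character(0), name = character(0), N = integer(0),
                      B = integer(0), n_star = integer(0), b_star = integer(0),
                      mhg = numeric(0), p = numeric(0), q = numeric(0)))
  }
  rows <- lapply(names(annotation), function(id) {
    members <- intersect(annotation[[id]], genes)
    B <- length(members)
    if (B < min_term_size || B > max_term_size) return(NULL)
    membership <- as.integer(genes %in% members)
    stat <- mhg_statistic(membership)
    p <- mhg_exact_pvalue(stat$mhg, N, B, cap = cap, n_perm = n_perm, seed = seed)
    data.frame(term = id,
               name = if (!is.null(descs)) descs[[id]] else id,
               N = N, B = B, n_star = stat$n_star, b_star = stat$b_star,
               mhg = stat$mhg, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    warnf("enrich_ranked_list: no term within the size bounds")
    return(data.frame(term = character(0), name = character(0), N = integer(0),
                      B = integer(0), n_star = integer(0), b_star = integer(0),
                      mhg = numeric(0), p = numeric(0), q = numeric(0)))
  }
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Fixed-set hypergeometric enrichment of a gene cluster
#'
#' One-sided over-representation test of each annotation term within a cluster
#' of genes, with the clustered-gene set as the universe and BH FDR across
#' terms. Used to annotate k-means clusters with their enriched biological
#' processes.
#'
#' @param cluster_genes character vector of genes in the cluster.
#' @param annotation named list of member-gene vectors.
#' @param universe character vector of all clustered genes; the cluster must be
#'   a subset.
#' @param min_term_size minimum term size within the universe.
#' @return A data.frame with columns `term`, `N`, `B`, `n`, `b`, `p`, `q`,
#'   sorted by p ascending.
#' @export
enrich_cluster <- function(cluster_genes, annotation, universe, min_term_size = 2) {
  if (length(cluster_genes) == 0) stopf("empty cluster")
  if (!all(cluster_genes %in% universe)) {
    stopf("cluster contains gene(s) outside the universe: %s",
          paste(utils::head(setdiff(cluster_genes, universe), 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(cluster_genes)
  rows <- lapply(names(annotation), function(id) {
    members <- intersect(annotation[[id]], universe)
    B <- length(members)
    if (B < min_term_size) return(NULL)
    b <- length(intersect(members, cluster_genes))
    data.frame(term = id, N = N, B = B, n = n, b = b,
               p = hypergeometric_tail(b, N, B, n), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(term = character(0), N = integer(0), B = integer(0),
                      n = integer(0), b = integer(0), p = numeric(0), q = numeric(0)))
  }
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}
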
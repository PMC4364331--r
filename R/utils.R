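#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards so package functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ", "))
  }
  invisible(as.integer(x))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, computed
#' from the contingency table of label co-occurrences. Used to benchmark cluster
#' recovery against recorded simulation truth.
#'
#' @param labels1,labels2 vectors of cluster labels of equal length.
#' @return A single number in \[-1, 1\]; 1 means identical partitions, 0 is the
#'   expectation under independent random partitions.
#' @export
adjusted_rand_index <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) {
    stopf("label vectors differ in length (%d vs %d)", length(labels1), length(labels2))
  }
  tab <- table(labels1, labels2)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# md5 of a set of files, named by relative path; used by the pipeline manifest.
file_checksums <- function(paths, root = NULL) {
  sums <- tools::md5sum(paths)
  if (!is.null(root)) {
    names(sums) <- sub(paste0("^", root, "/?"), "", names(sums))
  }
  sums
}
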
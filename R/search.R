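#' Exhaustive maximum-diversity subset search
#'
#' Enumerates all `choose(m, k)` size-`k` subsets of the populations in
#' lexicographic order of row indices, scores each with the requested
#' measure (per-locus scores summed over loci), and returns *every* subset
#' attaining the maximum within a small score tolerance — distinct subsets
#' can tie exactly, so ties are first-class results, not an error.
#'
#' No pruning is attempted: optimal totals need not be monotone in `k`
#' (averaging-type measures can decrease as populations are added), so
#' brute force is the correct baseline.
#'
#' @param M a [frequency_matrix()].
#' @param k subset size, `1 <= k <= nrow(M)`.
#' @param measure one of [diversity_measures()].
#' @param tol score tolerance for declaring a tie with the maximum. Totals
#'   are sums of thousands of doubles, so exact equality is too strict;
#'   default `1e-9`.
#' @return an object of class `search_result`: list with `measure`, `k`,
#'   `optimal_subsets` (list of character vectors, all ties), `optimal_score`
#'   and `evaluated_count`.
#' @examples
#' M <- frequency_matrix(cbind(p = c(0, 0.5, 1)))
#' max_diversity_exhaustive(M, 2, "het_pooling")
#' @export
max_diversity_exhaustive <- function(M, k, measure, tol = 1e-9) {
  M <- as_freq_matrix(M)
  m <- nrow(M)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > m || k != round(k)) {
    stop_invalid(sprintf("`k` must be an integer in 1..%d", m))
  }
  k <- as.integer(k)
  idx <- combn(m, k)
  scores <- unname(subset_scores(M, idx, measures = measure)[, 1L])
  best <- max(scores)
  ties <- which(abs(scores - best) <= tol)
  structure(
    list(
      measure = measure,
      k = k,
      optimal_subsets = lapply(ties, function(j) rownames(M)[idx[, j]]),
      optimal_score = best,
      evaluated_count = ncol(idx)
    ),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result> %s, k = %d: optimal score %.6g over %d subsets\n",
    x$measure, x$k, x$optimal_score, x$evaluated_count
  ))
  for (s in x$optimal_subsets) cat("  {", paste(s, collapse = ", "), "}\n")
  invisible(x)
}

#' Serialize a search result to JSON
#'
#' @param x a `search_result`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
search_result_json <- function(x, path = NULL) {
  obj <- list(
    measure = x$measure,
    k = x$k,
    score = x$optimal_score,
    subsets = x$optimal_subsets,
    evaluated = x$evaluated_count
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Sample random population subsets of fixed size
#'
#' Draws `N` subsets of `k` distinct population indices uniformly at random.
#' Sampling is with replacement at the subset level by default (the same
#' subset may recur across draws); each subset never repeats a population
#' internally. Reproducible for a given `seed`.
#'
#' @param m number of populations.
#' @param k subset size, `k <= m`.
#' @param N number of subsets to draw.
#' @param seed RNG seed (required — these draws feed sampled correlation
#'   estimates that must be re-runnable).
#' @param replace if `FALSE`, distinct subsets are enforced across draws
#'   (requires `N <= choose(m, k)`).
#' @return list of `N` sorted integer vectors of length `k`.
#' @export
sample_subsets <- function(m, k, N, seed, replace = TRUE) {
  if (k > m || k < 1L) stop_invalid("`k` must be in 1..m")
  if (N < 1L) stop_invalid("`N` must be at least 1")
  if (!replace && N > choose(m, k)) {
    stop_invalid("without replacement, `N` cannot exceed choose(m, k)")
  }
  with_seed(seed, {
    if (replace) {
      lapply(seq_len(N), function(i) sort(sample.int(m, k)))
    } else {
      seen <- new.env(hash = TRUE)
      out <- vector("list", N)
      got <- 0L
      while (got < N) {
        s <- sort(sample.int(m, k))
        key <- paste(s, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- s
        }
      }
      out
    }
  })
}
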
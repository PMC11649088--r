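#' Pearson correlation with explicit degeneracy handling
#'
#' Standard product-moment correlation, but a constant input is reported as
#' an error of class `popdiv_undefined_correlation` rather than a silent
#' `NA`: integer-valued scores (e.g. pooled SSD) degenerate easily, and a
#' correlation matrix should flag those pairs, not hide them.
#'
#' @param xs,ys numeric vectors of equal length `>= 2`.
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop_invalid("`xs` and `ys` must have equal length")
  if (length(xs) < 2L) stop_invalid("need at least two observations")
  if (anyNA(xs) || anyNA(ys)) stop_invalid("inputs must not contain NA")
  if (var(xs) == 0 || var(ys) == 0) {
    stop_invalid("correlation undefined: an input has zero variance",
                 class = "popdiv_undefined_correlation")
  }
  cor(xs, ys)
}

#' Standard error of a sampled Pearson correlation
#'
#' `se = (1 - r^2) / sqrt(N - 3)`, the large-sample standard error used to
#' assess correlations estimated from `N` randomly sampled subsets.
#'
#' @param r Pearson correlation coefficient.
#' @param N number of observations, `> 3`.
#' @return the standard error (0 when `|r| = 1`).
#' @examples
#' correlation_se(0, 1000) # 1/sqrt(997)
#' @export
correlation_se <- function(r, N) {
  if (!is.numeric(N) || any(N <= 3)) stop_invalid("`N` must exceed 3")
  (1 - r^2) / sqrt(N - 3)
}

#' Pairwise correlations of diversity measures over subsets of fixed size
#'
#' For each subset in the chosen collection (all `choose(m, k)` subsets, or
#' `N` sampled ones), the locus-summed total of every requested measure is
#' computed once; Pearson correlations are then taken between each pair of
#' measures across the shared subset list. Pairs where a score vector is
#' constant are flagged in the `note` column with `r = NA` instead of
#' aborting the whole analysis.
#'
#' @param M a [frequency_matrix()].
#' @param k subset size.
#' @param measures measure identifiers; default all eight.
#' @param mode `"exhaustive"` (all subsets; feasible for small `k`) or
#'   `"sampled"` (`N` random subsets, subset-level replacement).
#' @param N number of sampled subsets (sampled mode).
#' @param seed RNG seed (required in sampled mode).
#' @param replace passed to [sample_subsets()].
#' @return a data frame of class `correlation_report` with columns
#'   `measure_x`, `measure_y`, `k`, `r`, `se`, `n_subsets`, `mode`, `seed`,
#'   `note`. `se` is `NA` when `n_subsets <= 3`.
#' @export
correlation_matrix <- function(M, k, measures = diversity_measures(),
                               mode = c("exhaustive", "sampled"),
                               N = 1000L, seed = NULL, replace = TRUE) {
  M <- as_freq_matrix(M)
  mode <- match.arg(mode)
  m <- nrow(M)
  if (k < 1L || k > m) stop_invalid(sprintf("`k` must be in 1..%d", m))
  if (length(measures) < 2L) stop_invalid("need at least two measures to correlate")

  if (mode == "exhaustive") {
    subsets <- combn(m, k)
    seed_used <- NA_integer_
  } else {
    if (is.null(seed)) stop_invalid("`seed` is required in sampled mode")
    subsets <- sample_subsets(m, k, N, seed = seed, replace = replace)
    seed_used <- as.integer(seed)
  }
  scores <- subset_scores(M, subsets, measures = measures)
  n_sub <- nrow(scores)

  pairs <- combn(measures, 2L)
  res <- data.frame(
    measure_x = pairs[1L, ], measure_y = pairs[2L, ],
    k = k, r = NA_real_, se = NA_real_,
    n_subsets = n_sub, mode = mode, seed = seed_used,
    note = "", stringsAsFactors = FALSE
  )
  for (i in seq_len(ncol(pairs))) {
    r <- tryCatch(
      pearson_r(scores[, pairs[1L, i]], scores[, pairs[2L, i]]),
      popdiv_undefined_correlation = function(e) NA_real_
    )
    res$r[i] <- r
    if (is.na(r)) {
      res$note[i] <- "undefined: constant score vector"
    } else if (n_sub > 3L) {
      res$se[i] <- correlation_se(r, n_sub)
    }
  }
  class(res) <- c("correlation_report", class(res))
  res
}

#' Single-locus versus locus-summed correlation comparison
#'
#' Diagnostic for the claim that, with loci behaving as independent
#' replicates, the correlation between two measures computed on locus-summed
#' totals matches the correlation at a single locus. Computes, over the same
#' subset collection, (a) the Pearson r between the two measures' totals
#' summed over loci, and (b) the per-locus r at each individual locus.
#'
#' @param M a [frequency_matrix()] whose columns are (ideally) i.i.d. draws.
#' @param k subset size (exhaustive enumeration).
#' @param pair character vector of two measure identifiers.
#' @return list with `summed_r`, `per_locus_r` (numeric vector, `NA` where
#'   degenerate), and `mean_locus_r` over the defined loci.
#' @export
locus_sum_correlation_check <- function(M, k, pair) {
  M <- as_freq_matrix(M)
  if (length(pair) != 2L) stop_invalid("`pair` must name exactly two measures")
  subsets <- combn(nrow(M), k)
  totals <- subset_scores(M, subsets, measures = pair)
  summed_r <- pearson_r(totals[, 1L], totals[, 2L])
  per_locus_r <- vapply(seq_len(ncol(M)), function(j) {
    Mj <- frequency_matrix(unclass_freq(M)[, j, drop = FALSE])
    sc <- subset_scores(Mj, subsets, measures = pair)
    tryCatch(pearson_r(sc[, 1L], sc[, 2L]),
             popdiv_undefined_correlation = function(e) NA_real_)
  }, numeric(1))
  list(
    summed_r = summed_r,
    per_locus_r = per_locus_r,
    mean_locus_r = mean(per_locus_r, na.rm = TRUE)
  )
}

#' Write a correlation report to CSV
#'
#' @param report a `correlation_report` (or a row-bound set of them).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Plot correlation trends against subset size
#'
#' Simple base-graphics trend plot: one line per measure pair, correlation
#' `r` against `k`.
#'
#' @param reports a row-bound `correlation_report` covering several `k`.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the wide `k` x pair matrix of correlations plotted.
#' @export
plot_correlation_trends <- function(reports, ...) {
  df <- as.data.frame(reports)
  df$pair <- paste(df$measure_x, df$measure_y, sep = " ~ ")
  ks <- sort(unique(df$k))
  pairs <- unique(df$pair)
  wide <- matrix(NA_real_, nrow = length(ks), ncol = length(pairs),
                 dimnames = list(ks, pairs))
  for (i in seq_len(nrow(df))) wide[as.character(df$k[i]), df$pair[i]] <- df$r[i]
  graphics::matplot(ks, wide, type = "b", pch = 19, lty = 1,
                    xlab = "subset size k", ylab = "Pearson r",
                    ylim = c(-1, 1), ...)
  graphics::abline(h = 0, col = "grey70", lty = 2)
  graphics::legend("bottomright", legend = pairs, col = seq_along(pairs),
                   lty = 1, cex = 0.6, bty = "n")
  invisible(wide)
}
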
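#' Single-population diversity of a binary allele vector
#'
#' Per-locus diversity of one population of haplotypes scored 0/1. Expected
#' heterozygosity is the probability that two individuals drawn uniformly with
#' replacement differ in allele: `2p(1-p)` for allele-1 fraction `p`. Split
#' system diversity (SSD) is the indicator that both states are present.
#'
#' Each measure has three algebraically equivalent formulations, selectable
#' via `form`; the alternatives exist chiefly as cross-checks and because the
#' `linear` form (linear in each `x_i`) is the one whose expectation under
#' independent fixation yields the fixing measures.
#'
#' @param x binary vector (0/1) of allele states, one individual each.
#' @param form which formulation to evaluate: `"frequency"` (in terms of
#'   `p = mean(x)`), `"pairwise"` (in terms of `(x_i - x_j)^2`), or
#'   `"linear"` (linear in each `x_i`).
#' @return a single numeric score: in `[0, 0.5]` for `het_ind`, `{0, 1}` for
#'   `ssd_ind`.
#' @examples
#' het_ind(c(0, 1, 1, 0)) # p = 0.5 -> 0.5
#' ssd_ind(c(1, 1, 1))    # monomorphic -> 0
#' @export
het_ind <- function(x, form = c("frequency", "pairwise", "linear")) {
  form <- match.arg(form)
  check_binary(x)
  n <- length(x)
  switch(form,
    frequency = {
      p <- mean(x)
      2 * p * (1 - p)
    },
    pairwise = sum(outer(x, x, function(a, b) (a - b)^2)) / n^2,
    linear = {
      g <- outer(x, x, function(a, b) 1 - a * b - (1 - a) * (1 - b))
      diag(g) <- 0
      sum(g) / n^2
    }
  )
}

#' @rdname het_ind
#' @export
ssd_ind <- function(x, form = c("frequency", "pairwise", "linear")) {
  form <- match.arg(form)
  check_binary(x)
  switch(form,
    frequency = {
      p <- mean(x)
      as.numeric(p > 0 && p < 1)
    },
    pairwise = max(outer(x, x, function(a, b) (a - b)^2)),
    linear = 1 - prod(x) - prod(1 - x)
  )
}

check_binary <- function(x) {
  if (length(x) == 0L) stop_invalid("`x` must be a nonempty binary vector")
  if (anyNA(x) || any(x != 0 & x != 1)) {
    stop_invalid("`x` entries must be 0 or 1")
  }
  invisible(x)
}

check_freqs <- function(p) {
  if (length(p) == 0L) stop_invalid("`p` must be a nonempty frequency vector")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_invalid("`p` entries must lie in [0, 1]")
  }
  invisible(p)
}

check_weights <- function(w, m) {
  if (is.null(w)) return(NULL)
  if (length(w) != m || any(!is.finite(w)) || any(w <= 0)) {
    stop_invalid("`weights` must be positive and match the number of populations")
  }
  w / sum(w)
}

#' Collection-level diversity at a single locus
#'
#' The eight per-locus diversity scores for a collection of `m` populations
#' with per-population allele-1 frequencies `p = (p_1, ..., p_m)` (equal
#' population sizes unless `weights` is given). With `pbar = mean(p)`:
#'
#' * `het_pooling`: `2 * pbar * (1 - pbar)` — heterozygosity of the pooled
#'   population (total gene diversity); population structure is ignored.
#' * `het_averaging`: `mean(2 * p * (1 - p))` — within-population
#'   heterozygosity averaged over populations.
#' * `het_differencing`: `(1/m^2) * sum_{i,j} (p_i - p_j)^2` — the
#'   between-population component; equal to twice the (population) variance
#'   of the `p_i`.
#' * `het_fixing`: `(1/m^2) * sum_{i != j} [1 - p_i p_j - (1-p_i)(1-p_j)]` —
#'   expected heterozygosity of one individual sampled per population after
#'   each population drifts to fixation (fixing on allele 1 w.p. `p_i`).
#' * `ssd_pooling`: 1 iff `0 < pbar < 1` — both alleles survive pooling.
#' * `ssd_averaging`: fraction of populations with `0 < p_i < 1`.
#' * `ssd_differencing`: `max_{i,j} (p_i - p_j)^2` — squared range.
#' * `ssd_fixing`: `1 - prod(p) - prod(1 - p)` — probability that one draw
#'   per post-fixation population exhibits both states.
#'
#' `weights` (per-population sizes) are honoured by the pooling and averaging
#' measures as weighted means; the differencing and fixing measures have no
#' weighted form here and ignore sizes.
#'
#' @param p numeric vector of per-population frequencies, each in `[0, 1]`.
#' @param weights optional positive per-population weights (e.g. sample
#'   sizes); normalised internally.
#' @return a single numeric per-locus score.
#' @examples
#' het_pooling(c(0.1, 0.9))      # 0.5, same as c(0.5, 0.5)
#' het_averaging(c(0.1, 0.9))    # 0.18
#' het_differencing(c(0.1, 0.9)) # 0.32
#' het_fixing(c(0.1, 0.9))       # 0.41
#' @export
het_pooling <- function(p, weights = NULL) {
  check_freqs(p)
  w <- check_weights(weights, length(p))
  pbar <- if (is.null(w)) mean(p) else sum(w * p)
  2 * pbar * (1 - pbar)
}

#' @rdname het_pooling
#' @export
het_averaging <- function(p, weights = NULL) {
  check_freqs(p)
  w <- check_weights(weights, length(p))
  h <- 2 * p * (1 - p)
  if (is.null(w)) mean(h) else sum(w * h)
}

#' @rdname het_pooling
#' @export
het_differencing <- function(p) {
  check_freqs(p)
  m <- length(p)
  sum(outer(p, p, function(a, b) (a - b)^2)) / m^2
}

#' @rdname het_pooling
#' @export
het_fixing <- function(p) {
  check_freqs(p)
  m <- length(p)
  if (m == 1L) return(0)
  g <- outer(p, p, function(a, b) 1 - a * b - (1 - a) * (1 - b))
  diag(g) <- 0
  sum(g) / m^2
}

#' @rdname het_pooling
#' @export
ssd_pooling <- function(p, weights = NULL) {
  check_freqs(p)
  w <- check_weights(weights, length(p))
  pbar <- if (is.null(w)) mean(p) else sum(w * p)
  as.numeric(pbar > 0 && pbar < 1)
}

#' @rdname het_pooling
#' @export
ssd_averaging <- function(p, weights = NULL) {
  check_freqs(p)
  w <- check_weights(weights, length(p))
  s <- as.numeric(p > 0 & p < 1)
  if (is.null(w)) mean(s) else sum(w * s)
}

#' @rdname het_pooling
#' @export
ssd_differencing <- function(p) {
  check_freqs(p)
  (max(p) - min(p))^2
}

#' @rdname het_pooling
#' @export
ssd_fixing <- function(p) {
  check_freqs(p)
  1 - prod(p) - prod(1 - p)
}

#' The stable identifiers of the eight collection-level measures
#'
#' @return character vector
#' `c("het_pooling", ..., "ssd_fixing")`, base measure varying slowest.
#' @export
diversity_measures <- function() {
  c(
    "het_pooling", "het_averaging", "het_differencing", "het_fixing",
    "ssd_pooling", "ssd_averaging", "ssd_differencing", "ssd_fixing"
  )
}

measure_fun <- function(measure_id) {
  switch(measure_id,
    het_pooling = het_pooling,
    het_averaging = het_averaging,
    het_differencing = het_differencing,
    het_fixing = het_fixing,
    ssd_pooling = ssd_pooling,
    ssd_averaging = ssd_averaging,
    ssd_differencing = ssd_differencing,
    ssd_fixing = ssd_fixing,
    stop_invalid(sprintf(
      "unknown measure '%s'; see diversity_measures()", measure_id
    ))
  )
}

#' Total diversity of a population subset, per locus and summed
#'
#' Applies one collection-level measure locus by locus to the sub-matrix of a
#' frequency matrix given by `subset`, and sums the per-locus scores into the
#' subset's total diversity score.
#'
#' @param M a [frequency_matrix()].
#' @param subset character vector of population labels (or integer row
#'   indices); default all populations.
#' @param measure one of [diversity_measures()].
#' @param weighted if `TRUE` and `M` carries per-population sizes, the
#'   pooling/averaging measures use size-weighted means.
#' @return an object of class `diversity_result`: a list with elements
#'   `measure`, `subset`, `per_locus` (named numeric vector) and `total`.
#' @examples
#' M <- frequency_matrix(rbind(A = c(0.1, 0.1), B = c(0.9, 0.9)))
#' collection_diversity(M, c("A", "B"), "het_averaging")
#' @export
collection_diversity <- function(M, subset = NULL, measure, weighted = FALSE) {
  M <- as_freq_matrix(M)
  fn <- measure_fun(measure)
  idx <- resolve_subset(M, subset)
  w <- NULL
  if (weighted && measure %in% c("het_pooling", "het_averaging", "ssd_pooling", "ssd_averaging")) {
    sz <- pop_sizes(M)
    if (!is.null(sz)) w <- sz[idx]
  }
  sub <- unclass_freq(M)[idx, , drop = FALSE]
  per_locus <- if (is.null(w)) {
    apply(sub, 2L, fn)
  } else {
    apply(sub, 2L, fn, weights = w)
  }
  structure(
    list(
      measure = measure,
      subset = rownames(M)[idx],
      per_locus = per_locus,
      total = sum(per_locus)
    ),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf(
    "<diversity_result> %s over {%s}: total = %.6g (%d loci)\n",
    x$measure, paste(x$subset, collapse = ", "), x$total, length(x$per_locus)
  ))
  invisible(x)
}

resolve_subset <- function(M, subset) {
  if (is.null(subset)) return(seq_len(nrow(M)))
  if (length(subset) == 0L) stop_invalid("`subset` must be nonempty")
  if (is.numeric(subset)) {
    idx <- as.integer(subset)
    if (any(idx < 1L | idx > nrow(M))) {
      stop_invalid("subset indices out of range", class = "popdiv_unknown_label")
    }
  } else {
    idx <- match(as.character(subset), rownames(M))
    if (anyNA(idx)) {
      stop_invalid(
        sprintf(
          "unknown population label(s): %s",
          paste(subset[is.na(idx)], collapse = ", ")
        ),
        class = "popdiv_unknown_label"
      )
    }
  }
  if (anyDuplicated(idx)) stop_invalid("`subset` must not repeat populations")
  idx
}

#' Total diversity scores for many subsets at once
#'
#' Vectorised fast path used by the subset search and correlation analyses:
#' computes the locus-summed total of each requested measure for every subset
#' in one pass, from per-locus column sums over the subset's rows. Agrees
#' with [collection_diversity()] applied subset by subset (this is asserted
#' in the test suite); per-locus vectors are not retained.
#'
#' @param M a [frequency_matrix()].
#' @param subsets a list of subsets (population labels or row indices), or an
#'   integer matrix with one subset per column.
#' @param measures character vector of measure identifiers.
#' @return numeric matrix, `length(subsets)` rows x `length(measures)`
#'   columns.
#' @export
subset_scores <- function(M, subsets, measures = diversity_measures()) {
  M <- as_freq_matrix(M)
  bad <- setdiff(measures, diversity_measures())
  if (length(bad) > 0L) {
    stop_invalid(sprintf("unknown measure '%s'; see diversity_measures()", bad[1L]))
  }
  if (is.matrix(subsets)) {
    idx_list <- lapply(seq_len(ncol(subsets)), function(j) subsets[, j])
  } else {
    idx_list <- subsets
  }
  idx_list <- lapply(idx_list, function(s) resolve_subset(M, s))

  P <- unclass_freq(M)
  L <- ncol(P)
  P2 <- P * P
  # Per-population locus totals reused across subsets (O(1) per subset).
  row_het <- rowSums(2 * P * (1 - P))
  row_poly <- rowSums(P > 0 & P < 1)

  out <- matrix(NA_real_, nrow = length(idx_list), ncol = length(measures),
                dimnames = list(NULL, measures))
  need_s1 <- any(measures %in% c(
    "het_pooling", "het_differencing", "het_fixing", "ssd_pooling"
  ))
  need_s2 <- any(measures %in% c("het_differencing", "het_fixing"))
  need_rng <- "ssd_differencing" %in% measures
  need_prod <- "ssd_fixing" %in% measures

  for (s in seq_along(idx_list)) {
    idx <- idx_list[[s]]
    k <- length(idx)
    if (need_s1) {
      s1 <- .colSums(P[idx, , drop = FALSE], k, L)
      pbar <- s1 / k
    }
    if (need_s2) s2 <- .colSums(P2[idx, , drop = FALSE], k, L)
    for (ci in seq_along(measures)) {
      mm <- measures[ci]
      out[s, ci] <- switch(mm,
        het_pooling = sum(2 * pbar * (1 - pbar)),
        het_averaging = sum(row_het[idx]) / k,
        het_differencing = sum(2 * (s2 / k - pbar^2)),
        het_fixing = if (k == 1L) 0 else
          sum(k^2 - s1^2 - (k - s1)^2 - 2 * s1 + 2 * s2) / k^2,
        ssd_pooling = sum(s1 > 0 & s1 < k),
        ssd_averaging = sum(row_poly[idx]) / k,
        ssd_differencing = {
          cmax <- P[idx[1L], ]
          cmin <- cmax
          for (i in idx[-1L]) {
            cmax <- pmax(cmax, P[i, ])
            cmin <- pmin(cmin, P[i, ])
          }
          sum((cmax - cmin)^2)
        },
        ssd_fixing = {
          pr1 <- P[idx[1L], ]
          pr0 <- 1 - P[idx[1L], ]
          for (i in idx[-1L]) {
            pr1 <- pr1 * P[i, ]
            pr0 <- pr0 * (1 - P[i, ])
          }
          sum(1 - pr1 - pr0)
        }
      )
    }
  }
  out
}
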
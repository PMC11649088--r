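#' Construct a population-by-locus allele-frequency matrix
#'
#' The central container of the package: an `m x L` numeric matrix whose entry
#' `p[i, j]` is the minor-allele frequency of population `i` at locus `j`,
#' with population labels as row names, locus labels as column names, and
#' optionally a vector of per-population sample sizes (used by the
#' size-weighted pooling/averaging variants).
#'
#' @param p numeric matrix (or object coercible to one) with entries in
#'   `[0, 1]`. Rows are populations, columns are loci.
#' @param populations character vector of population labels; defaults to the
#'   row names of `p`, or `pop1, pop2, ...`.
#' @param loci character vector of locus labels; defaults to the column names
#'   of `p`, or `locus1, locus2, ...`.
#' @param sizes optional numeric vector of positive per-population sample
#'   sizes, length `m`.
#' @return an object of class `freq_matrix`: the numeric matrix with dimnames
#'   set and, if supplied, a `sizes` attribute.
#' @examples
#' frequency_matrix(rbind(A = c(0.1, 0.2), B = c(0.9, 0.0)))
#' @export
frequency_matrix <- function(p, populations = NULL, loci = NULL, sizes = NULL) {
  p <- as.matrix(p)
  if (!is.numeric(p) || nrow(p) < 1L || ncol(p) < 1L) {
    stop_invalid("`p` must be a numeric matrix with at least one row and column")
  }
  if (anyNA(p)) stop_invalid("`p` must not contain missing values")
  if (any(p < 0 | p > 1)) {
    bad <- which(p < 0 | p > 1, arr.ind = TRUE)[1L, ]
    stop_validation(sprintf(
      "allele frequencies must lie in [0, 1]; first violation at row %d, column %d (value %g)",
      bad[1L], bad[2L], p[bad[1L], bad[2L]]
    ))
  }
  if (is.null(populations)) populations <- rownames(p)
  if (is.null(populations)) populations <- paste0("pop", seq_len(nrow(p)))
  if (is.null(loci)) loci <- colnames(p)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(p)))
  if (length(populations) != nrow(p) || anyDuplicated(populations)) {
    stop_invalid("`populations` must be unique labels, one per row")
  }
  if (length(loci) != ncol(p)) stop_invalid("`loci` must have one label per column")
  dimnames(p) <- list(as.character(populations), as.character(loci))
  if (!is.null(sizes)) {
    if (length(sizes) != nrow(p) || any(!is.finite(sizes)) || any(sizes <= 0)) {
      stop_invalid("`sizes` must be positive and of length nrow(p)")
    }
    sizes <- as.numeric(sizes)
    names(sizes) <- rownames(p)
    attr(p, "sizes") <- sizes
  }
  class(p) <- c("freq_matrix", class(p))
  p
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf(
    "<freq_matrix> %d populations x %d loci%s\n",
    nrow(x), ncol(x),
    if (is.null(attr(x, "sizes"))) "" else " (with population sizes)"
  ))
  print(unclass_freq(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}

unclass_freq <- function(x) {
  attr(x, "sizes") <- NULL
  class(x) <- "matrix"
  x
}

#' @rdname frequency_matrix
#' @param M a `freq_matrix`.
#' @export
populations <- function(M) rownames(M)

#' @rdname frequency_matrix
#' @export
loci <- function(M) colnames(M)

#' @rdname frequency_matrix
#' @export
pop_sizes <- function(M) attr(M, "sizes")

as_freq_matrix <- function(M) {
  if (inherits(M, "freq_matrix")) M else frequency_matrix(M)
}

#' Construct a binary individuals-by-loci matrix for one population
#'
#' Holds the minority-allele presence/absence encoding of one population:
#' entry `x[i, j]` is 1 if individual `i` carries at least one copy of the
#' minority allele at locus `j`, 0 otherwise, `NA` if the genotype is missing.
#'
#' @param states matrix of 0/1/`NA` values, individuals in rows.
#' @param individuals optional individual labels (default `ind1, ...`).
#' @param loci optional locus labels (default `locus1, ...`).
#' @return an object of class `indiv_matrix`.
#' @examples
#' individual_matrix(rbind(c(0, 1), c(1, 1)))
#' @export
individual_matrix <- function(states, individuals = NULL, loci = NULL) {
  states <- as.matrix(states)
  if (!is.numeric(states) || nrow(states) < 1L || ncol(states) < 1L) {
    stop_invalid("`states` must be a numeric matrix with at least one row and column")
  }
  vals <- states[!is.na(states)]
  if (any(vals != 0 & vals != 1)) {
    stop_invalid("`states` entries must be 0, 1 or NA")
  }
  if (is.null(individuals)) individuals <- rownames(states)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(states)))
  if (is.null(loci)) loci <- colnames(states)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(states)))
  dimnames(states) <- list(as.character(individuals), as.character(loci))
  class(states) <- c("indiv_matrix", class(states))
  states
}

#' @export
print.indiv_matrix <- function(x, ...) {
  cat(sprintf("<indiv_matrix> %d individuals x %d loci\n", nrow(x), ncol(x)))
  y <- x
  class(y) <- "matrix"
  print(y[seq_len(min(6L, nrow(y))), seq_len(min(6L, ncol(y))), drop = FALSE])
  invisible(x)
}

#' Collapse per-population individual matrices to an allele-frequency matrix
#'
#' Computes `p[i, j]` as the fraction of 1s among the non-missing entries of
#' population `i` at locus `j`, and records per-population sample sizes. All
#' populations must share the same locus list (same order). Loci at which some
#' population has no called individual have an undefined frequency there; such
#' loci are dropped from the whole matrix with a warning.
#'
#' @param pops a (preferably named) list of [individual_matrix()] objects.
#' @return a [frequency_matrix()] with `sizes` set to the population sizes.
#' @examples
#' a <- individual_matrix(rbind(c(0, 1), c(1, 1)))
#' individuals_to_frequencies(list(A = a))
#' @export
individuals_to_frequencies <- function(pops) {
  if (!is.list(pops) || length(pops) == 0L) {
    stop_invalid("`pops` must be a nonempty list of individual matrices")
  }
  pops <- lapply(pops, function(x) {
    if (!inherits(x, "indiv_matrix")) individual_matrix(x) else x
  })
  locus_ids <- colnames(pops[[1L]])
  for (x in pops[-1L]) {
    if (!identical(colnames(x), locus_ids)) {
      stop_invalid("all populations must share an identical locus list")
    }
  }
  if (is.null(names(pops)) || any(names(pops) == "")) {
    names(pops) <- paste0("pop", seq_along(pops))
  }
  p <- t(vapply(pops, function(x) colMeans(x, na.rm = TRUE), numeric(length(locus_ids))))
  # colMeans over an all-NA column yields NaN: the frequency is undefined.
  undefined <- colSums(is.nan(p)) > 0L
  if (any(undefined)) {
    warning(sprintf(
      "dropping %d locus/loci with no called individuals in at least one population",
      sum(undefined)
    ))
    p <- p[, !undefined, drop = FALSE]
    if (ncol(p) == 0L) stop_invalid("no locus has a defined frequency in every population")
  }
  frequency_matrix(p,
    populations = names(pops),
    loci = colnames(p),
    sizes = vapply(pops, nrow, integer(1))
  )
}
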
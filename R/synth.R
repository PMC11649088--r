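#' Randomly permute all entries of a frequency matrix
#'
#' Shuffles the flattened `m x L` matrix of frequencies over both rows and
#' columns, destroying population and locus structure while preserving the
#' multiset of entries exactly — the randomization used to test whether
#' inter-measure correlation patterns depend on structure in the data or
#' only on the marginal frequency distribution.
#'
#' @param M a [frequency_matrix()].
#' @param seed RNG seed (required).
#' @return a [frequency_matrix()] of the same shape and labels.
#' @export
permute_matrix <- function(M, seed) {
  M <- as_freq_matrix(M)
  vals <- unclass_freq(M)
  shuffled <- with_seed(seed, sample(as.vector(vals)))
  frequency_matrix(matrix(shuffled, nrow = nrow(M), ncol = ncol(M)),
                   populations = rownames(M), loci = colnames(M),
                   sizes = pop_sizes(M))
}

#' Uniform-random frequency matrix
#'
#' Every `p[i, j]` drawn i.i.d. from U\[0, 1\]: the structure-free null in
#' which allele frequencies carry no skew toward rare alleles.
#'
#' @param m number of populations.
#' @param L number of loci.
#' @param seed RNG seed (required).
#' @return a [frequency_matrix()].
#' @export
uniform_matrix <- function(m, L, seed) {
  if (m < 1L || L < 1L) stop_invalid("`m` and `L` must be at least 1")
  vals <- with_seed(seed, runif(m * L))
  frequency_matrix(matrix(vals, nrow = m, ncol = L))
}

#' Bernoulli-sampled individual-level populations
#'
#' Draws, for each population `i`, `n_i` individuals whose binary state at
#' locus `j` is Bernoulli(`p[i, j]`) — a finite-sample emulation of
#' genotyping a handful of individuals per population, used to exercise the
#' encode-then-estimate pipeline end to end.
#'
#' @param p an `m x L` matrix (or [frequency_matrix()]) of true frequencies.
#' @param n per-population sample sizes: single value or vector of length `m`.
#' @param seed RNG seed (required).
#' @return named list of [individual_matrix()] objects.
#' @export
bernoulli_populations <- function(p, n, seed) {
  p <- as_freq_matrix(p)
  m <- nrow(p)
  n <- rep_len(as.integer(n), m)
  if (any(n < 1L)) stop_invalid("`n` must be at least 1 per population")
  vals <- unclass_freq(p)
  with_seed(seed, {
    out <- lapply(seq_len(m), function(i) {
      states <- matrix(rbinom(n[i] * ncol(vals), 1L, rep(vals[i, ], each = n[i])),
                       nrow = n[i])
      individual_matrix(states, loci = colnames(vals))
    })
    names(out) <- rownames(p)
    out
  })
}

#' The two-island worked examples
#'
#' Four single-locus, two-population frequency matrices that make the four
#' approaches disagree in instructive ways:
#'
#' * `A1 = (0.1, 0.9)` vs `B1 = (0.5, 0.5)` — pooling cannot tell the
#'   islands apart (both score 0.5), averaging prefers B1, differencing and
#'   fixing prefer A1;
#' * `A2 = (0.2, 0.2)` vs `B2 = (0.1, 0)` — pooling, averaging and fixing
#'   prefer A2 while differencing prefers B2.
#'
#' @return named list of [frequency_matrix()] objects `A1`, `B1`, `A2`, `B2`.
#' @examples
#' isl <- island_fixtures()
#' het_pooling(isl$A1[, 1]) == het_pooling(isl$B1[, 1])
#' @export
island_fixtures <- function() {
  mk <- function(p) frequency_matrix(cbind(locus1 = p),
                                     populations = c("pop1", "pop2"))
  list(
    A1 = mk(c(0.1, 0.9)),
    B1 = mk(c(0.5, 0.5)),
    A2 = mk(c(0.2, 0.2)),
    B2 = mk(c(0.1, 0))
  )
}

#' Zero-skewed ("salmon-like") frequency matrix
#'
#' Draws frequencies i.i.d. from a Beta distribution concentrated near 0,
#' mimicking SNP panels where most minor-allele frequencies are small in
#' every population. Defaults `Beta(0.3, 2.7)` give mean 0.1 with a heavy
#' spike at 0; shape parameters are configurable.
#'
#' @param m number of populations.
#' @param L number of loci.
#' @param seed RNG seed (required).
#' @param shape1,shape2 Beta shape parameters.
#' @return a [frequency_matrix()].
#' @export
salmon_like_matrix <- function(m, L, seed, shape1 = 0.3, shape2 = 2.7) {
  if (m < 1L || L < 1L) stop_invalid("`m` and `L` must be at least 1")
  vals <- with_seed(seed, rbeta(m * L, shape1, shape2))
  frequency_matrix(matrix(vals, nrow = m, ncol = L))
}
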
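# Independent reference implementations used as oracles: direct nested-loop
# evaluations of the per-locus formulas, kept deliberately free of any code
# from R/ so that agreement is a two-route check.

oracle_measure <- function(p, measure) {
  m <- length(p)
  switch(measure,
    het_pooling = {
      pb <- sum(p) / m
      2 * pb * (1 - pb)
    },
    het_averaging = {
      tot <- 0
      for (i in seq_len(m)) tot <- tot + 2 * p[i] * (1 - p[i])
      tot / m
    },
    het_differencing = {
      tot <- 0
      for (i in seq_len(m)) for (j in seq_len(m)) tot <- tot + (p[i] - p[j])^2
      tot / m^2
    },
    het_fixing = {
      tot <- 0
      for (i in seq_len(m)) for (j in seq_len(m)) {
        if (i != j) tot <- tot + 1 - p[i] * p[j] - (1 - p[i]) * (1 - p[j])
      }
      tot / m^2
    },
    ssd_pooling = {
      pb <- sum(p) / m
      if (pb > 0 && pb < 1) 1 else 0
    },
    ssd_averaging = {
      tot <- 0
      for (i in seq_len(m)) if (p[i] > 0 && p[i] < 1) tot <- tot + 1
      tot / m
    },
    ssd_differencing = {
      mx <- 0
      for (i in seq_len(m)) for (j in seq_len(m)) mx <- max(mx, (p[i] - p[j])^2)
      mx
    },
    ssd_fixing = {
      a <- 1
      b <- 1
      for (i in seq_len(m)) {
        a <- a * p[i]
        b <- b * (1 - p[i])
      }
      1 - a - b
    },
    stop("unknown measure in oracle")
  )
}

oracle_total <- function(P, idx, measure) {
  tot <- 0
  for (j in seq_len(ncol(P))) tot <- tot + oracle_measure(P[idx, j], measure)
  tot
}

# Recursive k-subset enumeration (independent of utils::combn).
oracle_subsets <- function(m, k) {
  if (k == 0L) return(list(integer(0)))
  if (m < k) return(list())
  with_last <- lapply(oracle_subsets(m - 1L, k - 1L), function(s) c(s, m))
  without <- oracle_subsets(m - 1L, k)
  c(without, with_last)
}

# All binary vectors of length n, one per row.
all_binary_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# Write a small VCF from a genotype-string matrix (loci x samples).
write_toy_vcf <- function(gt, ref = NULL, alt = NULL, path = tempfile(fileext = ".vcf")) {
  n_loc <- nrow(gt)
  if (is.null(ref)) ref <- rep("A", n_loc)
  if (is.null(alt)) alt <- rep("G", n_loc)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t")
  )
  body <- vapply(seq_len(n_loc), function(i) {
    paste(c("chr1", i * 100, ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

random_freq_vector <- function(m) {
  # Mix of interior, boundary and repeated values so degenerate cases occur.
  p <- runif(m)
  p[runif(m) < 0.15] <- 0
  p[runif(m) < 0.15] <- 1
  p
}
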
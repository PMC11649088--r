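#' Read a sample-to-population map
#'
#' Two-column tab-separated file (no header, or a header line starting with
#' `sample`): sample identifier, population identifier. Samples present in a
#' VCF but absent from the map are dropped with a message.
#'
#' @param path path to a TSV file.
#' @return named character vector: `popmap[sample_id] == population_id`.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("population map not found: %s", path))
  tab <- read.delim(path, header = FALSE, colClasses = "character",
                    comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(tab) < 2L) stop_validation("population map must have two columns: sample, population")
  if (tolower(tab[1L, 1L]) %in% c("sample", "sample_id")) tab <- tab[-1L, , drop = FALSE]
  if (nrow(tab) == 0L) stop_validation("population map is empty")
  map <- tab[[2L]]
  names(map) <- tab[[1L]]
  if (anyDuplicated(names(map))) stop_validation("duplicate sample ids in population map")
  map
}

#' Encode a biallelic SNP VCF as minority-allele presence/absence
#'
#' Reads a VCF (plain or bgzipped), keeps biallelic SNP records, and converts
#' genotypes to a per-population binary encoding: at each locus the *majority*
#' allele is determined from pooled allele counts over **all** mapped
#' individuals, and an individual scores 1 exactly when its genotype carries
#' at least one copy of the minority allele, 0 otherwise. Missing and
#' half-called genotypes (any `.` allele) are `NA`. If the two alleles are
#' equally frequent at a locus the tie is broken toward REF = majority, with
#' a warning. Multiallelic sites and non-SNP records are skipped and counted
#' in a message.
#'
#' @param path path to a VCF 4.x file.
#' @param popmap named character vector from [read_popmap()] (or equivalent).
#' @return a named list of [individual_matrix()] objects, one per population,
#'   sharing the locus list `CHROM:POS`; class `encoded_genotypes`. The
#'   number of skipped records is attached as attribute `skipped`.
#' @export
read_vcf <- function(path, popmap) {
  if (!file.exists(path)) stop_usage(sprintf("VCF not found: %s", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!is_snp)
  if (skipped > 0L) {
    message(sprintf("skipped %d non-biallelic-SNP record(s)", skipped))
  }
  if (!any(is_snp)) stop_validation("no biallelic SNP records in VCF")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  locus_ids <- paste0(fix[is_snp, "CHROM"], ":", fix[is_snp, "POS"])

  samples <- colnames(gt)
  mapped <- samples[samples %in% names(popmap)]
  if (length(mapped) == 0L) stop_usage("no VCF sample is present in the population map")
  if (length(mapped) < length(samples)) {
    message(sprintf("dropping %d unmapped sample(s)", length(samples) - length(mapped)))
  }
  gt <- gt[, mapped, drop = FALSE]

  # ALT-copy counts per genotype; NA for missing or half calls.
  alt_copies <- function(g) {
    al <- strsplit(g, "[/|]")
    vapply(al, function(a) {
      if (length(a) == 0L || any(a == ".") || any(is.na(a))) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  n_alt <- apply(gt, 2L, alt_copies)
  if (is.null(dim(n_alt))) n_alt <- matrix(n_alt, nrow = 1L, dimnames = list(NULL, mapped))
  ploidy <- apply(gt, 2L, function(g) {
    vapply(strsplit(g, "[/|]"), function(a) {
      if (length(a) == 0L || any(a == ".") || any(is.na(a))) NA_real_ else length(a)
    }, numeric(1))
  })
  if (is.null(dim(ploidy))) ploidy <- matrix(ploidy, nrow = 1L, dimnames = list(NULL, mapped))

  tot_alt <- rowSums(n_alt, na.rm = TRUE)
  tot_copies <- rowSums(ploidy, na.rm = TRUE)
  tot_ref <- tot_copies - tot_alt
  if (any(tot_alt == tot_ref & tot_copies > 0)) {
    warning(sprintf(
      "%d locus/loci with tied allele counts; treating REF as the majority allele",
      sum(tot_alt == tot_ref & tot_copies > 0)
    ))
  }
  minority_is_alt <- tot_alt <= tot_ref  # tie -> REF majority

  # 1 iff the individual carries >= 1 copy of the minority allele.
  carries <- matrix(NA_real_, nrow = nrow(n_alt), ncol = ncol(n_alt),
                    dimnames = dimnames(n_alt))
  carries[minority_is_alt, ] <- as.numeric(n_alt[minority_is_alt, , drop = FALSE] >= 1)
  if (any(!minority_is_alt)) {
    ref_copies <- ploidy - n_alt
    carries[!minority_is_alt, ] <- as.numeric(ref_copies[!minority_is_alt, , drop = FALSE] >= 1)
  }

  pops <- split(mapped, popmap[mapped])
  enc <- lapply(pops, function(ss) {
    individual_matrix(t(carries[, ss, drop = FALSE]),
                      individuals = ss, loci = locus_ids)
  })
  structure(enc, class = c("encoded_genotypes", "list"), skipped = skipped)
}

#' @export
print.encoded_genotypes <- function(x, ...) {
  cat(sprintf(
    "<encoded_genotypes> %d population(s), %d loci; sizes: %s\n",
    length(x), ncol(x[[1L]]),
    paste(vapply(x, nrow, integer(1)), collapse = ", ")
  ))
  invisible(x)
}

#' Per-population minor-allele frequencies from encoded genotypes
#'
#' Thin wrapper over [individuals_to_frequencies()]: `p[i, j]` is the
#' fraction of population `i`'s called individuals carrying the minority
#' allele at locus `j`; missing genotypes are excluded from both numerator
#' and denominator.
#'
#' @param g an `encoded_genotypes` object from [read_vcf()].
#' @return a [frequency_matrix()] with per-population sizes.
#' @export
frequencies_from_encoded <- function(g) {
  if (length(g) == 0L) stop_invalid("`g` must contain at least one population")
  individuals_to_frequencies(g)
}

#' Write / read a frequency matrix as CSV
#'
#' The CSV has a `population` column, an optional `size` column, and one
#' column per locus. Values are serialized with 17 significant digits so that
#' `read_matrix(write_matrix(M))` round-trips exactly in double precision.
#' On read, out-of-range entries raise a validation error naming the cell.
#'
#' @param M a [frequency_matrix()].
#' @param path output / input CSV path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   [frequency_matrix()].
#' @export
write_matrix <- function(M, path) {
  M <- as_freq_matrix(M)
  df <- data.frame(population = rownames(M), check.names = FALSE,
                   stringsAsFactors = FALSE)
  sz <- pop_sizes(M)
  if (!is.null(sz)) df$size <- sprintf("%.17g", sz)
  vals <- unclass_freq(M)
  for (j in seq_len(ncol(vals))) {
    df[[colnames(vals)[j]]] <- sprintf("%.17g", vals[, j])
  }
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_usage(sprintf("matrix file not found: %s", path))
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"population" %in% colnames(df) || nrow(df) == 0L) {
    stop_validation("matrix CSV must have a 'population' column and at least one row")
  }
  pops <- df$population
  sizes <- NULL
  if ("size" %in% colnames(df)) {
    sizes <- as.numeric(df$size)
    df$size <- NULL
  }
  df$population <- NULL
  if (ncol(df) == 0L) stop_validation("matrix CSV has no locus columns")
  p <- matrix(NA_real_, nrow = length(pops), ncol = ncol(df),
              dimnames = list(pops, colnames(df)))
  for (j in seq_len(ncol(df))) p[, j] <- as.numeric(df[[j]])
  if (anyNA(p)) {
    bad <- which(is.na(p), arr.ind = TRUE)[1L, ]
    stop_validation(sprintf(
      "non-numeric frequency for population '%s' at locus '%s'",
      pops[bad[1L]], colnames(p)[bad[2L]]
    ))
  }
  if (any(p < 0 | p > 1)) {
    bad <- which(p < 0 | p > 1, arr.ind = TRUE)[1L, ]
    stop_validation(sprintf(
      "frequency out of [0, 1] for population '%s' at locus '%s' (value %g)",
      pops[bad[1L]], colnames(p)[bad[2L]], p[bad[1L], bad[2L]]
    ))
  }
  frequency_matrix(p, populations = pops, loci = colnames(p), sizes = sizes)
}

#' One-call VCF to frequency-matrix pipeline
#'
#' @param vcf_path VCF file.
#' @param popmap_path sample-to-population TSV, see [read_popmap()].
#' @return a [frequency_matrix()].
#' @export
vcf_to_frequencies <- function(vcf_path, popmap_path) {
  frequencies_from_encoded(read_vcf(vcf_path, read_popmap(popmap_path)))
}
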
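#' Construct a genotype dataset
#'
#' The central container for diploid SNP-array genotypes: a samples x variants
#' matrix of A1-allele counts (0, 1, 2 or `NA` for missing) together with a
#' sample table (id + breed label) and a variant map table. Variants are kept
#' sorted by (chromosome, position); construction sorts them if needed.
#'
#' Calls count copies of `allele_a1` as listed in the map, i.e. file semantics
#' are preserved and no minor-allele recode is applied; consumers that need
#' allele frequencies derive them with [allele_frequencies()].
#'
#' @param samples data.frame with columns `sample_id` (unique) and `breed`.
#' @param variants data.frame with columns `id`, `chrom` (integer code;
#'   1-26 autosomes, 27+ or 0 non-autosomal), `pos_bp` (1-based physical
#'   position; 0 encodes a missing position), `a1`, `a2` (characters from
#'   A,C,G,T,0).
#' @param calls integer matrix, `nrow(samples)` x `nrow(variants)`, values in
#'   \{0,1,2,NA\}; `NA` is the missing-call sentinel and is never conflated
#'   with the count 0.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, variants, calls) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(
    all(c("sample_id", "breed") %in% names(samples)),
    all(c("id", "chrom", "pos_bp", "a1", "a2") %in% names(variants))
  )
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(variants)) {
    stop("calls matrix is ", nrow(calls), "x", ncol(calls),
         " but there are ", nrow(samples), " samples and ", nrow(variants), " variants")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("calls must be 0, 1, 2 or NA")
  }
  variants$chrom <- as.integer(variants$chrom)
  variants$pos_bp <- as.double(variants$pos_bp)
  if (any(variants$pos_bp < 0)) stop("pos_bp must be >= 0 (0 = missing position)")
  ord <- order(variants$chrom, variants$pos_bp)
  if (is.unsorted(ord)) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- NULL
  structure(
    list(samples = samples, variants = variants, calls = calls),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset: ", nrow(x$samples), " samples x ", nrow(x$variants),
      " variants\n", sep = "")
  br <- table(x$samples$breed)
  cat("breeds: ", paste(names(br), br, sep = "=", collapse = ", "), "\n", sep = "")
  nm <- sum(is.na(x$calls))
  cat(sprintf("missing calls: %d (%.4f)\n", nm, nm / max(1, length(x$calls))))
  invisible(x)
}

#' Number of samples / variants in a dataset
#' @param dataset a `genotype_dataset`
#' @return integer count
#' @export
n_samples <- function(dataset) nrow(dataset$samples)

#' @rdname n_samples
#' @export
n_variants <- function(dataset) nrow(dataset$variants)

#' Subset a genotype dataset
#'
#' @param dataset a `genotype_dataset`
#' @param samples sample indices, logical mask, or character sample_ids
#'   (NULL = keep all)
#' @param variants variant indices or logical mask (NULL = keep all)
#' @return a `genotype_dataset`
#' @export
subset_dataset <- function(dataset, samples = NULL, variants = NULL) {
  si <- resolve_samples(dataset, samples)
  vi <- if (is.null(variants)) seq_len(n_variants(dataset)) else variants
  genotype_dataset(
    dataset$samples[si, , drop = FALSE],
    dataset$variants[vi, , drop = FALSE],
    dataset$calls[si, vi, drop = FALSE]
  )
}

# Resolve a sample selector (indices, logical, ids, breed label via breed=) to
# integer indices.
resolve_samples <- function(dataset, samples) {
  if (is.null(samples)) return(seq_len(n_samples(dataset)))
  if (is.logical(samples)) return(which(samples))
  if (is.character(samples)) {
    idx <- match(samples, dataset$samples$sample_id)
    if (anyNA(idx)) stop("unknown sample_id: ", paste(samples[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(samples)
}

#' Indices of samples belonging to a breed
#' @param dataset a `genotype_dataset`
#' @param breed breed label
#' @return integer vector of sample indices
#' @export
breed_samples <- function(dataset, breed) {
  idx <- which(dataset$samples$breed == breed)
  if (!length(idx)) stop("no samples with breed label '", breed, "'")
  idx
}

#' Construct a phased haplotype set
#'
#' Two haplotype rows per sample (suffixes `_1`, `_2`), aligned to the variant
#' map of a genotype dataset. Alleles are binary: 1 = copy of `allele_a1`,
#' 0 = copy of `allele_a2`, so the two rows of a sample sum to its genotype
#' call at every site.
#'
#' @param haplotypes integer 0/1 matrix, `2 * n_samples` rows; rows `2i-1` and
#'   `2i` belong to sample `i`.
#' @param samples sample table as in [genotype_dataset()].
#' @param variants variant table as in [genotype_dataset()].
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haplotypes, samples, variants) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != 2L * nrow(samples)) {
    stop("haplotype matrix must have 2 rows per sample")
  }
  if (ncol(haplotypes) != nrow(variants)) stop("haplotype/variant dimension mismatch")
  if (!all(haplotypes %in% c(0L, 1L))) stop("haplotype alleles must be 0/1")
  structure(
    list(
      haplotypes = haplotypes,
      samples = as.data.frame(samples, stringsAsFactors = FALSE),
      variants = as.data.frame(variants, stringsAsFactors = FALSE)
    ),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set: ", nrow(x$haplotypes), " haplotypes (",
      nrow(x$samples), " samples) x ", nrow(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Genotype projection of a haplotype set
#' @param haps a `haplotype_set`
#' @return a `genotype_dataset` with calls = per-sample haplotype sums
#' @export
haps_to_genotypes <- function(haps) {
  n <- nrow(haps$samples)
  calls <- haps$haplotypes[2L * seq_len(n) - 1L, , drop = FALSE] +
    haps$haplotypes[2L * seq_len(n), , drop = FALSE]
  genotype_dataset(haps$samples, haps$variants, calls)
}

#' Haplotype rows belonging to a set of samples
#' @param haps a `haplotype_set`
#' @param sample_idx integer sample indices
#' @return integer row indices into `haps$haplotypes`
#' @export
hap_rows <- function(haps, sample_idx) {
  as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
}
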
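#' Write phased haplotypes as tab-separated text
#'
#' One row per haplotype: `sample_id`, `phase` (1 or 2), then one 0/1 allele
#' column per variant (1 = copy of `allele_a1`). A companion `.map`-style
#' header line carries the variant ids.
#'
#' @param haps a `haplotype_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_haplotypes <- function(haps, path) {
  n <- nrow(haps$samples)
  df <- data.frame(
    sample_id = rep(haps$samples$sample_id, each = 2L),
    phase = rep(1:2, n),
    haps$haplotypes,
    check.names = FALSE
  )
  names(df)[-(1:2)] <- haps$variants$id
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read phased haplotypes written by [write_haplotypes()]
#'
#' @param path haplotype TSV
#' @param dataset the `genotype_dataset` carrying the matching sample and
#'   variant tables (variant ids must agree with the file header)
#' @return a `haplotype_set`
#' @export
read_haplotypes <- function(path, dataset) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ids <- names(df)[-(1:2)]
  if (!identical(ids, dataset$variants$id)) {
    stop("haplotype file variants do not match the dataset map")
  }
  ord <- match(dataset$samples$sample_id, df$sample_id[df$phase == 1L])
  if (anyNA(ord)) stop("haplotype file is missing samples present in the dataset")
  # rows come in sample blocks of two phases; realign to the dataset order
  idx <- as.vector(rbind(2L * ord - 1L, 2L * ord))
  h <- as.matrix(df[idx, -(1:2), drop = FALSE])
  dimnames(h) <- NULL
  haplotype_set(h, dataset$samples, dataset$variants)
}
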
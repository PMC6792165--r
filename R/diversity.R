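#' Per-variant allele frequencies
#'
#' Frequency of `allele_a1` in a sample subset, with missing calls excluded
#' from both numerator and denominator. A SNP at which every subset call is
#' missing gets frequency `NA` (undefined, flagged), never 0.
#'
#' @param dataset a `genotype_dataset`
#' @param sample_subset sample selector (indices, logical, ids; NULL = all)
#' @return data.frame with columns `id`, `freq_a1` (allele-1 frequency or NA),
#'   `n_alleles` (observed allele count = 2 x non-missing samples)
#' @export
allele_frequencies <- function(dataset, sample_subset = NULL) {
  idx <- resolve_samples(dataset, sample_subset)
  if (!length(idx)) stop("sample subset is empty")
  g <- dataset$calls[idx, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  cnt <- colSums(g, na.rm = TRUE)
  freq <- ifelse(n_obs > 0L, cnt / (2 * n_obs), NA_real_)
  data.frame(id = dataset$variants$id, freq_a1 = freq, n_alleles = 2L * n_obs,
             stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) variance components for two populations at each SNP.
# Inputs are the two genotype submatrices (A1 counts with NA missing).
# Returns per-SNP a (among-population), b (among-individual-within) and
# c (within-individual) components; SNPs where any population has < 2 usable
# samples, or that are monomorphic across the pair, come back NA.
wc_components_pair <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- ifelse(n1 > 0, colSums(g1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(g2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(g1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(g2 == 1L, na.rm = TRUE) / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / r
  usable <- n1 >= 2 & n2 >= 2 & nbar > 1
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  mono <- !usable | pbar <= 0 | pbar >= 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[mono] <- b[mono] <- cc[mono] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Pairwise weighted Weir-Cockerham F_ST matrix
#'
#' For every breed pair, per-SNP Weir-Cockerham (1984) variance components
#' (a = among-population, b = among-individual-within-population, c =
#' within-individual) are computed and combined into the weighted multi-locus
#' estimate as a ratio of sums, sum(a) / sum(a + b + c). The ratio-of-sums
#' ("weighted") form accounts for unequal breed sample sizes. SNPs that are
#' monomorphic across a pair, or at which either breed has fewer than two
#' genotyped samples, are excluded from that pair and counted.
#'
#' Negative estimates (expected for undifferentiated pairs) are reported as
#' computed, not clamped to zero.
#'
#' @param dataset a `genotype_dataset`
#' @param labels breed label per sample (default: the dataset's breed column)
#' @return an `fst_matrix`: list with `breeds`, symmetric `values` matrix
#'   (NA diagonal), and `n_snps_used` matrix
#' @export
pairwise_fst <- function(dataset, labels = NULL) {
  if (is.null(labels)) labels <- dataset$samples$breed
  breeds <- unique(labels)
  if (length(breeds) < 2L) stop("need >= 2 breeds")
  for (b in breeds) {
    g <- dataset$calls[labels == b, , drop = FALSE]
    if (!any(colSums(!is.na(g)) >= 2L)) {
      stop("breed '", b, "' has < 2 usable samples at every SNP")
    }
  }
  k <- length(breeds)
  vals <- matrix(NA_real_, k, k, dimnames = list(breeds, breeds))
  nus <- matrix(NA_integer_, k, k, dimnames = list(breeds, breeds))
  for (i in seq_len(k - 1L)) {
    gi <- dataset$calls[labels == breeds[i], , drop = FALSE]
    for (j in (i + 1L):k) {
      gj <- dataset$calls[labels == breeds[j], , drop = FALSE]
      comp <- wc_components_pair(gi, gj)
      ok <- !is.na(comp$a)
      denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
      est <- if (denom > 0) sum(comp$a[ok]) / denom else NA_real_
      vals[i, j] <- vals[j, i] <- est
      nus[i, j] <- nus[j, i] <- sum(ok)
    }
  }
  structure(list(breeds = breeds, values = vals, n_snps_used = nus),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise weighted F_ST (", length(x$breeds), " breeds)\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Write an F_ST matrix as lower-triangle TSV
#' @param fst an `fst_matrix`
#' @param path output file
#' @export
write_fst_matrix <- function(fst, path) {
  v <- fst$values
  v[upper.tri(v, diag = TRUE)] <- NA
  df <- data.frame(breed = fst$breeds, as.data.frame(v), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "")
  invisible(path)
}

#' Principal component analysis of genotypes
#'
#' Eigen-analysis of the sample covariance of normalised genotype calls.
#' Each SNP column is mean-centred and divided by sqrt(p(1-p)) with p the
#' sample allele frequency (Patterson scaling, the normalisation that makes
#' drift contribute equally per locus). Missing calls are imputed to the
#' column mean before scaling (or the SNP dropped, by policy). SNPs
#' monomorphic in the sample set are dropped. No outlier-removal iterations
#' are performed; samples that do not group with their own breed are instead
#' reported by [flag_pc_outliers()].
#'
#' @param dataset a `genotype_dataset`
#' @param k number of components to return (`k < min(n samples, usable SNPs)`)
#' @param missing `"mean_impute"` (default) or `"drop_snp"` (drop any SNP with
#'   a missing call)
#' @return a `pca_result`: `scores` (samples x k, rownames = sample ids),
#'   `variance_explained` (length k, non-increasing, fractions of total),
#'   `n_snps_used`
#' @export
pca_genotypes <- function(dataset, k = 10L, missing = c("mean_impute", "drop_snp")) {
  missing <- match.arg(missing)
  g <- dataset$calls
  storage.mode(g) <- "double"
  if (missing == "drop_snp") g <- g[, colSums(is.na(g)) == 0L, drop = FALSE]
  mu <- colMeans(g, na.rm = TRUE)
  p <- mu / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  mu <- mu[poly]; p <- p[poly]
  if (ncol(g) < 2L) stop("fewer than 2 polymorphic SNPs")
  if (k >= min(nrow(g), ncol(g))) stop("k must be < min(samples, usable SNPs)")
  x <- sweep(g, 2L, mu)
  x[is.na(x)] <- 0                       # mean imputation after centring
  x <- sweep(x, 2L, sqrt(p * (1 - p)), "/")
  sv <- svd(x, nu = k, nv = 0L)
  scores <- sv$u * rep(sv$d[seq_len(k)], each = nrow(x))
  rownames(scores) <- dataset$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(
    scores = scores,
    variance_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
    n_snps_used = ncol(g)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA on ", nrow(x$scores), " samples, ", x$n_snps_used, " SNPs\n",
      "variance explained: ",
      paste(sprintf("%.3f", x$variance_explained), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Flag samples closer to another breed's PC centroid than their own
#'
#' A screening report for mislabelled or crossbred individuals: in PC space,
#' a sample is flagged when its Euclidean distance to its own breed centroid
#' exceeds its distance to some other breed's centroid. Removal is left to
#' the user.
#'
#' @param pca a `pca_result`
#' @param labels breed label per sample (in score row order)
#' @param k number of leading components to use (default: all in `pca`)
#' @return data.frame of flagged samples with own/nearest breed and distances
#' @export
flag_pc_outliers <- function(pca, labels, k = ncol(pca$scores)) {
  sc <- pca$scores[, seq_len(k), drop = FALSE]
  cent <- apply(sc, 2L, function(col) tapply(col, labels, mean))
  cent <- matrix(cent, nrow = length(unique(labels)),
                 dimnames = list(sort(unique(labels)), colnames(sc)))
  d <- outer(seq_len(nrow(sc)), seq_len(nrow(cent)),
             Vectorize(function(i, j) sqrt(sum((sc[i, ] - cent[j, ])^2))))
  colnames(d) <- rownames(cent)
  own <- d[cbind(seq_len(nrow(sc)), match(labels, rownames(cent)))]
  nearest <- rownames(cent)[apply(d, 1L, which.min)]
  flagged <- nearest != labels
  data.frame(
    sample_id = rownames(sc)[flagged],
    breed = labels[flagged],
    nearest_breed = nearest[flagged],
    dist_own = own[flagged],
    dist_nearest = apply(d, 1L, min)[flagged],
    stringsAsFactors = FALSE
  )
}
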
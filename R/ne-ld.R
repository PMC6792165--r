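#' Pairwise genotype-correlation LD within a breed
#'
#' For every intra-chromosomal SNP pair within the distance window and with
#' both minor-allele frequencies at or above `maf_min`, computes r-squared as
#' the squared Pearson correlation of the two genotype-count vectors over
#' samples non-missing at both SNPs — the composite (unphased) LD estimator,
#' which needs no haplotype phase. Pairs in which either SNP has zero
#' variance among usable samples are skipped and counted.
#'
#' @param dataset a `genotype_dataset`
#' @param breed breed label to subset to (NULL = all samples)
#' @param min_dist_bp,max_dist_bp inclusive physical distance window
#' @param maf_min minor-allele-frequency floor
#' @param min_samples error if the breed has fewer genotyped samples
#' @return an `ld_pair_stats` list: `pairs` data.frame (chrom, dist_bp, r2),
#'   `n_samples` (breed sample count), `n_skipped_zero_var`
#' @export
pairwise_r2 <- function(dataset, breed = NULL, min_dist_bp = 5e4,
                        max_dist_bp = 4e6, maf_min = 0.05, min_samples = 10L) {
  idx <- if (is.null(breed)) seq_len(n_samples(dataset)) else breed_samples(dataset, breed)
  if (length(idx) < min_samples) {
    stop("breed has ", length(idx), " samples; floor is ", min_samples)
  }
  g <- dataset$calls[idx, , drop = FALSE]
  storage.mode(g) <- "double"
  fr <- allele_frequencies(dataset, idx)
  maf <- pmin(fr$freq_a1, 1 - fr$freq_a1)
  use <- !is.na(maf) & maf >= maf_min
  v <- dataset$variants
  out <- list()
  n_skip <- 0L
  for (chr in unique(v$chrom)) {
    vi <- which(use & v$chrom == chr)
    if (length(vi) < 2L) next
    pos <- v$pos_bp[vi]
    cm <- suppressWarnings(stats::cor(g[, vi, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    d <- abs(outer(pos, pos, "-"))
    sel <- upper.tri(d) & d >= min_dist_bp & d <= max_dist_bp
    r2 <- cm[sel]^2
    n_skip <- n_skip + sum(is.na(r2))
    ok <- !is.na(r2)
    out[[length(out) + 1L]] <- data.frame(
      chrom = chr, dist_bp = d[sel][ok], r2 = r2[ok]
    )
  }
  pairs <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = integer(0), dist_bp = numeric(0), r2 = numeric(0))
  }
  structure(list(pairs = pairs, n_samples = length(idx),
                 n_skipped_zero_var = n_skip),
            class = "ld_pair_stats")
}

#' @export
print.ld_pair_stats <- function(x, ...) {
  cat("LD pairs: ", nrow(x$pairs), " (", x$n_samples, " samples, ",
      x$n_skipped_zero_var, " zero-variance pairs skipped)\n", sep = "")
  invisible(x)
}

# distance (bp) -> Morgans at the configured map rate, then Morgans ->
# recombination fraction under the chosen mapping function.
recomb_fraction <- function(dist_bp, mapping, cm_per_mb = 1) {
  d <- dist_bp * cm_per_mb * 1e-8            # Morgans
  switch(mapping,
         linear = d,
         haldane = 0.5 * (1 - exp(-2 * d)),
         sved_feldman = d / (2 * d + 1),
         stop("unknown mapping: ", mapping))
}

#' Historical effective population size from binned LD decay
#'
#' Bins SNP pairs by physical distance, converts bin distances to
#' recombination fractions `c` via the chosen map function (default linear at
#' 1 cM/Mb, `c = Morgans`), adjusts each r-squared for finite sample size
#' (`r2_adj = r2 - 1/(beta * n)`, beta = 1 for unphased genotype data, 2 for
#' phased haplotype data), and inverts the drift-LD expectation
#' `E[r2_adj] = 1 / (alpha + 4*N_e*c)` per bin:
#'
#'   `N_e(t) = (1 / mean(r2_adj) - alpha) / (4 * f(c_bar))`, `t = 1 / (2 * f(c_bar))`
#'
#' so each distance bin dates N_e roughly `1/(2c)` generations ago. `alpha`
#' = 2.2 (mutation-adjusted), 2, or 1 (the classic Sved form).
#'
#' Bins with fewer than `min_pairs` pairs are dropped; bins whose mean
#' adjusted r-squared is at or below `1/alpha`'s bound (non-positive N_e) are
#' flagged invalid rather than silently removed.
#'
#' @param ld an `ld_pair_stats` from [pairwise_r2()] (or a compatible
#'   data.frame in `$pairs`)
#' @param n_samples number of diploid samples behind the r2 values (defaults
#'   to the value recorded in `ld`)
#' @param bins number of equal-width distance bins, or a vector of bin edges
#'   (bp); the default 30 bins over the pair range spans roughly t = 12-1000
#'   generations under the default distance window
#' @param mapping `"linear"`, `"haldane"` or `"sved_feldman"`
#' @param alpha drift-equation constant (2.2 default)
#' @param beta sample-size-adjustment factor (1 = unphased)
#' @param cm_per_mb genetic map rate
#' @param min_pairs minimum pairs per emitted bin
#' @return a `ne_trajectory` data.frame: `t_generations`, `ne_estimate`,
#'   `mean_c`, `mean_r2_adj`, `n_pairs`, `valid`
#' @export
ne_trajectory <- function(ld, n_samples = NULL, bins = 30L,
                          mapping = c("linear", "haldane", "sved_feldman"),
                          alpha = 2.2, beta = 1, cm_per_mb = 1, min_pairs = 50L) {
  mapping <- match.arg(mapping)
  stopifnot(alpha %in% c(1, 2, 2.2) || alpha > 0)
  pairs <- if (inherits(ld, "ld_pair_stats")) ld$pairs else ld
  if (is.null(n_samples)) {
    if (!inherits(ld, "ld_pair_stats")) stop("n_samples required")
    n_samples <- ld$n_samples
  }
  if (!nrow(pairs)) stop("no LD pairs supplied")
  edges <- if (length(bins) == 1L) {
    seq(min(pairs$dist_bp), max(pairs$dist_bp), length.out = bins + 1L)
  } else sort(bins)
  bin_id <- findInterval(pairs$dist_bp, edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
  r2_adj <- pairs$r2 - 1 / (beta * n_samples)
  rows <- lapply(sort(unique(bin_id)), function(b) {
    sel <- bin_id == b
    if (sum(sel) < min_pairs) return(NULL)
    cbar <- mean(recomb_fraction(pairs$dist_bp[sel], mapping, cm_per_mb))
    mr2 <- mean(r2_adj[sel])
    ne <- if (mr2 > 0) (1 / mr2 - alpha) / (4 * cbar) else NA_real_
    data.frame(
      t_generations = 1 / (2 * cbar),
      ne_estimate = ne,
      mean_c = cbar,
      mean_r2_adj = mr2,
      n_pairs = sum(sel),
      valid = !is.na(ne) && ne > 0
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no bin reached min_pairs = ", min_pairs)
  out <- do.call(rbind, rows)
  out <- out[order(out$t_generations), ]
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}
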
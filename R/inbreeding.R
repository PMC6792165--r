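#' Heterozygosity-based genomic inbreeding coefficient
#'
#' Method-of-moments inbreeding coefficient per individual, comparing the
#' observed count of homozygous genotypes with the count expected under
#' Hardy-Weinberg at the sample allele frequencies (the classic
#' observed-vs-expected-homozygosity F). Per SNP the expected-homozygosity
#' contribution is `1 - 2*p*(1-p) * T/(T-1)` with `p` the allele frequency in
#' the full input sample set and `T` the observed allele count at that SNP
#' (the small-sample correction). Per individual, both sums run over that
#' individual's non-missing SNPs, and
#' `f_hat = (observed_hom - expected_hom) / (n_usable - expected_hom)`.
#'
#' Frequencies are estimated once from all samples pooled (all breeds
#' together), mirroring a single pooled run over a multi-breed panel; set
#' `by_breed = TRUE` to estimate frequencies within each breed instead
#' (values change accordingly).
#'
#' @param dataset a `genotype_dataset` (>= 2 samples)
#' @param by_breed estimate reference frequencies within breed rather than
#'   pooled
#' @return data.frame: `sample_id`, `observed_hom`, `expected_hom`,
#'   `n_usable_snps`, `f_hat` (NA if the individual has no usable SNPs or a
#'   zero denominator)
#' @export
het_inbreeding <- function(dataset, by_breed = FALSE) {
  if (n_samples(dataset) < 2L) stop("need >= 2 samples")
  g <- dataset$calls
  grp <- if (by_breed) dataset$samples$breed else rep("all", nrow(g))
  obs_hom <- exp_hom <- n_use <- numeric(nrow(g))
  for (lab in unique(grp)) {
    rows <- which(grp == lab)
    gs <- g[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(gs))
    T_all <- 2 * n_obs
    p <- ifelse(n_obs > 0, colSums(gs, na.rm = TRUE) / T_all, NA_real_)
    e_snp <- 1 - 2 * p * (1 - p) * T_all / (T_all - 1)
    usable <- !is.na(e_snp) & T_all > 1
    nonmiss <- !is.na(gs[, usable, drop = FALSE])
    obs_hom[rows] <- rowSums((gs[, usable, drop = FALSE] != 1L) & nonmiss, na.rm = TRUE)
    exp_hom[rows] <- as.vector(nonmiss %*% e_snp[usable])
    n_use[rows] <- rowSums(nonmiss)
  }
  denom <- n_use - exp_hom
  f_hat <- ifelse(n_use > 0 & abs(denom) > .Machine$double.eps^0.5,
                  (obs_hom - exp_hom) / denom, NA_real_)
  data.frame(
    sample_id = dataset$samples$sample_id,
    observed_hom = obs_hom, expected_hom = exp_hom,
    n_usable_snps = as.integer(n_use), f_hat = f_hat,
    stringsAsFactors = FALSE
  )
}

#' ROH scan parameters
#'
#' Defaults follow the long-standing PLINK sliding-window ROH scan defaults
#' (window of 50 SNPs allowing 1 heterozygote and 5 missing calls, 5% window
#' hit-rate threshold, segments of >= 100 SNPs and >= 1000 kb, density at
#' most 50 kb/SNP, splits at gaps > 1000 kb). All are exposed and echoed
#' into output headers.
#'
#' @param window_snp SNPs per sliding window
#' @param window_het max heterozygous calls in a "homozygous" window
#' @param window_missing max missing calls in a "homozygous" window
#' @param window_threshold min fraction of homozygous windows covering a SNP
#'   for it to be ROH-eligible
#' @param min_snp minimum SNPs per reported segment
#' @param min_kb minimum segment length (kb)
#' @param max_density maximum segment kb per SNP
#' @param max_gap_kb maximum allowed gap between consecutive SNPs in a
#'   segment (kb)
#' @return a `roh_params` list
#' @export
roh_params <- function(window_snp = 50L, window_het = 1L, window_missing = 5L,
                       window_threshold = 0.05, min_snp = 100L, min_kb = 1000,
                       max_density = 50, max_gap_kb = 1000) {
  structure(list(window_snp = as.integer(window_snp),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 window_threshold = window_threshold,
                 min_snp = as.integer(min_snp), min_kb = min_kb,
                 max_density = max_density, max_gap_kb = max_gap_kb),
            class = "roh_params")
}

# ROH-eligible SNP mask for one sample on one chromosome: sliding windows of
# `window_snp` SNPs, a window is homozygous if it has <= window_het hets and
# <= window_missing missing; a SNP is eligible if the fraction of homozygous
# windows among windows containing it is >= threshold.
roh_eligible_snps <- function(het, mis, params) {
  m <- length(het)
  w <- params$window_snp
  if (m < w) return(NULL)                 # caller warns and skips
  n_win <- m - w + 1L
  cs_het <- c(0L, cumsum(het)); cs_mis <- c(0L, cumsum(mis))
  win_het <- cs_het[(w + 1L):(m + 1L)] - cs_het[1:n_win]
  win_mis <- cs_mis[(w + 1L):(m + 1L)] - cs_mis[1:n_win]
  hom_win <- as.integer(win_het <= params$window_het & win_mis <= params$window_missing)
  # windows containing SNP i are those starting in [i-w+1, i] clipped to range
  lo <- pmax(1L, seq_len(m) - w + 1L)
  hi <- pmin(n_win, seq_len(m))
  cs_hom <- c(0L, cumsum(hom_win))
  hits <- cs_hom[hi + 1L] - cs_hom[lo]
  total <- hi - lo + 1L
  hits / total >= params$window_threshold
}

# Split a run of eligible SNP indices at large gaps, then apply segment-level
# filters; returns a data.frame of segments (possibly empty).
runs_to_segments <- function(idx, pos, params) {
  if (!length(idx)) return(NULL)
  gap_break <- c(FALSE, diff(pos[idx]) > params$max_gap_kb * 1000)
  piece <- cumsum(gap_break)
  out <- lapply(split(idx, piece), function(ii) {
    len_kb <- (pos[ii[length(ii)]] - pos[ii[1]]) / 1000
    n <- length(ii)
    if (n >= params$min_snp && len_kb >= params$min_kb &&
        len_kb / n <= params$max_density) {
      data.frame(start_bp = pos[ii[1]], end_bp = pos[ii[length(ii)]], n_snps = n)
    } else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Detect runs of homozygosity
#'
#' PLINK-style sliding-window scan, per sample and chromosome: windows of
#' consecutive SNPs are classified homozygous if they contain at most
#' `window_het` heterozygous and `window_missing` missing calls; each SNP's
#' hit rate is the fraction of homozygous windows among windows containing
#' it, and SNPs at or above `window_threshold` are ROH-eligible. Maximal runs
#' of eligible SNPs are split at gaps over `max_gap_kb` and reported as
#' segments if they satisfy the SNP-count, length and density filters.
#'
#' Chromosomes with fewer SNPs than the window are skipped with a warning.
#'
#' @param dataset a `genotype_dataset` (variants position-sorted, as
#'   guaranteed by the constructor)
#' @param params a [roh_params()]
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive SNP positions), `n_snps`
#' @export
detect_roh <- function(dataset, params = roh_params()) {
  v <- dataset$variants
  out <- list()
  skipped <- character(0)
  for (chr in unique(v$chrom)) {
    vi <- which(v$chrom == chr)
    if (length(vi) < params$window_snp) {
      skipped <- c(skipped, as.character(chr))
      next
    }
    pos <- v$pos_bp[vi]
    for (si in seq_len(n_samples(dataset))) {
      gg <- dataset$calls[si, vi]
      elig <- roh_eligible_snps(as.integer(!is.na(gg) & gg == 1L),
                                as.integer(is.na(gg)), params)
      segs <- lapply(consecutive_runs(which(elig)), runs_to_segments,
                     pos = pos, params = params)
      segs <- segs[!vapply(segs, is.null, logical(1))]
      seg <- if (length(segs)) do.call(rbind, segs) else NULL
      if (!is.null(seg)) {
        seg$sample_id <- dataset$samples$sample_id[si]
        seg$chrom <- chr
        out[[length(out) + 1L]] <- seg
      }
    }
  }
  if (length(skipped)) {
    warning("chromosome(s) with fewer SNPs than the scan window skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(0), chrom = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sample_id", "chrom", "start_bp", "end_bp", "n_snps")]
}

# maximal consecutive-index runs as a list
consecutive_runs <- function(idx) {
  if (!length(idx)) return(list())
  split(idx, cumsum(c(1L, diff(idx) != 1L)))
}

#' Genomic inbreeding from ROH (F_ROH)
#'
#' `f_roh` = total ROH span divided by the SNP-covered autosomal length.
#' Segment spans and the denominator use the same bp-span convention
#' (`end - start`), so a single segment covering a whole chromosome's SNP
#' extent contributes exactly that chromosome's span and `f_roh` is always in
#' \[0, 1\]. The default denominator is the sum over chromosomes of
#' (last SNP bp - first SNP bp); a fixed assembly length can be supplied
#' instead.
#'
#' @param segments segment table from [detect_roh()]
#' @param dataset the `genotype_dataset` the segments came from
#' @param denominator_bp optional fixed genome length (bp); default computed
#'   from the dataset's SNP coverage
#' @return data.frame: `sample_id`, `sum_roh_bp`, `denominator_bp`, `f_roh`
#' @export
froh <- function(segments, dataset, denominator_bp = NULL) {
  if (is.null(denominator_bp)) {
    spans <- tapply(dataset$variants$pos_bp, dataset$variants$chrom,
                    function(p) max(p) - min(p))
    denominator_bp <- sum(spans)
  }
  tot <- rep(0, n_samples(dataset))
  names(tot) <- dataset$samples$sample_id
  if (nrow(segments)) {
    s <- tapply(segments$end_bp - segments$start_bp, segments$sample_id, sum)
    tot[names(s)] <- s
  }
  data.frame(
    sample_id = dataset$samples$sample_id,
    sum_roh_bp = unname(tot),
    denominator_bp = denominator_bp,
    f_roh = unname(tot) / denominator_bp,
    stringsAsFactors = FALSE
  )
}

#' Mean total ROH length per length class and breed
#'
#' Each segment is assigned to the length bin containing it (segments beyond
#' the last edge go to the open-ended top bin); per breed and bin the
#' statistic is the mean over that breed's samples (zero-ROH samples
#' included) of the summed segment lengths.
#'
#' @param segments segment table from [detect_roh()]
#' @param dataset the source `genotype_dataset` (supplies breed labels and
#'   the full sample list)
#' @param bin_edges_mb ascending interior bin edges in Mb; default bins
#'   \[1,5), \[5,10), \[10,20), \[20,40), >=40
#' @return data.frame: `breed`, `bin`, `mean_total_mb`
#' @export
roh_length_summary <- function(segments, dataset, bin_edges_mb = c(1, 5, 10, 20, 40)) {
  stopifnot(!is.unsorted(bin_edges_mb, strictly = TRUE))
  edges <- c(bin_edges_mb, Inf)
  labs <- c(paste0("[", head(edges, -2), ",", edges[2:(length(edges) - 1)], ")"),
            paste0(">=", bin_edges_mb[length(bin_edges_mb)]))
  samp <- dataset$samples
  grid <- expand.grid(breed = unique(samp$breed), bin = labs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mean_total_mb <- 0
  if (nrow(segments)) {
    len_mb <- (segments$end_bp - segments$start_bp) / 1e6
    bin <- labs[findInterval(len_mb, edges[-length(edges)])]
    keep <- !is.na(bin)      # segments below the first edge are not binned
    if (any(keep)) {
      per <- aggregate(
        len ~ sample_id + bin,
        data.frame(sample_id = segments$sample_id[keep], bin = bin[keep],
                   len = len_mb[keep], stringsAsFactors = FALSE),
        FUN = sum
      )
      per$breed <- samp$breed[match(per$sample_id, samp$sample_id)]
      nb <- table(samp$breed)
      agg <- aggregate(len ~ breed + bin, per, FUN = sum)
      agg$mean_total_mb <- agg$len / as.integer(nb[agg$breed])
      i <- match(paste(agg$breed, agg$bin), paste(grid$breed, grid$bin))
      grid$mean_total_mb[i] <- agg$mean_total_mb
    }
  }
  grid[order(match(grid$breed, unique(samp$breed)), match(grid$bin, labs)), ]
}

#' Distributional comparison of a per-sample statistic across groups
#'
#' Runs the nonparametric battery used for breed comparisons of inbreeding
#' and N_e values: a per-group normality test (Shapiro-Wilk by default, or
#' one-sample Kolmogorov-Smirnov against the fitted normal), the
#' Kruskal-Wallis omnibus test (tie-corrected) across groups, and two-sided
#' pairwise Wilcoxon rank-sum tests over all group pairs with Bonferroni
#' adjustment.
#'
#' @param values numeric per-sample statistic
#' @param labels group label per value (>= 2 groups of >= 3 values)
#' @param normality `"shapiro"` or `"ks"`
#' @return a `group_comparison` list: `normality` (per-group p),
#'   `kruskal` (statistic H, df, p.value), `pairwise` (group1, group2, p_raw,
#'   p_bonferroni)
#' @export
compare_groups <- function(values, labels, normality = c("shapiro", "ks")) {
  normality <- match.arg(normality)
  keep <- !is.na(values)
  values <- values[keep]; labels <- as.character(labels[keep])
  groups <- unique(labels)
  if (length(groups) < 2L || any(table(labels) < 3L)) {
    stop("need >= 2 groups with >= 3 values each")
  }
  if (all(vapply(groups, function(g) {
    x <- values[labels == g]; diff(range(x)) == 0
  }, logical(1)))) {
    stop("all groups constant: omnibus statistic undefined")
  }
  norm_p <- vapply(groups, function(g) {
    x <- values[labels == g]
    if (diff(range(x)) == 0) return(NA_real_)
    if (normality == "shapiro") stats::shapiro.test(x)$p.value
    else suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }, numeric(1))
  kw <- stats::kruskal.test(values, factor(labels))
  pairs <- utils::combn(groups, 2L)
  n_comp <- ncol(pairs)
  p_raw <- vapply(seq_len(n_comp), function(i) {
    suppressWarnings(stats::wilcox.test(values[labels == pairs[1, i]],
                                        values[labels == pairs[2, i]],
                                        exact = FALSE)$p.value)
  }, numeric(1))
  structure(list(
    normality = data.frame(group = groups, p_value = unname(norm_p),
                           stringsAsFactors = FALSE),
    kruskal = list(statistic = unname(kw$statistic), df = unname(kw$parameter),
                   p.value = kw$p.value),
    pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          p_raw = p_raw,
                          p_bonferroni = pmin(1, p_raw * n_comp),
                          stringsAsFactors = FALSE)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.2f, df = %d, p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p.value))
  sig <- sum(x$pairwise$p_bonferroni < 0.05)
  cat(sig, "of", nrow(x$pairwise), "pairwise comparisons significant",
      "(Bonferroni-adjusted p < 0.05)\n")
  invisible(x)
}

#' Export ROH segments as BED
#'
#' Converts the 1-based inclusive segment intervals to BED's 0-based
#' half-open convention (`start-1`, `end`).
#' @param segments segment table from [detect_roh()]
#' @param path output file
#' @export
write_roh_bed <- function(segments, path) {
  data.table::fwrite(
    data.frame(chrom = segments$chrom,
               start = format(segments$start_bp - 1, scientific = FALSE, trim = TRUE),
               end = format(segments$end_bp, scientific = FALSE, trim = TRUE),
               name = segments$sample_id),
    path, sep = "\t", col.names = FALSE
  )
  invisible(path)
}
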
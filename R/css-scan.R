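#' Target-vs-reference contrast design
#'
#' Holds the two disjoint sample groups contrasted by the selection scan:
#' the target breed and a pooled reference drawn from the other breeds
#' (by convention a fixed number of randomly chosen animals per non-target
#' breed, seeded so the stochastic contrast is reproducible).
#'
#' @param dataset a `genotype_dataset`
#' @param target_breed breed label of the scanned population
#' @param n_per_ref_breed animals sampled per non-target breed
#' @param seed mandatory RNG seed for the reference draw
#' @return a `contrast_design`: `target_samples`, `reference_samples`
#'   (integer sample indices), `seed`
#' @export
make_contrast <- function(dataset, target_breed, n_per_ref_breed = 5L, seed) {
  if (missing(seed)) stop("seed is mandatory for the reference draw")
  set.seed(seed)
  target <- breed_samples(dataset, target_breed)
  others <- setdiff(unique(dataset$samples$breed), target_breed)
  if (!length(others)) stop("no non-target breeds to draw a reference from")
  ref <- unlist(lapply(others, function(b) {
    idx <- which(dataset$samples$breed == b)
    if (length(idx) <= n_per_ref_breed) idx else sort(sample(idx, n_per_ref_breed))
  }))
  contrast_design(target, ref, seed)
}

#' @rdname make_contrast
#' @param target_samples,reference_samples explicit disjoint index vectors
#' @export
contrast_design <- function(target_samples, reference_samples, seed = NA_integer_) {
  if (length(intersect(target_samples, reference_samples))) {
    stop("target and reference sample sets must be disjoint")
  }
  structure(list(target_samples = as.integer(target_samples),
                 reference_samples = as.integer(reference_samples),
                 seed = seed),
            class = "contrast_design")
}

#' Per-SNP Weir-Cockerham F_ST between target and reference
#'
#' Single-SNP two-population Weir-Cockerham estimator `a / (a + b + c)`.
#' SNPs monomorphic across both groups, or with fewer than two usable
#' samples in either group, are returned as `NA` (flagged undefined,
#' excluded from downstream ranking). Values can be negative for
#' undifferentiated SNPs.
#'
#' @param dataset a `genotype_dataset`
#' @param design a [contrast_design()]
#' @return numeric vector, one value (or NA) per variant
#' @export
snp_fst_contrast <- function(dataset, design) {
  g1 <- dataset$calls[design$target_samples, , drop = FALSE]
  g2 <- dataset$calls[design$reference_samples, , drop = FALSE]
  comp <- wc_components_pair(g1, g2)
  denom <- comp$a + comp$b + comp$c
  ifelse(!is.na(denom) & denom != 0, comp$a / denom, NA_real_)
}

#' Per-SNP allele-frequency difference (delta-SAF)
#'
#' Signed difference in allele-1 frequency, target minus reference. The
#' composite-score ranking uses the absolute value by default (the selected
#' allele's identity is unknown a priori); the signed value is what this
#' function returns.
#'
#' @inheritParams snp_fst_contrast
#' @return numeric vector (NA where either group is all-missing)
#' @export
delta_saf <- function(dataset, design) {
  pt <- allele_frequencies(dataset, design$target_samples)$freq_a1
  pr <- allele_frequencies(dataset, design$reference_samples)$freq_a1
  pt - pr
}

# EHH decay from a core SNP outward in one direction for one haplotype
# matrix (rows = haplotypes). Returns the integrated EHH (trapezoid over bp)
# truncated at the first SNP where EHH < cutoff, at a gap > max_gap_bp, or
# at the chromosome end. `order_idx` are variant column indices walking away
# from the core (excluding the core itself).
ihh_one_side <- function(H, core, order_idx, pos, cutoff, max_gap_bp) {
  grp <- H[, core] + 1L              # partition by core allele
  ehh_prev <- ehh_of_groups(grp)
  pos_prev <- pos[core]
  total <- 0
  for (j in order_idx) {
    if (abs(pos[j] - pos_prev) > max_gap_bp) break
    grp <- refine_groups(grp, H[, j])
    ehh <- ehh_of_groups(grp)
    total <- total + 0.5 * (ehh_prev + ehh) * abs(pos[j] - pos_prev)
    ehh_prev <- ehh
    pos_prev <- pos[j]
    if (ehh < cutoff) break
  }
  total
}

ehh_of_groups <- function(grp) {
  n <- length(grp)
  if (n < 2L) return(0)
  cnt <- tabulate(grp)
  sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
}

refine_groups <- function(grp, allele) {
  key <- grp * 2L + allele
  match(key, unique(key))
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' For each core SNP and each of the two populations, EHH at distance x is
#' the probability that two randomly drawn haplotypes are identical over all
#' SNPs from the core out to x (computed by refining the haplotype partition
#' SNP by SNP); iHH is the trapezoidal integral of EHH over physical
#' distance, in both directions, truncated where EHH drops below
#' `ehh_cutoff`, at an inter-SNP gap over `max_gap_bp`, or at the chromosome
#' end. The raw score is `ln(iHH_target / iHH_reference)`, normalised
#' genome-wide to zero mean and unit variance. A SNP with zero iHH in either
#' group is flagged undefined.
#'
#' Requires phased haplotypes; unphased chip data must be phased upstream.
#'
#' @param haps a `haplotype_set`
#' @param design a [contrast_design()] (indices into `haps$samples`)
#' @param ehh_cutoff EHH truncation level
#' @param max_gap_bp gap truncation (bp)
#' @return data.frame: `id`, `ihh_target`, `ihh_reference`, `xpehh_raw`,
#'   `xpehh_norm`
#' @export
xpehh <- function(haps, design, ehh_cutoff = 0.05, max_gap_bp = 2e6) {
  Ht <- haps$haplotypes[hap_rows(haps, design$target_samples), , drop = FALSE]
  Hr <- haps$haplotypes[hap_rows(haps, design$reference_samples), , drop = FALSE]
  v <- haps$variants
  m <- nrow(v)
  iht <- ihr <- rep(NA_real_, m)
  for (chr in unique(v$chrom)) {
    vi <- which(v$chrom == chr)
    pos <- v$pos_bp
    for (k in seq_along(vi)) {
      core <- vi[k]
      left <- rev(vi[seq_len(k - 1L)])
      right <- vi[seq_along(vi) > k]
      iht[core] <- ihh_one_side(Ht, core, left, pos, ehh_cutoff, max_gap_bp) +
        ihh_one_side(Ht, core, right, pos, ehh_cutoff, max_gap_bp)
      ihr[core] <- ihh_one_side(Hr, core, left, pos, ehh_cutoff, max_gap_bp) +
        ihh_one_side(Hr, core, right, pos, ehh_cutoff, max_gap_bp)
    }
  }
  raw <- ifelse(iht > 0 & ihr > 0, log(iht / ihr), NA_real_)
  mu <- mean(raw, na.rm = TRUE)
  sdv <- stats::sd(raw, na.rm = TRUE)
  norm <- if (!is.na(sdv) && sdv > 0) (raw - mu) / sdv else raw * NA_real_
  data.frame(id = v$id, ihh_target = iht, ihh_reference = ihr,
             xpehh_raw = raw, xpehh_norm = norm, stringsAsFactors = FALSE)
}

#' Combine selection statistics into a composite selection signal (CSS)
#'
#' Rank-probit combination: each constituent statistic is converted to an
#' ascending fractional rank `r' = rank / (n + 1)` over its defined SNPs
#' (average ranks for ties), probit-transformed (`z = qnorm(r')`), the z
#' scores averaged across the `m` statistics available at the SNP, and the
#' mean re-expressed as a p-value, `p = 1 - pnorm(z_bar * sqrt(m))`; the
#' composite score is `-log10(p)`. Larger constituent values must mean more
#' selection evidence: F_ST and |delta-SAF| enter as-is, XP-EHH as its
#' signed normalised score (positive = longer target haplotypes).
#'
#' @param dataset a `genotype_dataset` (supplies the SNP map)
#' @param fst per-SNP F_ST from [snp_fst_contrast()]
#' @param dsaf per-SNP signed delta-SAF from [delta_saf()]
#' @param xpehh_norm per-SNP normalised XP-EHH (NULL for the degraded
#'   two-statistic combination when phase is unavailable; the output is
#'   labelled with the statistics used)
#' @param dsaf_mode `"absolute"` (default, direction-agnostic) or `"signed"`
#' @param min_snps minimum defined SNPs per statistic for ranks to be
#'   meaningful
#' @return a `css_table` data.frame: map columns, constituent statistics,
#'   fractional ranks, z scores, `n_stats`, `css_raw`; attribute
#'   `statistics` lists the constituents used
#' @export
css_combine <- function(dataset, fst, dsaf, xpehh_norm = NULL,
                        dsaf_mode = c("absolute", "signed"), min_snps = 1000L) {
  dsaf_mode <- match.arg(dsaf_mode)
  stats_list <- list(fst = fst,
                     dsaf = if (dsaf_mode == "absolute") abs(dsaf) else dsaf)
  if (!is.null(xpehh_norm)) stats_list$xpehh <- xpehh_norm
  m_snps <- n_variants(dataset)
  z <- matrix(NA_real_, m_snps, length(stats_list),
              dimnames = list(NULL, names(stats_list)))
  rk <- z
  for (s in names(stats_list)) {
    x <- stats_list[[s]]
    if (length(x) != m_snps) stop("statistic '", s, "' has wrong length")
    def <- !is.na(x)
    if (sum(def) < min_snps) {
      stop("statistic '", s, "' defined for ", sum(def),
           " SNPs; ranks are not meaningful below ", min_snps)
    }
    fr <- rank(x[def], ties.method = "average") / (sum(def) + 1)
    rk[def, s] <- fr
    z[def, s] <- stats::qnorm(fr)
  }
  n_stats <- rowSums(!is.na(z))
  zbar <- ifelse(n_stats > 0, rowMeans(z, na.rm = TRUE), NA_real_)
  p <- 1 - stats::pnorm(zbar * sqrt(n_stats))
  css_raw <- -log10(p)
  out <- data.frame(
    id = dataset$variants$id,
    chrom = dataset$variants$chrom,
    pos_bp = dataset$variants$pos_bp,
    fst = fst, delta_saf = dsaf,
    xpehh_norm = if (is.null(xpehh_norm)) NA_real_ else xpehh_norm,
    stringsAsFactors = FALSE
  )
  out <- cbind(out,
               rank_fst = rk[, "fst"], rank_dsaf = rk[, "dsaf"],
               rank_xpehh = if (is.null(xpehh_norm)) NA_real_ else rk[, "xpehh"],
               z_fst = z[, "fst"], z_dsaf = z[, "dsaf"],
               z_xpehh = if (is.null(xpehh_norm)) NA_real_ else z[, "xpehh"],
               n_stats = n_stats, css_raw = css_raw)
  attr(out, "statistics") <- names(stats_list)
  class(out) <- c("css_table", "data.frame")
  out
}

#' Smooth composite scores over a physical window
#'
#' `css_smoothed` at each SNP is the mean `css_raw` over SNPs on the same
#' chromosome within half the window either side of it (sliding, inclusive);
#' an isolated SNP keeps its raw score.
#'
#' @param table a `css_table`
#' @param window_bp full window width (default 1 Mb)
#' @return the table with a `css_smoothed` column added
#' @export
smooth_css <- function(table, window_bp = 1e6) {
  half <- window_bp / 2
  table$css_smoothed <- NA_real_
  for (chr in unique(table$chrom)) {
    vi <- which(table$chrom == chr)
    pos <- table$pos_bp[vi]
    raw <- table$css_raw[vi]
    def <- !is.na(raw)
    cs <- cumsum(ifelse(def, raw, 0))
    cn <- cumsum(as.integer(def))
    lo <- findInterval(pos - half, pos, left.open = TRUE)       # first idx >= pos-half is lo+1
    hi <- findInterval(pos + half, pos)
    s <- cs[hi] - c(0, cs)[lo + 1L]
    n <- cn[hi] - c(0, cn)[lo + 1L]
    table$css_smoothed[vi] <- ifelse(n > 0, s / n, NA_real_)
  }
  table
}

#' Call significant selection-peak regions
#'
#' A SNP in the genome-wide top `top_frac_a` (default 0.1%) of scores is
#' significant when at least `min_support` distinct other SNPs from the top
#' `top_frac_b` (default 1%) lie within `flank_bp` of it on the same
#' chromosome. Significant SNPs within `merge_bp` of each other merge into
#' one region whose bounds span the supporting top-`top_frac_b` SNPs.
#'
#' @param table a `css_table`; the rule is applied to `css_smoothed` by
#'   default (must exist; see [smooth_css()]) or to `css_raw` with
#'   `score = "raw"`
#' @param top_frac_a,top_frac_b upper-tail fractions defining the candidate
#'   and supporting SNP sets
#' @param flank_bp flanking radius for the support count
#' @param min_support minimum supporting SNPs
#' @param merge_bp merge distance between significant SNPs
#' @param score `"smoothed"` or `"raw"`
#' @return data.frame of regions: `chrom`, `start_bp`, `end_bp`, `apex_id`
#'   (highest-scoring significant SNP), `n_top_a_snps`, `n_top_b_support`
#' @export
call_peaks <- function(table, top_frac_a = 0.001, top_frac_b = 0.01,
                       flank_bp = 5e5, min_support = 5L, merge_bp = 1e6,
                       score = c("smoothed", "raw")) {
  score <- match.arg(score)
  x <- if (score == "smoothed") table$css_smoothed else table$css_raw
  if (score == "smoothed" && is.null(x)) stop("no css_smoothed column; run smooth_css()")
  def <- which(!is.na(x))
  if (length(def) < 1 / top_frac_a) {
    stop("only ", length(def), " scored SNPs; top-", top_frac_a,
         " threshold is degenerate below ", ceiling(1 / top_frac_a))
  }
  thr_a <- stats::quantile(x[def], 1 - top_frac_a, names = FALSE)
  thr_b <- stats::quantile(x[def], 1 - top_frac_b, names = FALSE)
  top_a <- def[x[def] >= thr_a]
  top_b <- def[x[def] >= thr_b]
  empty <- data.frame(chrom = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), apex_id = character(0),
                      n_top_a_snps = integer(0), n_top_b_support = integer(0),
                      stringsAsFactors = FALSE)
  # all-tie degenerate case: "top" sets span everything, no localised signal
  if (thr_a == thr_b && length(top_a) == length(top_b)) return(empty)
  support_of <- function(i) {
    same <- top_b[table$chrom[top_b] == table$chrom[i] & top_b != i]
    same[abs(table$pos_bp[same] - table$pos_bp[i]) <= flank_bp]
  }
  sig <- top_a[vapply(top_a, function(i) length(support_of(i)) >= min_support,
                      logical(1))]
  if (!length(sig)) return(empty)
  sig <- sig[order(table$chrom[sig], table$pos_bp[sig])]
  brk <- c(TRUE, diff(table$chrom[sig]) != 0 | diff(table$pos_bp[sig]) > merge_bp)
  region_id <- cumsum(brk)
  out <- lapply(split(sig, region_id), function(ii) {
    supp <- unique(unlist(lapply(ii, support_of)))
    span <- range(table$pos_bp[c(ii, supp)])
    data.frame(
      chrom = table$chrom[ii[1]],
      start_bp = span[1], end_bp = span[2],
      apex_id = table$id[ii[which.max(x[ii])]],
      n_top_a_snps = length(ii),
      n_top_b_support = length(supp),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes within a flank of selection-peak regions
#'
#' Reads gene intervals from a GFF3 or BED annotation file (via
#' `rtracklayer`; BED's 0-based half-open coordinates are converted to
#' 1-based inclusive on import) and reports, per region, the genes whose
#' interval overlaps the region extended by `flank_bp` on both sides,
#' de-duplicated and sorted by position.
#'
#' @param regions region table from [call_peaks()]
#' @param annotation_path GFF3 (`.gff`, `.gff3`) or BED file; gene name is
#'   taken from the `Name`/`ID` attribute (GFF3) or the name column (BED)
#' @param flank_bp flank added to each region side (default 1 Mb)
#' @param feature_type GFF3 feature type to keep (default `"gene"`; ignored
#'   for BED)
#' @return data.frame: `region_index`, `chrom`, `gene`, `gene_start_bp`,
#'   `gene_end_bp`
#' @export
genes_in_regions <- function(regions, annotation_path, flank_bp = 1e6,
                             feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("genes_in_regions() needs the rtracklayer package")
  }
  gr <- tryCatch(rtracklayer::import(annotation_path),
                 error = function(e) stop("malformed annotation file ",
                                          annotation_path, ": ",
                                          conditionMessage(e), call. = FALSE))
  df <- as.data.frame(gr)
  is_gff <- grepl("\\.gff3?(\\.gz)?$", annotation_path, ignore.case = TRUE)
  if (is_gff && "type" %in% names(df)) df <- df[df$type == feature_type, ]
  name <- if ("Name" %in% names(df) && !all(is.na(df$Name))) df$Name
          else if ("ID" %in% names(df)) df$ID
          else if ("name" %in% names(df)) df$name
          else as.character(seq_len(nrow(df)))
  ann <- data.frame(chrom = chrom_code(as.character(df$seqnames)),
                    start = df$start, end = df$end, gene = as.character(name),
                    stringsAsFactors = FALSE)
  out <- list()
  for (ri in seq_len(nrow(regions))) {
    lo <- regions$start_bp[ri] - flank_bp
    hi <- regions$end_bp[ri] + flank_bp
    hit <- ann$chrom == regions$chrom[ri] & ann$end >= lo & ann$start <= hi
    g <- ann[hit, , drop = FALSE]
    g <- g[!duplicated(g$gene), , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g)) {
      out[[length(out) + 1L]] <- data.frame(
        region_index = ri, chrom = regions$chrom[ri], gene = g$gene,
        gene_start_bp = g$start, gene_end_bp = g$end, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(region_index = integer(0), chrom = integer(0),
                      gene = character(0), gene_start_bp = numeric(0),
                      gene_end_bp = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate peak regions with ROH overlap
#'
#' Reports, per region, how many distinct samples have a ROH segment
#' overlapping it — the kind of post-hoc observation used to note that
#' selection peaks fall in ROH tracts shared by several animals. This is an
#' annotation, not a filter.
#'
#' @param regions region table from [call_peaks()]
#' @param segments segment table from [detect_roh()]
#' @return `regions` with an `n_samples_roh_overlap` column added
#' @export
annotate_regions_roh <- function(regions, segments) {
  regions$n_samples_roh_overlap <- vapply(seq_len(nrow(regions)), function(ri) {
    hit <- segments$chrom == regions$chrom[ri] &
      segments$end_bp >= regions$start_bp[ri] &
      segments$start_bp <= regions$end_bp[ri]
    length(unique(segments$sample_id[hit]))
  }, integer(1))
  regions
}
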
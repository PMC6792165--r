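# Independent brute-force oracles. Each takes a different computational route
# from the implementation it checks (allele-level ANOVA mean squares, explicit
# window enumeration, exhaustive haplotype-class listing, manual rank
# arithmetic) and is deliberately written with plain loops.

# --- Weir-Cockerham F_ST via nested random-effects ANOVA on allele indicators.
# Populations / individuals-within / alleles-within-individuals mean squares,
# method-of-moments components a, b, c. Returns per-SNP components.
oracle_wc_components <- function(g1, g2) {
  m <- ncol(g1)
  a <- b <- cc <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    pops <- list(g1[, j][!is.na(g1[, j])], g2[, j][!is.na(g2[, j])])
    n <- vapply(pops, length, numeric(1))
    if (any(n < 2)) next
    ntot <- sum(n)
    r <- 2
    # allele indicator table: per individual two alleles, y = copies of A1
    pbar_i <- vapply(pops, function(x) sum(x) / (2 * length(x)), numeric(1))
    pbar <- sum(n * pbar_i) / ntot
    if (pbar <= 0 || pbar >= 1) next
    ssp <- 0
    for (i in 1:2) ssp <- ssp + 2 * n[i] * (pbar_i[i] - pbar)^2
    msp <- ssp / (r - 1)
    ssi <- 0
    for (i in 1:2) for (x in pops[[i]]) ssi <- ssi + 2 * (x / 2 - pbar_i[i])^2
    msi <- ssi / (ntot - r)
    ssg <- 0
    for (i in 1:2) for (x in pops[[i]]) {
      y <- c(rep(1, x), rep(0, 2 - x))          # the two allele indicators
      ssg <- ssg + sum((y - x / 2)^2)
    }
    msg <- ssg / ntot
    nc <- (ntot - sum(n^2) / ntot) / (r - 1)
    a[j] <- (msp - msi) / (2 * nc)
    b[j] <- (msi - msg) / 2
    cc[j] <- msg
  }
  list(a = a, b = b, c = cc)
}

oracle_weighted_fst <- function(g1, g2) {
  comp <- oracle_wc_components(g1, g2)
  ok <- !is.na(comp$a)
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

# --- heterozygosity-F: literal per-individual transcription of the formula.
oracle_het_f <- function(calls) {
  n <- nrow(calls); m <- ncol(calls)
  p <- e <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    x <- calls[, j][!is.na(calls[, j])]
    T <- 2 * length(x)
    if (T > 1) {
      p[j] <- sum(x) / T
      e[j] <- 1 - 2 * p[j] * (1 - p[j]) * T / (T - 1)
    }
  }
  f <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    O <- E <- N <- 0
    for (j in seq_len(m)) {
      if (!is.na(calls[i, j]) && !is.na(e[j])) {
        N <- N + 1
        E <- E + e[j]
        if (calls[i, j] != 1) O <- O + 1
      }
    }
    if (N > 0 && abs(N - E) > 1e-9) f[i] <- (O - E) / (N - E)
  }
  f
}

# --- ROH: exhaustive window enumeration for one sample on one chromosome.
# Returns a data.frame of segments (start_bp, end_bp, n_snps), or NULL.
oracle_roh_segments <- function(geno, pos, params) {
  m <- length(geno)
  w <- params$window_snp
  if (m < w) return(NULL)
  hom_win <- logical(m - w + 1)
  for (s in seq_len(m - w + 1)) {
    win <- geno[s:(s + w - 1)]
    hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$window_het &&
      sum(is.na(win)) <= params$window_missing
  }
  elig <- logical(m)
  for (i in seq_len(m)) {
    starts <- max(1, i - w + 1):min(m - w + 1, i)
    elig[i] <- mean(hom_win[starts]) >= params$window_threshold
  }
  segs <- NULL
  i <- 1
  while (i <= m) {
    if (!elig[i]) { i <- i + 1; next }
    j <- i
    while (j < m && elig[j + 1] &&
           (pos[j + 1] - pos[j]) <= params$max_gap_kb * 1000) j <- j + 1
    n_snps <- j - i + 1
    len_kb <- (pos[j] - pos[i]) / 1000
    if (n_snps >= params$min_snp && len_kb >= params$min_kb &&
        len_kb / n_snps <= params$max_density) {
      segs <- rbind(segs, data.frame(start_bp = pos[i], end_bp = pos[j],
                                     n_snps = n_snps))
    }
    i <- j + 1
  }
  segs
}

# --- iHH: exhaustive extended-haplotype-class enumeration. For each
# extension endpoint the haplotype classes are listed by pasting the full
# allele string from core to endpoint.
oracle_ihh <- function(H, core, pos, cutoff = 0.05, max_gap_bp = Inf) {
  N <- nrow(H)
  ehh_at <- function(cols) {
    keys <- apply(H[, cols, drop = FALSE], 1, paste, collapse = "")
    cnt <- table(keys)
    sum(choose(cnt, 2)) / choose(N, 2)
  }
  one_side <- function(idx_seq) {
    total <- 0
    prev_ehh <- ehh_at(core)
    prev_pos <- pos[core]
    cols <- core
    for (j in idx_seq) {
      if (abs(pos[j] - prev_pos) > max_gap_bp) break
      cols <- c(cols, j)
      e <- ehh_at(cols)
      total <- total + 0.5 * (prev_ehh + e) * abs(pos[j] - prev_pos)
      prev_ehh <- e
      prev_pos <- pos[j]
      if (e < cutoff) break
    }
    total
  }
  m <- ncol(H)
  one_side(rev(seq_len(core - 1))) + one_side(seq_len(m)[-seq_len(core)])
}

# --- CSS: step-by-step spreadsheet-style evaluation with manual average
# ranks (count-based, not rank()).
oracle_css <- function(stats_list) {
  m <- length(stats_list[[1]])
  zmat <- sapply(stats_list, function(x) {
    def <- !is.na(x)
    nd <- sum(def)
    z <- rep(NA_real_, m)
    for (i in which(def)) {
      rk <- sum(x[def] < x[i]) + (sum(x[def] == x[i]) + 1) / 2
      z[i] <- qnorm(rk / (nd + 1))
    }
    z
  })
  zmat <- matrix(zmat, nrow = m)
  css <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    zz <- zmat[i, ][!is.na(zmat[i, ])]
    if (length(zz)) {
      css[i] <- -log10(1 - pnorm(mean(zz) * sqrt(length(zz))))
    }
  }
  css
}

# --- peak rule: direct transcription with loops over candidate SNPs.
oracle_peaks <- function(chrom, pos, score, top_frac_a = 0.001,
                         top_frac_b = 0.01, flank_bp = 5e5, min_support = 5,
                         merge_bp = 1e6) {
  def <- which(!is.na(score))
  thr_a <- quantile(score[def], 1 - top_frac_a, names = FALSE)
  thr_b <- quantile(score[def], 1 - top_frac_b, names = FALSE)
  top_a <- def[score[def] >= thr_a]
  top_b <- def[score[def] >= thr_b]
  if (thr_a == thr_b && length(top_a) == length(top_b)) return(NULL)
  sig <- c()
  for (i in top_a) {
    supp <- 0
    for (j in top_b) {
      if (j != i && chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= flank_bp) {
        supp <- supp + 1
      }
    }
    if (supp >= min_support) sig <- c(sig, i)
  }
  if (!length(sig)) return(NULL)
  sig <- sig[order(chrom[sig], pos[sig])]
  groups <- list(sig[1])
  if (length(sig) > 1) {
    for (k in 2:length(sig)) {
      i <- sig[k]; prev <- groups[[length(groups)]]
      last <- prev[length(prev)]
      if (chrom[i] == chrom[last] && pos[i] - pos[last] <= merge_bp) {
        groups[[length(groups)]] <- c(prev, i)
      } else groups[[length(groups) + 1]] <- i
    }
  }
  out <- NULL
  for (grp in groups) {
    supp <- c()
    for (i in grp) for (j in top_b) {
      if (j != i && chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= flank_bp) {
        supp <- c(supp, j)
      }
    }
    span <- range(pos[c(grp, unique(supp))])
    out <- rbind(out, data.frame(chrom = chrom[grp[1]], start_bp = span[1],
                                 end_bp = span[2]))
  }
  out
}

# Kruskal-Wallis H with tie correction, computed from first principles.
oracle_kruskal_h <- function(values, labels) {
  n <- length(values)
  rk <- rank(values)
  h <- 0
  for (g in unique(labels)) {
    ri <- rk[labels == g]
    h <- h + sum(ri)^2 / length(ri)
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
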
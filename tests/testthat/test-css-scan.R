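# Shared small scan fixture: two diverged breeds, map on two chromosomes.
scan_fixture <- function(seed = 61, n1 = 20, n2 = 20, m = 40) {
  set.seed(seed)
  two_breed_dataset(n1, n2, m, runif(m, 0.2, 0.8), runif(m, 0.2, 0.8),
                    chrom = rep(1:2, each = m / 2),
                    pos = rep(seq_len(m / 2) * 5e4, 2))
}

test_that("per-SNP F_ST contrast matches boundary values and the ANOVA oracle", {
  ds <- make_dataset(rbind(matrix(2L, 10, 4), matrix(0L, 12, 4)),
                     breed = rep(c("T", "R"), c(10, 12)))
  design <- contrast_design(1:10, 11:22)
  expect_equal(snp_fst_contrast(ds, design), rep(1, 4))
  # identical groups: estimator is non-positive in expectation; exact check
  # that equal frequencies and sizes give a value <= 0
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 8), 8, 4, byrow = FALSE)
  ds2 <- make_dataset(rbind(g, g))
  expect_true(all(snp_fst_contrast(ds2, contrast_design(1:8, 9:16)) <= 0))
  # random instances vs the mean-squares route
  set.seed(62)
  for (trial in 1:20) {
    ds3 <- scan_fixture(seed = trial, m = 20)
    design3 <- contrast_design(1:20, 21:40)
    got <- snp_fst_contrast(ds3, design3)
    comp <- oracle_wc_components(ds3$calls[1:20, ], ds3$calls[21:40, ])
    want <- comp$a / (comp$a + comp$b + comp$c)
    expect_equal(got, want, tolerance = 1e-10)
  }
  # monomorphic-across-groups SNPs are flagged undefined
  ds4 <- make_dataset(matrix(2L, 8, 3))
  expect_true(all(is.na(snp_fst_contrast(ds4, contrast_design(1:4, 5:8)))))
})

test_that("delta-SAF is the signed frequency difference", {
  ds <- make_dataset(rbind(matrix(2L, 5, 2), matrix(0L, 5, 2)))
  design <- contrast_design(1:5, 6:10)
  expect_equal(delta_saf(ds, design), c(1, 1))
  expect_equal(delta_saf(ds, contrast_design(6:10, 1:5)), c(-1, -1))
  # equal frequencies -> 0
  g <- rbind(matrix(c(0L, 2L), 4, 2), matrix(c(2L, 0L), 4, 2))
  expect_equal(delta_saf(make_dataset(g), contrast_design(1:4, 5:8)), c(0, 0))
  # hand computation with missing data
  gm <- matrix(c(2L, 1L, NA, 0L), 4, 1)
  expect_equal(delta_saf(make_dataset(gm), contrast_design(1:2, 3:4)),
               3 / 4 - 0 / 2)
})

test_that("XP-EHH is zero for identical groups, antisymmetric, and matches enumeration", {
  set.seed(63)
  H <- matrix(rbinom(12 * 9, 1, 0.5), 12, 9)
  samples <- data.frame(sample_id = sprintf("s%d", 1:6), breed = "X")
  variants <- data.frame(id = sprintf("v%d", 1:9), chrom = 1L,
                         pos_bp = cumsum(c(1e5, sample(2e4:8e4, 8, TRUE))),
                         a1 = "A", a2 = "C")
  # identical haplotype multisets in target and reference -> raw score 0
  haps <- haplotype_set(rbind(H, H), rbind(samples, transform(samples,
                        sample_id = paste0(sample_id, "b"))), variants)
  design <- contrast_design(1:6, 7:12)
  xp <- xpehh(haps, design)
  expect_true(all(abs(xp$xpehh_raw[!is.na(xp$xpehh_raw)]) < 1e-12))
  # iHH equals the exhaustive extended-haplotype-class enumeration
  set.seed(64)
  for (trial in 1:20) {
    m <- sample(7:15, 1)
    Ht <- matrix(rbinom(10 * m, 1, runif(1, 0.3, 0.7)), 10, m)
    pos <- cumsum(sample(1e4:9e4, m, TRUE))
    for (core in c(1L, sample(seq_len(m), 2), m)) {
      got <- breedscan:::ihh_one_side(Ht, core, rev(seq_len(core - 1)), pos,
                                      0.05, Inf) +
        breedscan:::ihh_one_side(Ht, core, setdiff(seq_len(m), seq_len(core)),
                                 pos, 0.05, Inf)
      expect_equal(got, oracle_ihh(Ht, core, pos, 0.05), tolerance = 1e-10)
    }
  }
  # antisymmetry of the raw score under target/reference exchange
  set.seed(65)
  H2 <- matrix(rbinom(24 * 9, 1, 0.5), 24, 9)
  haps2 <- haplotype_set(H2, data.frame(sample_id = sprintf("s%d", 1:12),
                                        breed = rep(c("T", "R"), each = 6)),
                         variants)
  fwd <- xpehh(haps2, contrast_design(1:6, 7:12))
  rev_ <- xpehh(haps2, contrast_design(7:12, 1:6))
  expect_equal(fwd$xpehh_raw, -rev_$xpehh_raw, tolerance = 1e-12)
})

test_that("EHH is non-increasing as the partition refines outward", {
  set.seed(66)
  H <- matrix(rbinom(20 * 12, 1, 0.5), 20, 12)
  grp <- H[, 6] + 1L
  prev <- breedscan:::ehh_of_groups(grp)
  for (j in 7:12) {
    grp <- breedscan:::refine_groups(grp, H[, j])
    e <- breedscan:::ehh_of_groups(grp)
    expect_lte(e, prev + 1e-12)
    prev <- e
  }
})

test_that("CSS combination reproduces the analytic median case and the spreadsheet oracle", {
  m <- 1001
  x <- seq_len(m)                     # every statistic identical ranks
  ds <- make_dataset(matrix(0:2, 3, m), pos = seq_len(m) * 1e4)
  tab <- css_combine(ds, x, x, x, dsaf_mode = "signed", min_snps = 100)
  med <- which(x == 501)              # the median rank of all three statistics
  expect_equal(tab$css_raw[med], -log10(0.5), tolerance = 1e-12)
  # rank invariance under strictly monotone transforms of any input
  tab2 <- css_combine(ds, exp(x / 100), x, x^3, dsaf_mode = "signed",
                      min_snps = 100)
  expect_equal(tab2$css_raw, tab$css_raw, tolerance = 1e-12)
  # toy table vs the step-by-step oracle (ties included)
  set.seed(67)
  f <- round(runif(m), 2); d <- round(rnorm(m), 1); xp <- rnorm(m)
  xp[sample(m, 50)] <- NA              # some SNPs lack the haplotype statistic
  tab3 <- css_combine(ds, f, d, xp, dsaf_mode = "signed", min_snps = 100)
  want <- oracle_css(list(f = f, d = d, xp = xp))
  expect_equal(tab3$css_raw, want, tolerance = 1e-10)
  expect_true(all(tab3$css_raw >= 0, na.rm = TRUE))
  rk <- c(tab3$rank_fst, tab3$rank_dsaf, tab3$rank_xpehh)
  expect_true(all(rk > 0 & rk < 1, na.rm = TRUE))
})

test_that("the degraded two-statistic combination works without phase", {
  m <- 1200
  ds <- make_dataset(matrix(0:2, 3, m), pos = seq_len(m) * 1e4)
  set.seed(68)
  tab <- css_combine(ds, runif(m), rnorm(m))
  expect_equal(attr(tab, "statistics"), c("fst", "dsaf"))
  expect_true(all(tab$n_stats == 2))
  expect_true(all(is.na(tab$z_xpehh)))
  expect_error(css_combine(ds, c(runif(500), rep(NA, m - 500)), rnorm(m)),
               "not meaningful")
})

test_that("smoothing averages css_raw over the physical window", {
  pos <- c(1e5, 1.2e5, 1.3e5, 5e6, 8e6, 8.1e6) # SNP 4 isolated
  ds <- make_dataset(matrix(0:2, 3, 6), pos = pos)
  tab <- data.frame(id = ds$variants$id, chrom = 1L, pos_bp = pos,
                    css_raw = c(1, 2, 6, 5, 3, 7))
  sm <- smooth_css(tab, window_bp = 1e6)
  expect_equal(sm$css_smoothed, c(3, 3, 3, 5, 5, 5))
  # constant scores smooth to themselves
  tabc <- transform(tab, css_raw = 2)
  expect_equal(smooth_css(tabc)$css_smoothed, rep(2, 6))
  # 12-SNP layout vs direct double-loop averaging
  set.seed(69)
  pos2 <- sort(runif(12, 0, 3e6))
  tab2 <- data.frame(id = letters[1:12], chrom = rep(1:2, each = 6),
                     pos_bp = c(sort(pos2[1:6]), sort(pos2[7:12])),
                     css_raw = runif(12))
  sm2 <- smooth_css(tab2, window_bp = 8e5)
  want <- vapply(1:12, function(i) {
    sel <- tab2$chrom == tab2$chrom[i] & abs(tab2$pos_bp - tab2$pos_bp[i]) <= 4e5
    mean(tab2$css_raw[sel])
  }, numeric(1))
  expect_equal(sm2$css_smoothed, want, tolerance = 1e-12)
})

test_that("the peak rule fires exactly on constructed clusters", {
  set.seed(70)
  m <- 2000
  base_chrom <- rep(2:21, each = 95)
  cluster_chrom <- rep(1L, 100)
  chrom <- c(cluster_chrom, base_chrom)
  pos <- c(seq_len(100) * 8e4, rep(seq_len(95) * 1e5, 20))
  # keep chromosome 1's background low so no stray top-1% SNP lands near the
  # constructed cluster
  score <- c(runif(100) * 0.5, runif(1900))
  # cluster within 0.4 Mb on chromosome 1: one extreme SNP + 5 supporters
  apex <- 50; supp <- c(46, 48, 52, 54, 55)     # 80 kb spacing -> within 0.4 Mb
  score[apex] <- 3
  score[supp] <- 2 + runif(5) / 10
  tab <- data.frame(id = as.character(seq_len(m)), chrom = chrom, pos_bp = pos,
                    css_raw = score)
  pk <- call_peaks(tab, score = "raw")
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$chrom, 1L)
  expect_gte(pk$n_top_b_support, 5L)
  expect_true(pk$start_bp <= pos[apex] && pk$end_bp >= pos[apex])
  # agreement with the loop-transcription oracle
  want <- oracle_peaks(chrom, pos, score)
  expect_equal(pk[, c("chrom", "start_bp", "end_bp")], want, ignore_attr = TRUE)
  # with only 4 supporting SNPs the cluster is rejected
  score4 <- score; score4[55] <- runif(1) * 0.5
  tab4 <- transform(tab, css_raw = score4)
  expect_equal(nrow(call_peaks(tab4, score = "raw")), 0L)
  expect_null(oracle_peaks(chrom, pos, score4))
  # uniform scores (all ties): zero regions
  tabu <- transform(tab, css_raw = 1)
  expect_equal(nrow(call_peaks(tabu, score = "raw")), 0L)
  # degenerate genome: too few SNPs for the 0.1% threshold
  expect_error(call_peaks(tab[1:500, ], score = "raw"), "degenerate")
})

test_that("neutral CSS scores exceed the 0.1% level at the nominal rate", {
  set.seed(71)
  m <- 5000
  ds <- make_dataset(matrix(0:2, 3, m), pos = seq_len(m) * 1e4)
  tab <- css_combine(ds, runif(m), rnorm(m), rnorm(m), dsaf_mode = "signed")
  frac <- mean(tab$css_raw > -log10(0.001))
  se <- sqrt(0.001 * 0.999 / m)
  expect_lt(abs(frac - 0.001), 4 * se + 1e-4)
})

test_that("reference draws are seeded, disjoint and per-breed balanced", {
  sim <- simulate_breeds(breed_sim_config(n_breeds = 4, n_per_breed = 10,
                                          n_snps = 50), seed = 8)
  ds <- sim$dataset
  d1 <- make_contrast(ds, "B2", n_per_ref_breed = 3, seed = 5)
  d2 <- make_contrast(ds, "B2", n_per_ref_breed = 3, seed = 5)
  expect_identical(d1, d2)
  expect_length(d1$reference_samples, 9L)
  expect_length(intersect(d1$target_samples, d1$reference_samples), 0L)
  expect_equal(as.integer(table(ds$samples$breed[d1$reference_samples])),
               rep(3L, 3))
  expect_error(contrast_design(1:5, 3:8), "disjoint")
})

test_that("gene lookup intersects flanked regions with GFF3 and BED annotation", {
  skip_if_not_installed("rtracklayer")
  regions <- data.frame(chrom = c(1L, 1L, 2L),
                        start_bp = c(5e6, 40e6, 10e6),
                        end_bp = c(6e6, 41e6, 11e6))
  genes <- data.frame(
    chrom = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 3, 3),
    start = c(3.0e6, 4.2e6, 6.85e6, 7.15e6, 39.5e6, 42.3e6,
              9.2e6, 10.5e6, 12.1e6, 20e6, 5e6, 6e6),
    end = c(3.1e6, 4.3e6, 6.95e6, 7.25e6, 39.6e6, 42.4e6,
            9.3e6, 10.6e6, 12.2e6, 20.1e6, 5.1e6, 6.1e6),
    name = sprintf("G%02d", 1:12)
  )
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("%d\tsrc\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                       genes$chrom, as.integer(genes$start),
                       as.integer(genes$end), genes$name, genes$name)), gff)
  got <- genes_in_regions(regions, gff, flank_bp = 1e6)
  # manual intersection of [start-1Mb, end+1Mb] with the gene intervals:
  manual <- vapply(seq_len(3), function(ri) {
    hit <- genes$chrom == regions$chrom[ri] &
      genes$end >= regions$start_bp[ri] - 1e6 &
      genes$start <= regions$end_bp[ri] + 1e6
    paste(sort(genes$name[hit]), collapse = ",")
  }, character(1))
  for (ri in 1:3) {
    expect_equal(sort(got$gene[got$region_index == ri]),
                 sort(strsplit(manual[ri], ",")[[1]]))
  }
  # boundary arithmetic: gene 0.9 Mb out is in, 1.1 Mb out is not
  expect_true("G03" %in% got$gene[got$region_index == 1])   # 0.85 Mb away
  expect_false("G04" %in% got$gene[got$region_index == 1])  # 1.15 Mb away
  # BED input, 0-based half-open, same genes
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf("%d\t%d\t%d\t%s", genes$chrom,
                     as.integer(genes$start) - 1L, as.integer(genes$end),
                     genes$name), bed)
  got_bed <- genes_in_regions(regions, bed, flank_bp = 1e6)
  expect_equal(got_bed$gene, got$gene)
  # empty annotation -> empty result
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(genes_in_regions(regions, empty)), 0L)
})

test_that("ROH overlap annotation counts distinct samples per region", {
  regions <- data.frame(chrom = 1L, start_bp = 1e6, end_bp = 2e6)
  segs <- data.frame(sample_id = c("a", "a", "b", "c"),
                     chrom = c(1L, 1L, 1L, 2L),
                     start_bp = c(0.5e6, 1.5e6, 1.9e6, 1e6),
                     end_bp = c(1.2e6, 1.8e6, 3e6, 2e6),
                     n_snps = 100L)
  out <- annotate_regions_roh(regions, segs)
  expect_equal(out$n_samples_roh_overlap, 2L)   # a and b; c is on chrom 2
})
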
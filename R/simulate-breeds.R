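#' Configuration for the multi-breed genotype sampler
#'
#' Defaults mirror the desk-scale study conditions used throughout the test
#' battery: two breeds of 50 animals, 5,000 SNPs spread over 26 autosomes,
#' target differentiation F_ST = 0.10, ancestral minor-allele frequencies
#' uniform on \[0.05, 0.5\], and a 0.003 missing-call rate (a 99.7%
#' genotyping rate, typical of filtered SNP-chip panels).
#'
#' @param n_breeds number of breeds
#' @param n_per_breed samples per breed (scalar or length `n_breeds`)
#' @param n_snps total SNP count
#' @param n_chromosomes autosome count over which SNPs are spread
#' @param chrom_length_bp chromosome length (bp)
#' @param divergence_fst Balding-Nichols differentiation parameter in \[0, 1);
#'   scalar, or one value per breed for breeds at unequal drift distances
#'   from the common ancestor
#' @param ancestral_maf_range interval in (0, 0.5] for ancestral MAF draws
#' @param missing_rate per-call missing probability
#' @return a `breed_sim_config` list
#' @export
breed_sim_config <- function(n_breeds = 2L, n_per_breed = 50L, n_snps = 5000L,
                             n_chromosomes = 26L, chrom_length_bp = 100e6,
                             divergence_fst = 0.10,
                             ancestral_maf_range = c(0.05, 0.5),
                             missing_rate = 0.003) {
  n_per_breed <- rep_len(as.integer(n_per_breed), n_breeds)
  divergence_fst <- rep_len(divergence_fst, n_breeds)
  stopifnot(
    n_breeds >= 1L, all(n_per_breed >= 1L), n_snps >= 1L, n_chromosomes >= 1L,
    chrom_length_bp > 0, all(divergence_fst >= 0), all(divergence_fst < 1),
    length(ancestral_maf_range) == 2L, ancestral_maf_range[1] > 0,
    ancestral_maf_range[2] <= 0.5, missing_rate >= 0, missing_rate < 1
  )
  structure(list(
    n_breeds = as.integer(n_breeds), n_per_breed = n_per_breed,
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp, divergence_fst = divergence_fst,
    ancestral_maf_range = ancestral_maf_range, missing_rate = missing_rate
  ), class = "breed_sim_config")
}

# Random variant map: SNPs spread evenly over chromosomes, positions uniform,
# allele pairs drawn from {A,C,G,T} and stored with a1 < a2 alphabetically.
random_variant_map <- function(n_snps, n_chromosomes, chrom_length_bp) {
  chrom <- sort(rep_len(seq_len(n_chromosomes), n_snps))
  pos <- ceiling(runif(n_snps, 0, chrom_length_bp))
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  pair <- t(vapply(seq_len(n_snps),
                   function(i) sort(sample(c("A", "C", "G", "T"), 2L)),
                   character(2)))
  data.frame(
    id = sprintf("snp%05d_c%d", seq_len(n_snps), chrom),
    chrom = chrom, pos_bp = pos, a1 = pair[, 1], a2 = pair[, 2],
    stringsAsFactors = FALSE
  )
}

#' Simulate multi-breed SNP-array genotypes (Balding-Nichols model)
#'
#' Ancestral allele-1 frequencies are drawn uniformly from the configured MAF
#' range and folded at random (so allele 1 is equally likely to be the major
#' or minor allele). Each breed's frequency is then drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `divergence_fst` (for F = 0 the
#' breed frequency equals the ancestral frequency exactly), and genotypes are
#' Binomial(2, p_breed) — so realized Weir-Cockerham F_ST between breeds is
#' controlled by F. Missing calls are injected at the configured rate.
#' Deterministic under `seed`.
#'
#' @param config a [breed_sim_config()]
#' @param seed integer RNG seed (R's default Mersenne-Twister generator)
#' @return list with `dataset` (a `genotype_dataset`, breeds labelled
#'   "B1", "B2", ...) and `truth` (ancestral and realized per-breed allele
#'   frequencies)
#' @export
simulate_breeds <- function(config = breed_sim_config(), seed = 1L) {
  set.seed(seed)
  m <- config$n_snps
  variants <- random_variant_map(m, config$n_chromosomes, config$chrom_length_bp)
  maf <- runif(m, config$ancestral_maf_range[1], config$ancestral_maf_range[2])
  p_anc <- ifelse(runif(m) < 0.5, maf, 1 - maf)
  pb <- matrix(NA_real_, config$n_breeds, m)
  for (b in seq_len(config$n_breeds)) {
    f <- config$divergence_fst[b]
    pb[b, ] <- if (f == 0) p_anc else {
      rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
  }
  n_total <- sum(config$n_per_breed)
  calls <- matrix(NA_integer_, n_total, m)
  breed <- rep(paste0("B", seq_len(config$n_breeds)), config$n_per_breed)
  row0 <- 0L
  for (b in seq_len(config$n_breeds)) {
    nb <- config$n_per_breed[b]
    calls[row0 + seq_len(nb), ] <-
      matrix(rbinom(nb * m, 2L, rep(pb[b, ], each = nb)), nb, m)
    row0 <- row0 + nb
  }
  if (config$missing_rate > 0) {
    calls[runif(length(calls)) < config$missing_rate] <- NA_integer_
  }
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", breed, unlist(lapply(config$n_per_breed, seq_len))),
    breed = breed, stringsAsFactors = FALSE
  )
  dataset <- genotype_dataset(samples, variants, calls)
  truth <- list(
    ancestral_freq = p_anc,
    breed_freq = pb,
    divergence_fst = f,
    seed = seed
  )
  list(dataset = dataset, truth = truth)
}
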
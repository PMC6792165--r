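#' Configuration for the forward Wright-Fisher simulator
#'
#' Discrete, non-overlapping generations of diploid Wright-Fisher
#' reproduction with crossover recombination, so the output carries genuine
#' LD (encoding the N_e history), runs of homozygosity, and — when a sweep or
#' mating plan is configured — haplotype structure and autozygosity with
#' known truth. Alleles are standing variation in the founders; no mutation
#' occurs during the simulated epoch.
#'
#' The genetic map is fixed at a constant rate (default 1e-8 Morgans/bp =
#' 1 cM/Mb), the same mapping [ne_trajectory()] uses by default, so N_e
#' recovery checks are internally consistent.
#'
#' @param n_snps total SNPs over all chromosomes
#' @param n_chromosomes,chrom_length_bp genome layout
#' @param ne_schedule data.frame(generation, ne): population size from each
#'   breakpoint generation onward (generation 0 row required; ne >= 2)
#' @param n_generations generations of random mating
#' @param recomb_rate_per_bp Morgans per bp
#' @param n_pops populations after `split_generation` (1 = no split); after
#'   the split each population evolves independently at the scheduled size
#' @param split_generation generation at which the ancestral population
#'   splits (required if `n_pops > 1`)
#' @param sample_size animals sampled per population at the end (NULL = all)
#' @param founder_maf_range founder minor-allele-frequency range
#' @param inbreeding_plan integer vector: one full-sib line per entry, run
#'   for that many generations of sib mating after the main epoch (0 = line
#'   founders output unchanged); each line outputs its final two sibs with
#'   breed label "LINE" and their exact pedigree inbreeding coefficient
#' @param sweep NULL or list(chrom, pos_bp, s, start_generation, pop = 1,
#'   initial_freq = 0.05, core_share_bp = 2e6): directional selection
#'   (fitness 1, 1+s, 1+2s for 0/1/2 copies) at the SNP nearest the given
#'   position, applied in the given population from `start_generation` on.
#'   The founder frequency of the swept allele is forced to `initial_freq`,
#'   and all founder carriers share one donor haplotype over
#'   `core_share_bp` around the site — a hard sweep from a variant that
#'   arose once and drifted to its standing frequency, so carriers are
#'   identical by descent at the core (set `core_share_bp = 0` for a soft
#'   sweep from independent backgrounds)
#' @param missing_rate missing-call rate injected into the genotype
#'   projection (haplotypes stay complete)
#' @return a `forward_sim_config` list
#' @export
forward_sim_config <- function(n_snps = 2000L, n_chromosomes = 10L,
                               chrom_length_bp = 5e6,
                               ne_schedule = data.frame(generation = 0, ne = 100),
                               n_generations = 200L,
                               recomb_rate_per_bp = 1e-8,
                               n_pops = 1L, split_generation = NULL,
                               sample_size = NULL,
                               founder_maf_range = c(0.05, 0.5),
                               inbreeding_plan = NULL,
                               sweep = NULL,
                               missing_rate = 0.003) {
  stopifnot(
    n_snps >= 2L, n_chromosomes >= 1L, chrom_length_bp > 0,
    is.data.frame(ne_schedule), all(c("generation", "ne") %in% names(ne_schedule)),
    any(ne_schedule$generation == 0), all(ne_schedule$ne >= 2),
    n_generations >= 1L, recomb_rate_per_bp >= 0, n_pops >= 1L,
    missing_rate >= 0, missing_rate < 1
  )
  if (n_pops > 1L && is.null(split_generation)) {
    stop("split_generation required when n_pops > 1")
  }
  if (!is.null(sweep)) {
    stopifnot(sweep$chrom >= 1, sweep$chrom <= n_chromosomes,
              sweep$pos_bp >= 1, sweep$pos_bp <= chrom_length_bp)
    sweep$pop <- if (is.null(sweep$pop)) 1L else as.integer(sweep$pop)
    if (is.null(sweep$initial_freq)) sweep$initial_freq <- 0.05
    if (is.null(sweep$core_share_bp)) sweep$core_share_bp <- 2e6
  }
  structure(list(
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    ne_schedule = ne_schedule[order(ne_schedule$generation), ],
    n_generations = as.integer(n_generations),
    recomb_rate_per_bp = recomb_rate_per_bp,
    n_pops = as.integer(n_pops), split_generation = split_generation,
    sample_size = sample_size, founder_maf_range = founder_maf_range,
    inbreeding_plan = inbreeding_plan, sweep = sweep,
    missing_rate = missing_rate
  ), class = "forward_sim_config")
}

ne_at <- function(schedule, g) {
  schedule$ne[max(which(schedule$generation <= g))]
}

# Per-interval switch probabilities for the Haldane (Poisson-crossover)
# recombination model; 0.5 at chromosome starts (independent assortment) and
# for the leading interval (random starting haplotype).
switch_probs <- function(chrom, pos, morgans_per_bp) {
  L <- length(pos)
  d <- c(0, diff(pos)) * morgans_per_bp
  r <- 0.5 * (1 - exp(-2 * d))
  r[c(TRUE, chrom[-1L] != chrom[-L])] <- 0.5
  r
}

# One generation of meiosis: H is the parental haplotype matrix (2 rows per
# parent), sires/dams are parent indices per offspring. Returns the offspring
# haplotype matrix (2 rows per offspring: sire gamete then dam gamete).
meiosis_generation <- function(H, sires, dams, r) {
  n_off <- length(sires)
  L <- length(r)
  pidx <- c(sires, dams)                                   # one gamete per entry
  n_gam <- 2L * n_off
  # switch indicators are sparse (r is tiny between adjacent SNPs), so draw
  # per-interval switch counts and scatter them instead of a dense Bernoulli
  B <- matrix(0L, n_gam, L)
  counts <- rbinom(L, n_gam, r)
  for (l in which(counts > 0L)) B[sample.int(n_gam, counts[l]), l] <- 1L
  parity <- t(apply(B, 1L, cumsum)) %% 2L
  rows <- (2L * pidx - 1L) + parity                        # parental haplotype row
  G <- matrix(H[cbind(as.vector(rows), rep(seq_len(L), each = 2L * n_off))],
              2L * n_off, L)
  out <- matrix(0L, 2L * n_off, L)
  out[2L * seq_len(n_off) - 1L, ] <- G[seq_len(n_off), , drop = FALSE]
  out[2L * seq_len(n_off), ] <- G[n_off + seq_len(n_off), , drop = FALSE]
  out
}

sample_parents <- function(n_parents, n_off, w = NULL) {
  sires <- sample.int(n_parents, n_off, replace = TRUE, prob = w)
  dams <- sample.int(n_parents, n_off, replace = TRUE, prob = w)
  clash <- which(dams == sires)
  while (length(clash) && n_parents > 1L) {
    dams[clash] <- sample.int(n_parents, length(clash), replace = TRUE, prob = w)
    clash <- clash[dams[clash] == sires[clash]]
  }
  list(sires = sires, dams = dams)
}

# Pedigree inbreeding coefficient after k generations of full-sib mating
# (unrelated non-inbred line founders), by the kinship recursion.
fullsib_pedigree_f <- function(k) {
  if (k == 0L) return(0)
  f_par <- c(0, 0)            # inbreeding of current parent pair
  phi <- 0                    # kinship between current parents
  f_child <- 0
  for (i in seq_len(k)) {
    f_child <- phi
    phi_new <- 0.25 * (0.5 * (1 + f_par[1]) + 2 * phi + 0.5 * (1 + f_par[2]))
    f_par <- c(f_child, f_child)
    phi <- phi_new
  }
  f_child
}

#' Simulate a population forward in time (Wright-Fisher with recombination)
#'
#' Runs the configured demography: founders at the generation-0 scheduled
#' size with independently drawn standing variants, then `n_generations` of
#' random mating with Poisson crossovers; optionally a split into `n_pops`
#' descendant populations, a selective sweep in one population, and full-sib
#' inbred lines appended after the main epoch. Deterministic under `seed`.
#'
#' If the swept allele is lost it is reported in `truth$sweep$lost` rather
#' than the simulation being re-run; callers may retry with another seed.
#'
#' @param config a [forward_sim_config()]
#' @param seed integer RNG seed
#' @return list with `dataset` (genotype projection, breeds "P1"... and
#'   "LINE"), `haps` (a `haplotype_set`, phased, no missing data), and
#'   `truth` (per-population allele frequencies, per-sample pedigree F,
#'   sweep trajectory, echoed ne schedule)
#' @export
simulate_forward <- function(config = forward_sim_config(), seed = 1L) {
  set.seed(seed)
  L <- config$n_snps
  variants <- random_variant_map(L, config$n_chromosomes, config$chrom_length_bp)
  r <- switch_probs(variants$chrom, variants$pos_bp, config$recomb_rate_per_bp)

  sweep <- config$sweep
  sweep_idx <- NA_integer_
  if (!is.null(sweep)) {
    on_chr <- which(variants$chrom == sweep$chrom)
    sweep_idx <- on_chr[which.min(abs(variants$pos_bp[on_chr] - sweep$pos_bp))]
  }

  n0 <- ne_at(config$ne_schedule, 0)
  maf <- runif(L, config$founder_maf_range[1], config$founder_maf_range[2])
  p0 <- ifelse(runif(L) < 0.5, maf, 1 - maf)
  if (!is.na(sweep_idx)) p0[sweep_idx] <- sweep$initial_freq
  pops <- list(matrix(rbinom(2L * n0 * L, 1L, rep(p0, each = 2L * n0)), 2L * n0, L))
  if (!is.na(sweep_idx) && sweep$core_share_bp > 0) {
    # hard-sweep founders: carriers are IBD over the core region around the
    # selected site (one donor haplotype copied onto every carrier)
    carriers <- which(pops[[1L]][, sweep_idx] == 1L)
    core <- which(variants$chrom == sweep$chrom &
                    abs(variants$pos_bp - variants$pos_bp[sweep_idx]) <=
                      sweep$core_share_bp / 2)
    if (length(carriers) > 1L) {
      donor <- pops[[1L]][carriers[1L], core]
      pops[[1L]][carriers, core] <- rep(donor, each = length(carriers))
    }
  }

  split_g <- if (config$n_pops > 1L) config$split_generation else Inf
  traj <- if (!is.na(sweep_idx)) rep(NA_real_, config$n_generations) else NULL

  for (g in seq_len(config$n_generations)) {
    if (g == split_g) pops <- rep(pops, config$n_pops)
    ng <- ne_at(config$ne_schedule, g)
    for (k in seq_along(pops)) {
      H <- pops[[k]]
      n_par <- nrow(H) / 2L
      w <- NULL
      if (!is.na(sweep_idx) && k == sweep$pop && g >= sweep$start_generation) {
        geno_sweep <- H[2L * seq_len(n_par) - 1L, sweep_idx] +
          H[2L * seq_len(n_par), sweep_idx]
        w <- 1 + sweep$s * geno_sweep
        if (all(w == w[1])) w <- NULL
      }
      par <- sample_parents(n_par, ng, w)
      pops[[k]] <- meiosis_generation(H, par$sires, par$dams, r)
    }
    if (!is.na(sweep_idx)) {
      traj[g] <- mean(pops[[sweep$pop]][, sweep_idx])
    }
  }

  # assemble output samples: per-population draws, then inbred lines
  hap_blocks <- list()
  sample_id <- breed <- character(0)
  pedigree_f <- numeric(0)
  for (k in seq_along(pops)) {
    H <- pops[[k]]
    n_k <- nrow(H) / 2L
    take <- if (is.null(config$sample_size)) seq_len(n_k) else {
      sort(sample.int(n_k, min(config$sample_size, n_k)))
    }
    hap_blocks[[length(hap_blocks) + 1L]] <-
      H[as.vector(rbind(2L * take - 1L, 2L * take)), , drop = FALSE]
    sample_id <- c(sample_id, sprintf("P%d_%03d", k, seq_along(take)))
    breed <- c(breed, rep(paste0("P", k), length(take)))
    pedigree_f <- c(pedigree_f, rep(0, length(take)))
  }
  if (!is.null(config$inbreeding_plan)) {
    H1 <- pops[[1L]]
    n1 <- nrow(H1) / 2L
    for (li in seq_along(config$inbreeding_plan)) {
      gens <- config$inbreeding_plan[li]
      fnd <- sample.int(n1, 2L)
      Hline <- H1[as.vector(rbind(2L * fnd - 1L, 2L * fnd)), , drop = FALSE]
      if (gens > 0L) {
        for (gg in seq_len(gens)) {
          Hline <- meiosis_generation(Hline, c(1L, 1L), c(2L, 2L), r)
        }
      }
      hap_blocks[[length(hap_blocks) + 1L]] <- Hline
      sample_id <- c(sample_id, sprintf("L%02d_%d", li, 1:2))
      breed <- c(breed, rep("LINE", 2L))
      pedigree_f <- c(pedigree_f, rep(fullsib_pedigree_f(gens), 2L))
    }
  }
  haplotypes <- do.call(rbind, hap_blocks)
  samples <- data.frame(sample_id = sample_id, breed = breed,
                        stringsAsFactors = FALSE)
  haps <- haplotype_set(haplotypes, samples, variants)
  dataset <- haps_to_genotypes(haps)
  if (config$missing_rate > 0) {
    dataset$calls[runif(length(dataset$calls)) < config$missing_rate] <- NA_integer_
  }
  pop_freq <- do.call(rbind, lapply(pops, colMeans))
  truth <- list(
    pop_freq = pop_freq,
    pedigree_f = stats::setNames(pedigree_f, sample_id),
    ne_schedule = config$ne_schedule,
    seed = seed,
    sweep = if (!is.na(sweep_idx)) {
      list(snp_index = sweep_idx, snp_id = variants$id[sweep_idx],
           chrom = variants$chrom[sweep_idx], pos_bp = variants$pos_bp[sweep_idx],
           trajectory = traj,
           final_freq = traj[length(traj)],
           lost = traj[length(traj)] == 0)
    } else NULL
  )
  list(dataset = dataset, haps = haps, truth = truth)
}
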
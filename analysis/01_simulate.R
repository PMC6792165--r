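#!/usr/bin/env Rscript
# Build the synthetic study inputs for the downstream analyses:
#   (a) an 11-breed SNP-chip panel (Balding-Nichols) with breed-specific
#       drift, mirroring a multi-breed diversity panel that includes one
#       at-risk heritage breed of interest ("GAL") — used by the filtering,
#       PCA, F_ST and inbreeding-F analyses;
#   (b) a forward-simulated two-population dataset with a hard selective
#       sweep in the target population, phased — used by the selection scan;
#   (c) a forward-simulated declining herd — used by the N_e analysis.
# Everything is seeded; ground truth is written alongside the data.

library(breedscan)
seed <- 20260925L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

## (a) 11-breed chip panel ---------------------------------------------------
breeds <- c("GAL", "MER", "BRL", "DSH", "FIN", "ISF", "ROM", "SBF", "SOA",
            "STX", "WIL")
# breed-specific drift from the common ancestor: conventional breeds low,
# long-isolated island/heritage breeds high; pairwise F_ST is roughly the
# mean of the two breeds' drift, spanning ~0.08 (MER-SBF) to ~0.33 (SOA-WIL)
drift <- c(GAL = 0.13, MER = 0.07, BRL = 0.15, DSH = 0.17, FIN = 0.11,
           ISF = 0.12, ROM = 0.09, SBF = 0.09, SOA = 0.40, STX = 0.10,
           WIL = 0.25)
cfg <- breed_sim_config(n_breeds = 11, n_per_breed = 30, n_snps = 6000,
                        n_chromosomes = 26, divergence_fst = unname(drift))
sim <- simulate_breeds(cfg, seed = seed)
panel <- sim$dataset
panel$samples$breed <- breeds[match(panel$samples$breed,
                                    paste0("B", seq_along(breeds)))]
panel$samples$sample_id <- sub("^B\\d+", "", panel$samples$sample_id)
panel$samples$sample_id <- paste0(panel$samples$breed,
                                  panel$samples$sample_id)
# a sprinkle of unusable markers so the QC stage has real work:
# 40 unassigned, 40 sex-linked, 20 with no map position
n <- n_variants(panel)
bad <- sample(n, 100)
panel$variants$chrom[bad[1:40]] <- 0L
panel$variants$chrom[bad[41:80]] <- 27L
panel$variants$pos_bp[bad[81:100]] <- 0
write_plink(panel, "results/data/panel", "bed")
jsonlite::write_json(
  list(seed = seed, breeds = breeds, drift = drift,
       n_snps = n, n_bad_markers = 100),
  "results/data/panel_truth.json", auto_unbox = TRUE, digits = NA)
cat("panel:", n_samples(panel), "samples x", n, "SNPs,",
    length(breeds), "breeds -> results/data/panel.{bed,bim,fam}\n")

## (b) selection-scan dataset ------------------------------------------------
scan_cfg <- forward_sim_config(
  n_snps = 2400, n_chromosomes = 20, chrom_length_bp = 5e6,
  ne_schedule = data.frame(generation = 0, ne = 400),
  n_generations = 45, n_pops = 2, split_generation = 1, sample_size = 50,
  sweep = list(chrom = 1, pos_bp = 2.5e6, s = 0.2, start_generation = 1,
               initial_freq = 0.05),
  missing_rate = 0)
scan <- simulate_forward(scan_cfg, seed = seed + 1L)
write_plink(scan$dataset, "results/data/scan", "ped")
write_haplotypes(scan$haps, "results/data/scan_haplotypes.tsv")
jsonlite::write_json(
  list(seed = seed + 1L, sweep = scan$truth$sweep[c("snp_id", "chrom",
                                                    "pos_bp", "final_freq")]),
  "results/data/scan_truth.json", auto_unbox = TRUE, digits = NA)
cat("scan: sweep at chr", scan$truth$sweep$chrom, "pos",
    scan$truth$sweep$pos_bp, "swept to frequency",
    round(scan$truth$sweep$final_freq, 3), "\n")

## (c) declining herd for the N_e analysis -----------------------------------
herd_cfg <- forward_sim_config(
  n_snps = 2000, n_chromosomes = 10, chrom_length_bp = 5e6,
  ne_schedule = data.frame(generation = c(0, 150), ne = c(300, 100)),
  n_generations = 200, missing_rate = 0.003)
herd <- simulate_forward(herd_cfg, seed = seed + 2L)
write_plink(herd$dataset, "results/data/herd", "ped")
jsonlite::write_json(list(seed = seed + 2L,
                          ne_schedule = herd_cfg$ne_schedule),
                     "results/data/herd_truth.json", auto_unbox = TRUE,
                     digits = NA)
cat("herd: declining history (N_e 300 -> 100 at generation 150) ->",
    "results/data/herd.{ped,map}\n")
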
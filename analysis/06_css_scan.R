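#!/usr/bin/env Rscript
# Composite selection-signal scan of the forward-simulated target population
# against its sister population: per-SNP Weir-Cockerham F_ST, allele
# frequency difference, and XP-EHH, combined by rank-probit averaging into
# CSS, smoothed over 1 Mb, with peaks called by the flanking rule (raw-score
# mode) and annotated with ROH overlap and nearby genes from a toy GFF3.

library(breedscan)
sim_truth <- jsonlite::fromJSON("results/data/scan_truth.json")
ds <- read_plink("results/data/scan", "ped")
haps <- read_haplotypes("results/data/scan_haplotypes.tsv", ds)

design <- contrast_design(which(ds$samples$breed == "P1"),
                          which(ds$samples$breed == "P2"))
fst <- snp_fst_contrast(ds, design)
dsaf <- delta_saf(ds, design)
xp <- xpehh(haps, design)
tab <- smooth_css(css_combine(ds, fst, dsaf, xp$xpehh_norm))
write.table(tab, "results/css_table.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

regions <- call_peaks(tab, score = "raw")
seg <- detect_roh(ds, roh_params(min_snp = 50L))
regions <- annotate_regions_roh(regions, seg)
write.table(regions, "results/css_regions.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("called", nrow(regions), "selection region(s):\n")
print(regions)
cat("true sweep site: chr", sim_truth$sweep$chrom, "pos",
    sim_truth$sweep$pos_bp, "\n")

# candidate genes within +/-1 Mb of each peak, from a small synthetic
# annotation built around the simulated genome
set.seed(1)
genes <- data.frame(chrom = rep(1:20, each = 10),
                    start = round(rep(seq(2e5, 4.7e6, length.out = 10),
                                      20) + runif(200, 0, 1e5)))
genes$end <- genes$start + round(runif(200, 5e3, 8e4))
genes$name <- sprintf("GENE%03d", seq_len(200))
gff <- "results/data/synthetic_genes.gff3"
writeLines(c("##gff-version 3",
             sprintf("%d\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
                     genes$chrom, genes$start, genes$end, genes$name,
                     genes$name)), gff)
if (nrow(regions)) {
  hits <- genes_in_regions(regions, gff, flank_bp = 1e6)
  write.table(hits, "results/css_region_genes.tsv", sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat(nrow(hits), "candidate genes within 1 Mb of the peaks ->",
      "results/css_region_genes.tsv\n")
}
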
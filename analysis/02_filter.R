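#!/usr/bin/env Rscript
# Marker QC on the synthetic chip panel: drop SNPs without map positions,
# SNPs unassigned to a chromosome, and sex-linked SNPs; report the partition
# of removals and the post-filter genotyping rate. Writes the filtered panel
# that all later breed analyses consume.

library(breedscan)
dir.create("results", showWarnings = FALSE)

panel <- read_plink("results/data/panel", "bed")
flt <- filter_variants(panel, autosome_max = 26L)
print(flt$report)
write_filter_report(flt$report, "results/filter_report.tsv")
write_plink(flt$dataset, "results/data/panel_filtered", "bed")
cat("retained", flt$report$n_retained, "of", flt$report$n_input,
    "SNPs; genotyping rate", sprintf("%.4f", flt$report$genotyping_rate),
    "-> results/data/panel_filtered.*\n")
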
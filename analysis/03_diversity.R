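#!/usr/bin/env Rscript
# Breed differentiation on the filtered panel: Patterson-scaled PCA (no
# outlier-removal iterations; samples that stray from their own breed
# centroid are reported, not removed) and the pairwise weighted
# Weir-Cockerham F_ST matrix.

library(breedscan)
ds <- read_plink("results/data/panel_filtered", "bed")

pc <- pca_genotypes(ds, k = 10)
print(pc)
write.table(data.frame(sample_id = rownames(pc$scores),
                       breed = ds$samples$breed, pc$scores),
            "results/pca_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(data.frame(component = seq_along(pc$variance_explained),
                       variance_explained = pc$variance_explained),
            "results/pca_variance.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
out <- flag_pc_outliers(pc, ds$samples$breed, k = 4)
write.table(out, "results/pca_outliers.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(nrow(out), "samples sit closer to another breed's PC centroid",
    "(candidate mislabels/crossbreds) -> results/pca_outliers.tsv\n")

fst <- pairwise_fst(ds)
write_fst_matrix(fst, "results/fst_matrix.tsv")
v <- fst$values[lower.tri(fst$values)]
pairs <- which(lower.tri(fst$values), arr.ind = TRUE)
lab <- function(i) paste(fst$breeds[pairs[i, 2]], fst$breeds[pairs[i, 1]],
                         sep = "-")
cat(sprintf("pairwise weighted F_ST: min %.3f (%s), max %.3f (%s)\n",
            min(v), lab(which.min(v)), max(v), lab(which.max(v))))
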
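#!/usr/bin/env Rscript
# Historical effective population size of the simulated declining herd from
# the decay of genotype-correlation LD with recombination distance (linear
# 1 cM/Mb map, unphased adjustment, alpha = 2.2). The herd was simulated
# with N_e 300 dropping to 100 fifty generations before sampling, so the
# trajectory should fall towards the present.

library(breedscan)
herd <- read_plink("results/data/herd", "ped")

ld <- pairwise_r2(herd, breed = "P1")
print(ld)
tr <- ne_trajectory(ld)
write.table(tr, "results/ne_trajectory.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
rec <- tr[tr$valid & tr$t_generations <= 25, ]
old <- tr[tr$valid & tr$t_generations >= 60, ]
cat(sprintf("most recent point: N_e = %.0f at t = %.0f generations ago\n",
            rec$ne_estimate[1], rec$t_generations[1]))
cat(sprintf("mean recent (t<=25) N_e = %.0f; mean older (t>=60) N_e = %.0f\n",
            mean(rec$ne_estimate), mean(old$ne_estimate)))
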
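---
title: "Methods: population-genomic characterisation of livestock breeds"
author: "breedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic characterisation of livestock breeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

breedscan implements the analysis battery used to characterise an at-risk
livestock breed from medium-density SNP-array genotypes: marker QC, breed
differentiation (PCA, pairwise weighted F~ST~), genomic inbreeding
(heterozygosity-based F, runs of homozygosity, F~ROH~), LD-based historical
effective population size, and a composite selection-signal scan. This
vignette records the models, the parameter choices, and the design decisions
behind each stage, together with what the simulation-based checks do and do
not demonstrate.

## Data model and formats

The central container is a `genotype_dataset`: a samples x variants matrix
of diploid calls coded as the count of `allele_a1` (0/1/2, with `NA` the
missing sentinel — never conflated with the homozygous-A2 count 0), a sample
table (id + breed label, taken from the PLINK family-ID column by
convention), and a map table with 1-based physical coordinates. Variants are
kept sorted by (chromosome, position); unsorted files are accepted and
stably sorted on read rather than rejected, since real BIM files are usually
but not reliably sorted.

Both PLINK dialects are supported: PED/MAP text and SNP-major BED/BIM/FAM
binary (magic bytes `6C 1B`, mode `01`). Call coding follows the file: for
BED/BIM, A1/A2 are the BIM allele columns; PED/MAP carries no allele
columns, so A1 is defined as the alphabetically first allele observed at the
SNP. One consequence is worth knowing: the text format cannot represent an
allele absent from the sample set, so a dataset round-trips through PED/MAP
with its original allele orientation only at SNPs where both alleles are
observed. BED/BIM preserves orientation unconditionally. All downstream
statistics are either orientation-symmetric or use orientation only through
frequencies they re-derive.

Chromosome codes are integers; X, Y, XY and MT map to 27, 28, 29, 30 and
anything outside 1..`autosome_max` (26 for sheep, OAR1-OAR26) is
non-autosomal. The variant filter retains exactly the positioned autosomal
SNPs — markers with no map position, no chromosome assignment, or a
sex-chromosome assignment are removed and the report partitions every
removal. Sample-level QC (call rate, MAF) is deliberately out of scope:
array panels of this kind arrive already filtered.

## The two simulators

No single cheap generative model covers every stage, so there are two:

**Balding-Nichols breed sampler** (`simulate_breeds`). Ancestral allele
frequencies are uniform on a configurable MAF range (folded at random);
each breed's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) with F the breed's
divergence parameter (per-breed values supported; F = 0 returns the
ancestral frequency exactly); genotypes are Binomial(2, p~b~). This gives
exact, fast control of differentiation — realized pairwise Weir-Cockerham
F~ST~ is close to the mean of the two breeds' F — and is the substrate for
the F~ST~/PCA/inbreeding-F checks. Its defaults (2 breeds x 50 animals,
5,000 SNPs over 26 autosomes, F = 0.10, 0.3% missing calls matching a
99.7% genotyping rate) are the conditions used by the parameter-recovery
checks. It produces *no* linkage structure: sites are independent, so ROH,
LD and haplotype statistics on its output are null.

**Forward Wright-Fisher simulator** (`simulate_forward`). Diploid
discrete-generation reproduction with Poisson crossovers (Haldane model,
implemented as per-interval Markov switching; a constant 1 cM/Mb map, the
same mapping the N~e~ stage assumes by default). Founders carry standing
variation drawn in linkage equilibrium; there is no mutation during the
epoch, so all downstream signal is drift, recombination, mating design and
selection. Options: a stepwise `ne_schedule`; a split into descendant
populations at a chosen generation; full-sib inbred lines appended after
the main epoch, each annotated with its exact pedigree inbreeding
coefficient from the kinship recursion (0, 1/4, 3/8, 1/2, 19/32, ... for
successive sib matings from unrelated founders); and a selective sweep
(fitness 1, 1+s, 1+2s) at the SNP nearest a requested position. Genotype
output gets missing calls injected at 0.3% by default; the phased
haplotypes are returned complete.

The sweep is *hard* by default: founder carriers of the selected allele
share one donor haplotype over a 2 Mb core around the site, emulating a
variant that arose once and drifted to its standing frequency (5% by
default). Without this (set `core_share_bp = 0`) the allele starts on many
independent backgrounds and sweeps softly, which dilutes exactly the
haplotype-homozygosity and hitchhiking signals a selection scan looks for.
A lost sweep is reported in the returned truth, never silently re-run; the
recovery analyses re-draw seeds at the caller level and say so.

What the simulators do *not* emulate: genotyping error, ascertainment bias
of chip SNPs, overlapping generations, family structure beyond the sib
lines, mutation, and gene flow after a split. Checks passing on this
material demonstrate correctness of the estimators under their own model
assumptions, not robustness to array artefacts.

## Breed differentiation

Allele frequencies always exclude missing calls from numerator and
denominator, and a SNP with no genotyped sample in a subset is flagged
undefined rather than set to 0.

Pairwise F~ST~ uses the Weir-Cockerham (1984) variance components
(a = among-population, b = among-individual-within, c = within-individual,
with the two-population sample-size terms and observed heterozygote
frequencies), combined across loci as the **ratio of sums**
sum(a)/sum(a+b+c) — the "weighted" form, chosen because breed sample sizes
are unequal. SNPs monomorphic across a pair, or with fewer than two
genotyped samples in either breed, are excluded from that pair and counted.
Negative estimates are reported as computed, not clamped: clamping would
bias the permutation-null comparisons the tests rely on. The test suite
checks the implementation against an independent derivation that computes
the same components from nested ANOVA mean squares on allele indicators.

PCA mean-centres each SNP and scales by sqrt(p(1-p)) (Patterson scaling),
drops monomorphic SNPs, imputes missing calls to the column mean (a
`drop_snp` alternative is exposed), and takes the SVD. No outlier-removal
iterations are run — outliers can be biologically meaningful crossbreds —
but `flag_pc_outliers` reports samples whose distance to their own breed
centroid exceeds the distance to another breed's; removal is the user's
decision. With many weakly separated breeds this report is intentionally
liberal: it is a screening list, not a verdict.

## Genomic inbreeding

**Heterozygosity-based F.** Per SNP, the expected-homozygosity contribution
is 1 - 2p(1-p)T/(T-1), with p the pooled sample frequency and T the
observed allele count (the small-sample correction); per individual,
f_hat = (O - E)/(N - E) over that individual's non-missing SNPs. Pooling
all breeds for p mirrors a single run over a multi-breed panel and makes
values comparable across breeds; a per-breed-frequency mode is exposed and
documented to change the values (within-breed F is relative to the breed's
own frequencies and is typically much closer to zero).

**ROH.** The sliding-window scan follows the long-standing PLINK defaults:
50-SNP windows calling a window homozygous if it has at most 1 heterozygous
and 5 missing calls; a SNP is ROH-eligible when at least 5% of windows
containing it are homozygous; maximal eligible runs are split at inter-SNP
gaps over 1,000 kb and kept if they have at least 100 SNPs, span at least
1,000 kb, and average at most 50 kb/SNP. All eight parameters are exposed
and echoed into output headers. The implementation is checked against an
exhaustive window-enumeration oracle for exact segment equality; one edge
behaviour to be aware of is that the outermost one or two SNPs of a long
homozygous tract can fall below the hit-rate threshold (few of their
covering windows are fully homozygous), so a tract of n homozygous SNPs may
be reported with slightly fewer than n.

**F~ROH~** is the summed ROH span divided by the SNP-covered autosomal
length. Both use the same bp-span convention (end - start, summed per
chromosome as last-SNP minus first-SNP position), so a segment covering a
chromosome's whole SNP extent contributes exactly that chromosome's span
and F~ROH~ is always in [0, 1]. A fixed assembly length can be substituted
for the denominator. Length-class summaries default to bins [1,5), [5,10),
[10,20), [20,40), >=40 Mb; only the lowest class boundary is conventional,
so the bins are configurable.

**Group comparisons** use the nonparametric battery: Shapiro-Wilk (or KS)
per group, tie-corrected Kruskal-Wallis omnibus, and two-sided pairwise
Wilcoxon rank-sum tests with Bonferroni adjustment (adjusted p = raw p
times the number of pairs, capped at 1).

## Historical effective population size

LD between loci at recombination fraction c reflects N~e~ roughly 1/(2c)
generations ago. The pipeline computes r² as the squared Pearson
correlation of genotype-count vectors (the composite estimator — valid
without phase), within a breed, for intra-chromosomal pairs between 50 kb
and 4 Mb with MAF >= 0.05, then bins pairs by distance (30 equal-width bins
by default, spanning roughly t = 12 to 1,000 generations), adjusts for
sample size (r²_adj = r² - 1/(beta n), beta = 1 for unphased data), and
inverts E[r²_adj] = 1/(alpha + 4 N~e~ c) per bin:

    N_e(t) = (1/mean(r²_adj) - alpha) / (4 f(c)),   t = 1/(2 f(c))

with f the distance-to-recombination map (linear 1 cM/Mb by default;
Haldane and Sved-Feldman are exposed) and alpha = 2.2 (the
mutation-adjusted constant; 1 and 2 are exposed). Bins that cannot be
inverted (mean adjusted r² at or below the bound) are flagged invalid
rather than dropped.

Recovery is verified two ways: a closed-form check on synthetic bins built
to satisfy the drift equation exactly (recovering N~e~ = 100 to numerical
precision), and end-to-end forward simulations at constant N~e~ = 100 for
200 generations (2,000 SNPs over ten 5 Mb chromosomes, 100 animals). The
forward check aggregates the mean estimate over recent time points
(t <= 25, where 200 generations suffice for LD to equilibrate) and takes
the median across 10 seeds; single replicates fluctuate by tens of percent
because r² values within a chromosome share genealogy, which is why the
check is formulated on the aggregate. Deep-time points (large t, small c)
are systematically underestimated when the simulated epoch is shorter than
their equilibration time — visible in the declining-herd analysis script,
and a caveat that applies equally to real data whose deep history exceeds
the assumption of quasi-equilibrium.

## Composite selection signals

The scan contrasts a target breed against a pooled reference —
conventionally a fixed number of randomly drawn animals per non-target
breed; the draw takes a mandatory seed so the stochastic contrast is
reproducible. Three per-SNP statistics are combined:

* the single-SNP Weir-Cockerham two-population F~ST~;
* the allele-frequency difference (delta-SAF), target minus reference,
  entering the ranking as |delta| by default because the selected allele's
  identity is unknown a priori (signed mode exposed);
* XP-EHH: per population, EHH at distance x is the probability two random
  haplotypes are identical over all SNPs from the core out to x (computed
  by refining the haplotype partition outward); iHH is the trapezoidal
  integral of EHH over physical distance in both directions, truncated
  where EHH drops below 0.05, at an inter-SNP gap over 2 Mb, or at the
  chromosome end (the integral includes the first sub-cutoff point); the
  raw score ln(iHH_t/iHH_r) is normalised genome-wide to zero mean and
  unit variance. Phase is required; simulated data are natively phased,
  real chip data must be phased upstream, and a two-statistic combination
  (F~ST~ + delta-SAF, m = 2) is supported and labelled when phase is
  unavailable.

Each statistic is converted to an ascending fractional rank r' = rank/(n+1)
over its defined SNPs (average ranks for ties, keeping r' strictly inside
(0,1)), probit-transformed (z = qnorm(r')), averaged across the m
statistics available at the SNP, and re-expressed as
css_raw = -log10(1 - pnorm(z_bar sqrt(m))). The construction makes css_raw
invariant under any strictly monotone transform of an input statistic, and
calibrates it analytically: a SNP at the median rank of all constituents
scores -log10(0.5), and under no selection the fraction of SNPs above
-log10(0.001) is 0.001 up to binomial error. Smoothing averages css_raw
over SNPs within a 1 Mb window on the same chromosome.

**Peak calling** implements the flanking rule: a SNP in the genome-wide top
0.1% of scores is significant only if at least 5 distinct top-1% SNPs lie
within 0.5 Mb of it; significant SNPs within 1 Mb merge into regions
spanning their supporting SNPs. The flanking radius is a parameter (the
default matches the 1 Mb smoothing scale, i.e. half-window on each side),
as is the choice of smoothed versus raw scores. The default applies the
rule to smoothed scores; the simulation-based recovery checks apply it to
raw scores, for a reason worth recording: at the simulated marker density
(about one SNP per 40 kb, matching a 50k chip), 1 Mb smoothing makes
neighbouring scores strongly dependent, so the top-0.1% smoothed SNPs are
spatially clustered *by construction* and the flanking rule then flags a
"peak" in essentially every dataset, selected or neutral. On raw scores the
rule behaves as intended — neutral datasets are quiet (rank construction
makes extreme raw scores spatially exchangeable under neutrality) and a
hard sweep concentrates enough top-ranked SNPs to fire it. Users applying
the smoothed mode on dense panels should treat its output as descriptive
region-finding, not as a calibrated test.

Sweep recovery is verified on the forward simulator: 2,400 SNPs over twenty
5 Mb chromosomes (chip-like density), two populations of N~e~ = 400 split
one generation after founding, 45 generations, 50 animals sampled per side,
and a hard sweep (s = 0.2 from 5% standing frequency, shared-core founders)
in the target. Replicates are conditioned on the sweep exceeding 90%
frequency — the simulator reports losses and the driver re-draws seeds —
and the matched neutral arm uses the same configuration without selection.

Candidate-gene lookup intersects peak regions, extended by 1 Mb on each
side, with gene intervals read from GFF3 or BED (via rtracklayer; BED's
0-based half-open coordinates are converted on import). ROH overlap of peak
regions is reported as an annotation (how many distinct samples have a ROH
crossing the region), never as a filter.

## Pipeline and reproducibility

`run_pipeline` chains filter, PCA + F~ST~, inbreeding (F, ROH, F~ROH~,
length classes, group comparisons), per-breed N~e~, and — when a target
breed is set — the CSS scan. Every stage writes TSV; a JSON manifest
records the seed, every stage parameter including untouched defaults, and
per-stage row counts, so a run is reconstructible from manifest + inputs.
Identical config + seed yields byte-identical outputs. The numbered scripts
under `analysis/` are thin narrative drivers over the same functions, and
`scripts/acceptance.R` re-runs the recovery battery from scratch and writes
its headline numbers as JSON.

All problem sizes used by the checks (5,000-SNP panels for differentiation,
2,000-2,400-SNP forward simulations, 10-seed aggregates) were chosen as the
smallest sizes at which the quantities being recovered are statistically
stable; they are stated here so that anyone scaling the checks up or down
knows what was actually exercised.

## Known limitations

* PED/MAP allele orientation is recoverable only for alleles observed in
  the sample (inherent to the format); use BED/BIM where orientation
  matters.
* The N~e~ inversion assumes drift-recombination quasi-equilibrium; points
  whose time depth exceeds the population's (or simulation's) history are
  biased low, and no confidence intervals are attached.
* XP-EHH requires externally phased data for real panels; phasing error is
  not modelled.
* The smoothed-score peak rule is not calibrated at chip densities (see
  above); raw-score mode is the tested configuration.
* The simulators' idealisations (no genotyping error, no ascertainment
  bias, no gene flow) bound what the green checks prove about field data.
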
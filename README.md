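# strixpop

Population genomics of hybridizing owls: genotype filtering, kinship
screening, ZW sex-chromosome identification, diversity statistics,
diagnostic-panel hybrid classification, and a private-allele moment
estimator for very recent population split times.

## The problem

Western barred owls (WBO, *Strix varia*) were long assumed to have
colonized western North America within the last ~130 years, which would
leave them genetically indistinguishable from a subset of eastern barred
owls (EBO). Split times that recent are far below the resolution of
sequential-coalescent methods (PSMC/SMC++), so this package implements a
counting-based estimator that works directly from rare variation, plus
the surrounding cohort analyses: hard filtering of a joint call set
(including an excess-heterozygosity Hardy–Weinberg exact test on the
phred scale), KING-robust kinship to drop close relatives, read-depth
classification of Z/W scaffolds and sample sexes, nucleotide diversity /
Tajima's D / F<sub>ST</sub>, and fixed-difference panels that classify
spotted × barred owl hybrids (F1 vs backcross) and their maternal
lineage from mtDNA. A coalescent segment simulator (Rcpp) generates
cohorts with the same statistical structure, so the entire pipeline is
exercised end to end without any sequence downloads.

## The estimator

For 13 focal (WBO) and 12 reference (EBO) samples, form all 13 groups of
{1 focal + all 12 reference}. Within a group, a **private allele** of a
sample is an allele (reference *or* alternate) carried by that sample
and absent from the other 12 — counted 1 if heterozygous, 2 if
homozygous. The statistic is

&nbsp;&nbsp;R̄ = mean over groups of
C<sub>focal</sub> / mean(C<sub>reference</sub>),

which equals 1 under panmixia (label exchangeability, tested by
permutation; the exhaustive floor is 1/C(25,13) ≈ 1.9×10⁻⁷) and grows
with isolation time because mutations accumulating on focal-only
branches are visible only in the focal sample. Simulating the isolation
model over a grid of split times T (in 4N<sub>e</sub> generations)
yields an expected-ratio curve; the moment estimate T̂ is the linear
interpolation of that curve at the observed R̄, and
years = T̂ · 4N<sub>e</sub> · g with N<sub>e</sub> = π/(4μ). Counting
private homozygotes double makes R̄ — provably, and verifiably in the
test suite — insensitive to focal-population bottlenecks after the
split.

## Worked example

```r
library(strixpop)

# simulate 25 diploids under a two-population isolation model:
# split 0.0029 x 4Ne generations ago, Ne = 120,000, mu = 4.6e-9
m  <- demographic_model(T_split = 0.0029)
gm <- simulate_split_cohort(m, n_w = 13, n_e = 12, seed = 1,
                            n_segments = 10000)
des <- group_design(gm$samples$sample_id[1:13], gm$samples$sample_id[14:25])
r_obs <- ratio_statistic(private_allele_counts(gm, des))

curve <- expected_ratio_curve(m, T_grid = seq(0, 0.006, 0.001),
                              n_replicates = 15, seed = 7,
                              n_segments = 2000)
T_hat <- estimate_split_time(r_obs, curve)
yrs   <- split_time_to_years(T_hat, Ne = 120000, gen_time = 5)
c(r_obs = r_obs, T_hat = T_hat, years = yrs$years)
```

On the synthetic study cohort this workflow prints (from
`analysis/07_split_time.R`):

```
observed mean focal/reference ratio: 1.1020 (10.2% excess)
permutation test vs panmixia: p = 0.001996 (monte_carlo, 5,200,300 assignments possible)
T_hat = 0.0023 x 4Ne generations -> 5,458 years (rounded 5,000; 5-fold band 1092-27288)
(cohort simulated at a true split of ~0.0029 x 4Ne generations)
```

i.e. the focal samples carry ~10% more private alleles than the
reference average, panmixia is rejected at the resolution of the
Monte-Carlo permutations, and the inverted ratio curve dates the split
within the Monte-Carlo error of the simulated truth (the 20-Mb analysis
genome is deliberately small; precision grows with genome size). The
companion diversity stage prints per-population π of 1.4×10⁻⁴ (spotted
owls) and 2.3×10⁻³ (barred owls) and a between-species divergence of
0.70%, the calibration targets of the generator.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
data, writing tables to `results/`:

1. `01_simulate_cohort.R` — 36-sample four-population cohort + 3 F1s +
   2 backcrosses; VCF, metadata, depth table, mtDNA FASTA
2. `02_filter_genotypes.R` — GQ masking and site filters, attrition report
3. `03_genome_partition.R` — autosome/Z/W classes and sex calls
4. `04_kinship.R` — within-species kinship screen and exclusions
5. `05_popstats.R` — π, S, Tajima's D, F<sub>ST</sub>, LD-pruned PCA
6. `06_hybrids.R` — diagnostic panels, hybrid classes, mtDNA lineages
7. `07_split_time.R` — private alleles, permutation test, ratio curve,
   split-time estimate in years

Run them in order with `Rscript analysis/01_simulate_cohort.R` etc.
The methods vignette (`vignettes/strixpop-methods.Rmd`) documents the
models, defaults and design choices.

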
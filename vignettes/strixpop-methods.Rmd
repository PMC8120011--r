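---
title: "Methods: private-allele split-time estimation and cohort analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: private-allele split-time estimation and cohort analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`strixpop` implements the population-genomic workflow for a two-species,
four-population owl cohort — northern and California spotted owls
(NSO, CSO) and eastern and western barred owls (EBO, WBO) — from raw VCF
filtering through hybrid classification to the estimation of very recent
population split times from private alleles. This vignette is the
package's own account of the models, the defaults, and the choices made
where the design was genuinely open.

## The private-allele split-time estimator

Standard sequential-coalescent methods (PSMC/SMC++-style) cannot resolve
splits a few thousand years old or younger. The estimator implemented in
`private_allele_counts()` / `ratio_statistic()` /
`expected_ratio_curve()` / `estimate_split_time()` works from a simple
observation: in a group of one focal sample plus $r$ reference samples,
the number of alleles private to any one sample is proportional to the
expected length of the genealogy's branches that are ancestral only to
that sample, which in turn grows with the time the focal population has
been isolated from the reference population.

**Counting rule.** A private allele of sample $i$ within a group is an
allele — *either* reference or alternate; the orientation is
presence/absence, not minor/derived — carried by $i$ and absent from all
other group members: a heterozygous private allele counts 1, a
homozygous private allele counts 2. The factor 2 matters: for a diploid
whose two lineages coalesce at time $t_c$ inside an isolation period of
length $T$ generations, the private-branch weight is
$1 \cdot 2t_c + 2 \cdot (T - t_c) + \dots = 2T + \dots$, independent of
$t_c$. This is why the estimator is insensitive to post-split focal
demography (bottlenecks change $t_c$, not the weighted total), a
property the test suite verifies by simulation with a 20-fold
post-split bottleneck. Counting homozygotes double also keeps the
statistic robust to background inbreeding.

**Groups.** With 13 focal (WBO) and 12 reference (EBO) samples, all 13
groups of {1 WBO + all 12 EBO} are formed; the statistic is
$\bar R = \text{mean}_g\, C_{\text{focal}}(g) / \overline{C}_{\text{ref}}(g)$.
Under panmixia the labels are exchangeable and $E[\bar R] = 1$.

**Permutation test.** The null of panmixia is tested by reassigning
which 13 of the 25 samples are "focal", rebuilding all groups, and
recomputing $\bar R$. The number of distinct assignments is
$\binom{25}{13} = 5{,}200{,}300$, so the smallest attainable exhaustive
p-value is $1/\binom{25}{13} \approx 1.9\times10^{-7}$ — attained
exactly when the observed assignment is the unique extreme. Both an
exhaustive mode (guarded for small designs) and a Monte-Carlo mode with
the standard $(1 + k)/(1 + n)$ correction are provided; the Monte-Carlo
p-values are uniform under data simulated at split time zero
(Kolmogorov–Smirnov check in the suite).

**Moment estimation.** `expected_ratio_curve()` simulates the isolation
model over a grid of split times $T$ (in units of $4N_e$ generations),
records the mean ratio and a 95% CI of the mean per grid point, and
`estimate_split_time()` linearly interpolates the curve at the observed
$\bar R$. The curve is anchored at ratio 1 for $T = 0$ and is monotone
increasing; non-monotonicity around the crossing (possible with too few
replicates) is an error, not silently smoothed.

**Conversions.** Years $= \hat T \times 4 N_e \times g$ with
$N_e = \pi/(4\mu)$ from within-population diversity. Defaults:
$\pi_{\text{WBO}} = 2.15\times10^{-3}$,
$\mu = 4.6\times10^{-9}$/site/generation (collared-flycatcher rate),
$g = 5$ years, giving $N_e \approx 120{,}000$ (both candidate $\pi$
values, WBO-only and all-BO, round to within 10,000 of it; the WBO value
is the default and the choice is exposed). A multiplicative $k$-fold
uncertainty band (years$/k$, years$\times k$), default 5-fold, expresses
total parameter uncertainty.

## The coalescent generator

No structured-coalescent simulator exists in the R stack this package
builds on, and the generator is first-class here: it defines the
conditions under which every closed-loop test runs. `src/coalescent.cpp`
implements the standard backward-in-time structured coalescent for
independent, internally non-recombining segments, with population merges
and stepwise size changes, and infinite-sites mutations placed as
Poisson counts per branch ($\mu L$ per generation of branch length).

Defaults follow the analysis conditions: $N_e = 120{,}000$ diploids,
$\mu = 4.6\times10^{-9}$, 10-kb segments, 100,000 segments for a 1-Gb
genome equivalent (desk-scale runs use 1,500–10,000 segments; the
acceptance script uses 10,000 segments × 25 replicate genomes for the
ratio target and states so in its output). Intra-segment recombination
is omitted in the genealogies: expected private-allele counts depend
only on expected branch lengths, which recombination does not change;
the cost is larger between-replicate variance, absorbed by replication.
Recombination *is* honored where it matters — in the gamete-level
constructors `make_f1()` / `make_backcross()`, with crossovers per
segment per meiosis $\sim$ Poisson($\rho L$), $\rho = \mu$ by default.

The two-species cohort generator solves its sizes and times from
diversity targets: $\pi = 4N_e\mu$ within populations
($\pi_{SO} = 1.4\times10^{-4}$, $\pi_{BO} = 2.3\times10^{-3}$) and
$d = 2\mu t + \pi_{\text{anc}}$ between ($d = 0.7\%$, ancestral size =
the barred-owl size), with the EBO–WBO split at `T_split` (default
0.0029 × 4N~e~). The ancestral population size at each split is the
constant daughter size — the plain isolation model; there is no
post-split gene flow, no selection, and no mutation-spectrum realism.
Realized values at 10,000 segments: divergence 0.70%, BO π 2.31e-3,
SO π 1.4e-4, species-level Weir–Cockerham F~ST~ ≈ 0.78. What passing
closed-loop tests show is therefore internal consistency under this
idealized model, not robustness to artifacts real data carry (mapping
error, allele-specific bias, linked selection).

## Filtering

`apply_site_filters()` fixes the rule order: biallelic-SNP restriction →
hard annotation thresholds (QD < 2, FS > 60, MQ < 40, MQRankSum < −12.5,
ReadPosRankSum < −8, SOR > 3; a site lacking an annotation passes that
rule, the GATK convention) → total-depth cap at mean + 5 SD computed
over the sites still retained → Hardy–Weinberg filter. The attrition
report makes order effects visible; rerunning the filters on their own
output is a no-op except for the depth cap, whose mean/SD are
recomputed.

The HWE filter is the one-sided *excess-heterozygosity* conditional
exact test (Levene's distribution of the heterozygote count given the
allele counts), removed below $p = 3.4\times10^{-6}$, i.e. above phred
54.69 — the formulation consistent with a phred-scaled
variant-annotation filter, whose purpose is to catch collapsed paralogs
and similar artifacts that inflate heterozygosity. Whether the original
filter was one-sided is not documented anywhere we could rely on; the
two-sided variant is available behind `hwe_two_sided = TRUE`.

Genotype masking (GQ < 40 → missing) is separate from site filtering,
because the two interact differently with downstream statistics:
diversity statistics run on the masked matrix with per-site
non-missing allele counts (dropping incomplete sites first would
deflate per-base π by the attrition factor — the analysis scripts
demonstrate exactly this), while kinship, panels, F~ST~, PCA and
private-allele counting run on complete-data sites
(`drop_incomplete_sites()`), mirroring the usual practice. For
private-allele counting, a site with a missing call is skipped *for
that group only*, so groups may differ in usable sites.

With missing data Tajima's D uses the modal non-missing allele count for
its normalizing constants — an explicit approximation; run it on
complete-data matrices when exactness matters.

## Kinship

`pairwise_kinship()` is the robust within-cohort estimator
$\varphi = (N_{\text{het,het}} - 2N_{\text{opp,hom}})
/ (N_{\text{het},i} + N_{\text{het},j})$ over pairwise-complete sites,
with IBS0 $= N_{\text{opp,hom}}/n$. Expected values 0.5 / 0.25 / 0.125
for duplicates / first / second degree are recovered on gene-dropped
pedigrees in the suite; IBS0 separates parent–offspring (≈0) from full
siblings (>0). The first-degree band defaults to the conventional
$[2^{-5/2}, 2^{-3/2})$; the exclusion policy — keep the lowest sample id
per connected component of flagged pairs — is deterministic, replacing
any hand curation. The estimator assumes a homogeneous cohort: screen
within populations, not across the species boundary, and not on hybrid
genomes, where inflated $\varphi$ reflects admixture rather than
relatedness (the analysis scripts screen each species separately for
this reason).

## Sex chromosomes from depth

Birds are ZW: females carry one Z and one W. `classify_autosome_z()`
normalizes each sample by its median scaffold depth (two passes, the
second over provisional autosomes, so sex-linked scaffolds cannot drag
the baseline), then classifies the female/male depth ratio: Z in
[0.35, 0.65], autosome in [0.8, 1.2], otherwise unclassified — a
deliberate gap instead of forced calls, since the underlying claim is
only "about half". W scaffolds are those ≥ 100 kb with male missingness
above 0.99 in every male. `infer_sex()` calls a sample female when its
W marker shows > 0.1× autosome-median depth and its Z marker < 0.75×,
male in the opposite configuration, and unknown for contradictions.
Single-marker calls tolerate less scaffold-level depth noise than the
sex-averaged class calls: at a noise CV of 0.15 a male's Z-marker
relative depth crosses 0.75 a few percent of the time, so the
closed-loop guarantees are stated at CV 0.10 (classes, 16 samples per
sex) and CV 0.05 (sex calls); with real data prefer large marker
scaffolds or average several.

## Hybrid classification

Apparent fixed differences (complete data among panel-defining samples;
all of group A one homozygote, all of group B the opposite) are the
diagnostic panel; orientation (which allele is the A-species allele) is
recorded per site. The identity
$\text{frac}_A = (2n_{\text{hom}A} + n_{\text{het}})/(2n)$ holds exactly.
Classification thresholds are surrogates for by-eye calls on profiles
near 0%, ≈50%-all-heterozygous, and ≈25%: `pure_B` at frac_A ≤ 0.01,
`F1` at frac_het ≥ 0.95 with frac_A in [0.45, 0.55], `backcross_B` at
frac_A in [0.15, 0.40] with at most 1% A-homozygote sites — the band is
wider than the 24–32% seen in first backcrosses because whole-segment
inheritance makes the realized fraction fluctuate around 25% — and
`complex` otherwise. All thresholds are arguments.

For subspecies ancestry the NSO-vs-CSO panel is built with
`exclude_segregating_in =` the barred-owl samples, and the panel records
which allele barred owls carry; `subspecies_profile()` subtracts that
gamete, so an F1's spotted-owl-derived allele reads ~1 (NSO parent), ~0
(CSO parent) or ~0.5 (admixed SO parent) instead of being shifted by the
barred-owl background. Subspecies fixed differences are rare at small
genome fractions (the original ratio is roughly 773 : 2.5 million
relative to species differences), so desk-scale demonstrations deepen
the subspecies split; the default cohort keeps the calibrated shallow
one.

Mitochondrial assignment is nearest-cluster Hamming distance on an
aligned control region, with a margin rule (runner-up minus best < 3
sites → unknown). It presumes the caller supplies a correctly extracted,
single-copy region — control-region duplications must be resolved
upstream.

## Numerical and testing choices

Tolerances in the test suite are derived from the Monte-Carlo standard
errors of the quantities they bound (e.g. the closed-loop depth test
sizes its cohort so the class bands sit > 5 SD from the mean; ratio
assertions use ~3.5 SE bands). The split-time recovery check runs at
T* = 0.003 with a 7-point curve (25 replicates × 2,500 segments per
point) against 20 replicate 10,000-segment observed genomes, and asserts
recovery within ±15%. The exhaustive-permutation floor is checked on a
$\binom{7}{3}$ design where the extreme assignment is engineered, plus
the combinatorial identity for $\binom{25}{13}$. Sub-seeds are derived
from one master seed and all generators are bit-reproducible given it.

Known limitations, beyond those noted above: the infinite-sites
assumption ignores multiple hits (fine at $\mu L$ per branch ≪ 1, the
default regime); per-segment positions are drawn uniformly so duplicate
coordinates within a 10-kb segment are possible in very dense segments;
the Weir–Cockerham estimator degrades under strongly asymmetric sample
sizes (the Hudson form is provided for that case); and LD pruning is
greedy and windowed, so the retained set depends on site order, exactly
as in the standard tools it mirrors.
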
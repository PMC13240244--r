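---
title: "Methods: genotype-likelihood population structure and structural variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-likelihood population structure and structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcpopgen)
```

`lcpopgen` implements a complete population-genomic workflow for
low-coverage whole-genome resequencing (lcWGS, roughly 1-3x), where
individual genotypes cannot be called confidently and every analysis works
from genotype likelihoods (GLs) instead. The package covers quality
filtering, PCA and admixture, differentiation and isolation-by-distance,
windowed diversity, a PCA-based selection scan with candidate-region
calling, and local-PCA detection plus characterization of putative
chromosomal inversions. A seeded synthetic-data generator with a truth
ledger makes every step testable end to end.

## The data model

A `gl_dataset` holds an ordered marker table and a sites x individuals x 3
array of likelihoods `P(reads | g)` for `g` = 0, 1, 2 copies of the minor
allele, normalized to sum to one. A site-by-individual entry with an
exactly flat triplet is *missing* - this is how a depth-0 site behaves after
normalization, and the convention survives round trips through Beagle
files, whose scaling dialects differ (any positive rescaling of a triplet
is accepted on read). Genomic coordinates are 1-based inclusive everywhere
inside the package; only the BED reader/writer converts to the 0-based
half-open convention. Marker names of the form `chrom_pos` are split on the
*last* underscore so chromosome names may themselves contain underscores.

## The synthetic-data generator

`simulate_dataset()` draws, in order: marker positions (uniform per
chromosome), ancestral allele frequencies, deme frequencies by drift,
genotypes, and reads. All randomness flows from one master seed through
named sub-streams (`substream_seed`), so each stage is individually
reproducible.

**Ancestral frequencies.** By default Uniform(0.05, 0.5) - the floor keeps
most sites above a 5% MAF filter. In `neutral_sfs_mode` they instead follow
the neutral density proportional to $1/x$, truncated to
$[1/(2N), 1 - 1/(2N)]$ with $N$ = `pop_size` (default $10^4$), which makes
the expected Watterson and pairwise estimators agree and Tajima's D centre
near zero.

**Drift.** Demes are connected by a graph whose edges carry a drift
parameter $F \in (0, 0.5)$, interpreted as the *target pairwise Hudson*
$F_{ST}$ *across that edge*. Frequencies propagate over a breadth-first
spanning tree: the root deme keeps the ancestral values and each child is
drawn from a Balding-Nichols step,
$p_c \mid p_p \sim \mathrm{Beta}\!\big(p_p(1-c)/c,\,(1-p_p)(1-c)/c\big)$
with conditional drift $c = 2F$. The factor two is a deliberate
calibration: for Hudson's estimator the expected numerator across one edge
is $c\,\mathbb{E}[p(1-p)]$ while the expected denominator is
$2\,\mathbb{E}[p(1-p)]$, so the expected $F_{ST}$ equals exactly $c/2 = F$.
Conditional drifts compose along paths as $c_{12} = c_1 + c_2(1 - c_1)$,
which `expected_pairwise_fst()` uses to fill the truth ledger. The
consequence to keep in mind is that the *conditional variance* of a child
around its parent is $2F\,p(1-p)$, twice the edge label.

**Inversion polymorphism.** Inside a configured span two arrangements A/B
segregate; each individual's karyotype (0, 1, 2 copies of B) is drawn from
Hardy-Weinberg at its deme's inversion frequency. A configurable fraction
of in-span SNPs is divergent with $|p_A - p_B| = \delta$ (direction
randomized per site; $p_A$ uniform on $[0, 1-\delta]$); the rest share the
ancestral frequency. In-span genotypes are sums of two haplotypes drawn
from the carried arrangements - there is no recombination between
arrangements, which produces the three local-PCA clusters, the elevated
heterokaryotype heterozygosity and the internal LD that the detection
machinery looks for.

**Reads.** Depth is Poisson(`mean_depth`, default 1.5 - the lcWGS regime
this package targets; the per-site depth distribution beyond its centre is
a modelling choice). Alternate-read counts are binomial with success
probability $g/2\,(1-\varepsilon) + (1-g/2)\,\varepsilon$ and
$\varepsilon$ = `error_rate` (default 0.01, ordinary short-read scale);
likelihoods use the same binomial model, so the generator and the
downstream methods share one error model.

What the generator does *not* emulate: linked background LD from finite
recombination, coalescent ancestry, selection through time, mapping
artefacts, batch effects and reference bias. Tests passing on this
generator therefore validate the statistical machinery, not robustness to
those real-data complications.

## Quality filters

Site filters follow the standard lcWGS pipeline: minor-allele frequency
strictly above 0.05 (from the per-site EM estimator below), at least 75% of
individuals covered at 1x or more (a non-flat triplet), and mean depth at
most 10x when a depth sidecar is available (without one the depth rule is
skipped with a warning, since Beagle files carry no depth). The paralog
filter is a surrogate for read-level mismapping likelihoods, which need
pileups this package does not carry: sites whose maximum-posterior
genotypes show significantly more heterozygotes than Hardy-Weinberg expects
(one-sided exact binomial, Benjamini-Hochberg adjusted p < 0.001) are
removed. Sample filters: missingness above the cohort's 95th percentile
(an absolute cutoff can be supplied; both are reported), then duplicate
removal. The duplicate statistic deserves a note: a naive Pearson
correlation of posterior dosages is badly attenuated at 1.5x (a true
re-sequenced duplicate scores only ~0.5 once the shared prior mean is
removed, and the uncentred version is inflated to ~0.74 by between-site
frequency structure), so no fixed threshold separates duplicates from
relatives. `detect_duplicates()` therefore fits, per pair over at least
100 jointly non-missing sites, the maximum-likelihood identity
coefficient of a two-component site mixture - genotypes independent
Hardy-Weinberg draws versus one shared genotype - directly on the
likelihoods. That estimate is unattenuated: simulated 1.5x duplicates
score ~1.0, full sibs ~0.43 and unrelated pairs ~0, so the default
threshold of 0.9 flags exactly the re-sequenced copies. Filters
run sites first, then samples, then duplicates; missingness is computed
before any removal so dropping one sample never changes another's value.

## Allele frequencies, PCA and the selection scan

`estimate_maf_em()` maximizes the site likelihood
$\prod_i \sum_g GL_{ig}\,P(g \mid f)$ under Hardy-Weinberg by EM
(tolerance $10^{-6}$, at most 100 iterations), which is the `-doMaf`-style
estimator of GL pipelines. `posterior_dosage()` and `call_genotypes()`
derive expected and maximum-posterior genotypes under the same prior.

`pcangsd_fit()` is the iterative individual-allele-frequency PCA for
structured low-coverage samples: expected genotypes given per-individual
frequencies $\pi$, centering by $2f$, a rank-K SVD, and the update
$\pi = (\text{reconstruction} + 2f)/2$ truncated to
$[10^{-4}, 1-10^{-4}]$, iterated until the RMS change of $\pi$ drops below
$10^{-5}$ (at most 100 rounds; a raw Frobenius criterion would scale with
problem size, so the RMS form is used). An alternative update that
reconstructs the *standardized* matrix was evaluated and rejected: on
unstructured data it feeds sampling noise back into the prior, inflating
the leading eigenvalues several-fold and destroying the selection scan's
null calibration, while separating true demes worse. The final covariance
is $C = Z^\top Z / M$ over standardized expected genotypes
$Z = (e - 2f)/\sqrt{2f(1-f)}$.

The selection statistic of SNP $j$ on axis $k$ is
$s_{jk} = (z_j^\top u_k)^2/\lambda_k$ with $u_k, \lambda_k$ from $C$.
Because $\sum_j (z_j^\top u_k)^2 = M\lambda_k$, the statistic has mean
exactly one over SNPs, and under drift alone it follows $\chi^2(1)$;
p-values are its upper tail. Storey q-values estimate $\pi_0$ on the
0.05-0.95 lambda grid with a cubic smoothing spline (falling back to
$\pi_0 = 1$, plain Benjamini-Hochberg, whenever the estimate leaves
$(0,1]$), and SNPs with $q < 0.01$ are outliers. Candidate regions:
non-overlapping 1000-SNP windows with at least 10 outliers, merged when
separated by fewer than 10 windows. The default axis count comes from an
elbow (maximum-curvature) rule on the eigenvalues - a proxy for a visual
scree decision, with an explicit override.

LD is the squared Pearson correlation of posterior-mean dosages over
jointly non-missing individuals (at least 10), computed in compiled code
for all same-chromosome pairs within 200 kb. This dosage-correlation form
replaces an EM haplotype estimator; the analyses here only need relative
LD contrasts. Pruning greedily removes the site with the most pairs above
$r^2 = 0.075$ (ties: lower MAF, then later position) until no violating
pair remains.

## Admixture

`admix_em()` fits the standard GL admixture model
$h_{is} = \sum_k q_{ik} f_{sk}$, genotypes Binomial(2, h), by EM with the
published defaults (tolerance $10^{-5}$ on the log-likelihood increase,
at most 2000 iterations). F is initialized from the per-site MAF perturbed
by seeded Uniform(±0.05) and Q from a symmetric Dirichlet(1); the
log-likelihood is non-decreasing by construction and checked in tests.
Replicated runs (`run_replicates`, default 50 per K over K = 2..15) tag the
best-likelihood fit per K. Cluster-number estimators follow the
site-anchored counting scheme (MedMedK, MedMeanK, MaxMedK, MaxMeanK at
thresholds 0.5-0.8): a cluster counts when at least one sampling site's
mean (resp. median) membership reaches the threshold; fractional medians
round down. First-generation migrants are individuals with membership
strictly above 0.99 to a cluster other than their site's dominant one
(dominant = highest mean membership; the mean was chosen where the
convention is unstated) and are relabelled; individuals with maximum
membership below 0.8 are flagged as putatively admixed. Replicate
alignment across runs uses a greedy label permutation on membership
correlations, sufficient at the K used here.

## Differentiation and isolation by distance

Per-group allele frequencies are EM estimates with the *global* minor
allele counted in every group, so polarity is consistent and nothing is
re-folded per population (per-population folding would make the allele
frequency difference non-metric). Hudson's $F_{ST}$ uses the per-site
components $N = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$,
$D = p_1(1-p_2) + p_2(1-p_1)$ and the ratio-of-averages
$\sum N / \sum D$, the form least sensitive to uneven sample sizes. One
refinement matters at low coverage: the finite-sample correction assumes
$\hat p$ carries binomial noise from $n$ chromosomes, but EM frequencies
from shallow GLs are noisier. The correction therefore uses the *effective*
haploid size $n_\mathrm{eff} = \hat p(1-\hat p)\,\hat I$, with $\hat I$ the
observed Fisher information (negative curvature) of the site's frequency
log-likelihood; $n_\mathrm{eff}$ equals $2\times$ individuals-with-data for
hard genotypes and shrinks with depth. Without it, two demes simulated at
$F_{ST} = 0.05$ and sequenced at 2x measure near 0.060; with it, 0.047-0.048.
AFD is the mean absolute frequency difference with the same polarity;
isolation by distance correlates linearized $F_{ST}/(1-F_{ST})$ with
least-cost in-water distance (Dijkstra over water cells, 8-neighbour moves,
diagonal steps cost $\sqrt 2$ cells, land impassable, samples snapped to
the nearest water cell) via a one-tailed Mantel test with 9999 permutations
and the +1 correction. With few groups the Mantel p is bounded below by
1/(number of distinct permutations) - 1/24 for four groups - which is worth
remembering when reading small-panel IBD tests.

## Windowed diversity and heterozygosity

`pop_sfs()` subsamples 26 diploids per group (seeded, without replacement;
smaller groups are used whole with a warning, mirroring how an
undersampled site must be handled) and counts minor alleles among called
chromosomes from maximum-posterior genotypes. `window_thetas()` computes,
in 25 kb windows stepped by 5 kb with at least 1000 sites with data,
$\theta_W = S/a_1$, $\theta_\pi = \sum 2\hat p(1-\hat p)\,n/(n-1)$ (each
site's own chromosome count in the unbiased factor; the nominal subsample
size in the constants) and Tajima's D with the standard normalization. The
"per 1000 sites" scale divides by all sites with data in the window,
monomorphic included. Known limitation, documented rather than hidden:
hard calls at 1.5x shrink heterozygote counts toward the prior, deflating
$\theta_\pi$ by about 15% while leaving S nearly unbiased, so neutral
simulations measure a window mean D near -0.48 (truth 0; the true-genotype
oracle in the tests confirms the generator itself is neutral) and a
$\theta_W/\theta_\pi$ ratio near 1.15. Individual heterozygosity
(`individual_heterozygosity`) and the inversion heterozygosity contrast
(`region_het_test`) therefore default to the *posterior heterozygote
probability* summed over covered sites - the probabilistic analogue of
counting singleton sites in a one-individual SFS, and the estimator family
the original analyses used - with hard calls kept as an option; at 2x the
expected-het estimator recovers simulated heterozygosity within ~3%
versus a ~21% undercount for calls.

## Local PCA, MDS and inversion characterization

Local PCA runs on non-overlapping 100-SNP windows: standardized expected
genotypes (missing entries imputed at the site mean $2f$), the individual
covariance, and a rank-4 eigen reconstruction scaled to unit Frobenius
norm as the window summary. Window distances are Frobenius distances
between summaries - a metric by construction that captures "how different
are the leading four axes of relationship here". Classical (Torgerson)
scaling maps windows onto exactly five MDS axes (non-positive eigenvalues
zero-filled; signs fixed by making the largest-magnitude loading
positive). Per axis, windows beyond three genome-wide standard deviations
are outliers; outliers within 20 window indices merge, and clusters with
at least 10 outlier windows survive. The genome-wide (not per-chromosome)
mean/SD choice is configurable.

Karyotyping clusters region PC1 scores with k-means (k = 3, 50 restarts);
when any cluster has fewer than two members or the mean silhouette falls
below 0.3, the fallback re-clusters at k = 4..6 (best silhouette) and
merges the centers back into three groups by 1-D 3-means. Groups are
ordered along PC1: the middle is AB, the larger extreme AA. The LD block
test compares mean in-region $r^2$ (pairs subsampled to at most $10^5$)
against 1000 random same-length windows on the same chromosome (uniform
starts, windows overlapping the candidate excluded so the null stays
uncontaminated; each null window's mean uses up to 2000 subsampled pairs),
reporting a one-tailed Z-test. Boundary refinement declares a SNP tightly
linked to another when their $r^2$ exceeds the chromosome's 95th
percentile (estimated from a seeded subsample of banded pairs within
200 kb): within the cluster span padded by 25%, the refined start is the
SNP tightly linked to the most downstream SNPs (ties to the smallest
position) and the refined end the SNP tightly linked to the most upstream
SNPs (ties to the largest); a refined end at or before the start falls
back to the original span, flagged. The 200 kb cap means spans much longer
than 200 kb produce a count plateau whose argmax wanders - refinement is
reliable when the span is within the cap, which is why the validation
scenario uses a 150 kb inversion (the same scale as the smallest
characterized real inversions); region lengths are $(end - start)/1000$
kbp to one decimal, a convention validated against printed
boundary/length pairs. Karyotype frequencies per sampling site report the
AA/AB/BB fractions and the arrangement allele frequency
$(n_{AB} + 2n_{BB})/2n$.

## Annotation

Gene overlap is the zero-flank, any-overlap intersection of 1-based closed
intervals (a shared boundary base counts). GO enrichment is a per-term
hypergeometric upper tail with BH adjustment at 0.05; terms with fewer
than two universe genes are untestable and skipped. The gene-to-GO input
is assumed pre-propagated up the GO graph - no DAG propagation is
performed - and the default universe is all genes in the supplied
annotation.

## Validation scenarios and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` run the package at these desk-scale study
conditions, chosen once: two demes at edge F = 0.05, 50,000 SNPs, 30+30
diploids at 2x for $F_{ST}$ recovery; a panmictic 100-individual,
20,000-SNP run at 1.5x for scan calibration; twenty seeded replicates of a
three-deme, 20,000-SNP, 2 Mb chromosome with a 1500-SNP (150 kb) inversion
at $\delta = 0.8$, arrangement frequencies 0.2/0.4/0.6 and 30% divergent
sites for the inversion pipeline; a four-deme stepping stone on the
bundled synthetic lake raster with per-edge drift proportional to in-water
distance (0.0002 per km) for IBD; a 100,000-SNP neutral-SFS run for
diversity; and a 45+45+10 two-deme mixture at 5000 SNPs for admixture.
Boundary-refinement accuracy is scored per boundary against 10% of the
true length. The bundled fixtures (`inst/extdata`) are synthetic and
generated by seeded scripts: a 337-sample QC manifest with 28
high-missingness samples and 4 duplicates, and a 21 x 46 Arc-ASCII lake
raster with 5 km cells.

## Known limitations

Beyond the points above: the generator's free recombination outside
inversions means LD-decay-based threshold selection cannot be exercised;
the elbow rule is a crude stand-in for a visual scree test; EM admixture
can need its full 2000 iterations near convergence on weakly
differentiated data; and Hudson $F_{ST}$ between very shallowly sequenced,
weakly diverged demes retains a small downward residual after the
effective-size correction.
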
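---
title: "Methods: characterizing an autotetraploid breeding collection from SNP dosages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing an autotetraploid breeding collection from SNP dosages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrapop)
```

`tetrapop` implements the marker-based workflow a potato (or other
autotetraploid) breeding program runs over its clone bank: genotype quality
control, diversity statistics, population structure, selection-signature
scans, core-collection selection, and pedigree verification. This vignette
is the package's account of the models behind each stage, the parameters
that matter, and the choices made where the design was genuinely open.

## Dosage data and quality control

The universal input is a clones x markers matrix of B-allele dosages. An
autotetraploid genotype at a biallelic SNP falls in one of five classes —
nulliplex (AAAA, dosage 0), simplex (AAAB, 1), duplex (AABB, 2), triplex
(ABBB, 3), quadruplex (BBBB, 4). Dosage counts the array's B allele; the
orientation is fixed and documented because array manifests do not define an
ancestral allele.

`filter_markers()` removes markers in two stages: minor allele frequency
below `maf_min` (default 0.05; this also removes monomorphic markers), then
missing-call fraction at or above `max_missing` (default 0.10). The MAF
stage runs first, and a marker missing in exactly 10% of clones is removed
— "at least 10% no-calls" is treated as failure, not survival. Both
thresholds are arguments because array-QC conventions differ between labs.

`diploidize()` collapses the three heterozygous classes onto one code
(0/1/2 for AA/AB/BB), the transformation needed by diploid-only downstream
tools. It refuses already-diploid input rather than being idempotent, so an
accidental double application is caught instead of silently passing.

Ploidy is inferred per clone from the five-class frequencies: diploids
cannot produce simplex or triplex calls, so with
s = freq(simplex) + freq(triplex), `infer_ploidy()` calls diploid below
`tau_low = 0.05`, tetraploid above `tau_high = 0.20`, and ambiguous between.
The upper threshold operationalizes the published five-cluster rule; the
lower one quantifies "close to zero" and is exposed as an argument. For a
genuine tetraploid with allele frequency p the expected s is
4p(1-p)(p^2 + (1-p)^2 + 2p(1-p))-ish large — e.g. about 0.49 at p = 0.3 —
so the bands are far apart and the call is insensitive to the exact cutoffs.

## Diversity statistics

Per marker (allele counts pooled over clones, four alleles per tetraploid
clone): frequency p, MAF, expected heterozygosity He = 2p(1-p), and
Botstein's biallelic polymorphic information content
PIC = 1 - (p^2+q^2) - 2p^2q^2, bounded by 0.375. Per clone: observed
heterozygosity Ho (fraction of non-missing markers in the heterozygous
classes) and an inbreeding coefficient F = 1 - Ho / mean(He). That
definition of F was chosen because it reproduces, from the printed
collection means alone, all three published anchors of the original
analysis (maximum 0.44 at Ho = 0.22, mean -0.51 at Ho = 0.59, and values
near -1 for the most heterozygous clones); the snpReady formula it stands
in for is not published in closed form.

`sequence_diversity()` treats each clone's diploidized genotype as one
sequence over the assayed SNP positions (n = number of clones, not 2n
pseudo-haplotypes). Per site with m non-missing clones and allele frequency
p-hat from the 2m alleles, pairwise diversity is 2*p*(1-p) with the
small-sample factor 2m/(2m-1); the factor is switchable (`correction =
FALSE`) because the reference implementation's behavior on this point is
not documented. pi averages over all assayed sites, fixed sites included.
Watterson's theta is S/(a1 L) with a1 the harmonic number evaluated at the
harmonic mean across sites of the per-site sample size; the digamma
representation makes a1 continuous in that (generally non-integer)
effective n and exact at integers. This choice is the only one consistent
with a printed theta of 0.169 when all 10,106 retained sites segregate:
complete data at n = 214 gives 1/a1 = 0.1683, and missing calls can only
shrink the effective n. Tajima's D uses the textbook variance constants at
the same effective n and is reported as missing below S = 3.

On panels like this one D is large and positive (reconstruction from the
summary statistics gives about 4.2-4.3): an array of common, pre-filtered
SNPs carries an excess of intermediate-frequency variants relative to the
neutral spectrum, and population structure pushes the same way. The
`simulate_neutral_panel()` generator draws site counts from the 1/i neutral
spectrum as clone-level (homozygous) sequences; on such panels pi and theta
agree in expectation and D calibrates near zero, which the test suite
checks. Heterozygous pairing would instead calibrate pi against the
2n-allele harmonic number and shift D negative by construction — the reason
the calibration panel is built from sequences, not genotypes.

## Population structure

`nei_distance_matrix()` computes Nei's 1972 standard distance between
clones from within-clone allele frequencies (dosage/4), with loci missing
in either member of a pair excluded pairwise. Identical clones sit at
distance zero, which is what makes the matrix the substrate for duplicate
detection (default threshold 0.001). `ward_tree()` clusters it with the
classical Ward criterion on unsquared distances ("ward.D"); the squared
variant is available as an argument since the two dialects are frequently
confused.

Mislabel candidates come from cutting the tree at k = 3 groups and asking,
for each clone, whether its declared market class is essentially absent
from its own tree group (within-group fraction below 5%, or at most one
other same-class member, excluding the clone itself) while reaching at
least 10% representation in another group.
A plain majority rule was rejected: the structure groups are class
mixtures (reds/purples/yellows travel together, russets split between two
groups), so majority voting flags every legitimate minority-class clone,
and even a relative-representation rule flags whole shared classes. The
absence rule flags a lone russet-labeled clone sitting among the reds
without flagging the purples — or the other russets — that belong where
they are.

`kmeans_bic_scan()` selects the number of subpopulations: PCA of the
centered, mean-imputed, diploidized matrix, K-means on the retained
components (k-means++ seeding, 25 restarts, fixed seed) for K = 1..k_max,
and BIC(K) = n ln(WSS/n) + K ln(n) minimized with ties broken toward
smaller K. The BIC form is the standard spherical-Gaussian one; the cited
clustering approach names BIC without a formula, and this form reproduces
its elbow behavior. `dapc_fit()` then runs linear discriminant analysis on
the retained components, returning membership probabilities (Gaussian
posteriors in discriminant space; rows of Q sum to 1), at most groups - 1
discriminant axes, and per-marker loadings mapped back through the PCA
rotation. The guard n_pca < n - groups prevents the well-known DAPC
overfit. `dapc_crossval()` picks n_pca by stratified 90/10 cross-validation
minimizing the RMSE of holdout assignment error, ties to the smallest
n_pca. `snpzip_select()` splits one axis's absolute loadings into two Ward
groups and returns the high-loading group.

`pairwise_fst()` is a Weir-Cockerham-type moment estimator from group
allele counts (four per clone), combined across markers as a ratio of sums.
No polysomy-specific correction is applied — none is defined for the
published workflow either — and the estimator is checked in the tests
against Balding-Nichols panels at F = 0.02, 0.10 and 0.15, recovering F
within 0.03.

## Selection scans

`pca_outlier_scan()` regresses each standardized marker on K principal
components (K = 3 matches a scree inspection of a three-group collection),
takes the Mahalanobis distance of the K z-scores per marker (robust
covariance via `MASS::cov.rob`), rescales by the genomic inflation factor
lambda_GC = median(D2)/median(chi2_K), and converts to chi-squared
p-values. Optional greedy LD clumping (r2 > 0.2 within a 50-marker window)
thins the input before PC estimation. On unstructured null panels
lambda_GC calibrates to within 0.8-1.2.

The haplotype statistics work on phased binary panels. EHH at distance x
from a focal marker is the probability that two random carrier haplotypes
are identical over [focal, x], computed outward until it drops below 0.05
(the cited tool's default; the first sub-threshold point is kept) or the
chromosome ends; iES integrates the curve over physical distance by
trapezoids. `ihs_scan()` takes ln(iES_ancestral/iES_derived) per marker
with derived frequency in [0.05, 0.95], standardized within 20 equal-width
derived-frequency bins (bins with fewer than 10 scored markers merge with
neighbors); `xpehh_scan()` takes ln(iES_A/iES_B) over site-level EHH (no
allele split) within each population, standardized genome-wide, so swapping
populations negates every score. Two-sided normal p-values and Storey
q-values (smoother pi0 over a lambda grid; pi0 pinned to 1 below 100 tests,
where the smoother is unstable) finish both scans. For real array data the
B allele stands in for "derived" — arrays carry no ancestral-state
annotation — which leaves |iHS| interpretable but flips signs wherever the
proxy is wrong; simulations carry true polarity.

`consensus_sweeps()` implements the at-least-two-methods rule: markers
significant in two or more scans (iHS and XP-EHH at q < 0.01, the PCA scan
at q < 0.05) are clustered, strongest first, suppressing weaker qualifying
markers within 250 kb; each surviving top SNP defines the region top SNP
+/- 250 kb. Regions from distinct top SNPs are deliberately not merged even
when their 0.50 Mb intervals overlap, matching how neighboring sweep
regions are reported in practice. `genes_near()` then intersects a region,
extended 250 kb both ways, with the gene features of a GFF3 annotation
(closed intervals: a gene ending exactly on the boundary counts).

## Core selection

`select_core()` maximizes average entry-to-nearest-entry distance (E-NE) on
the precomputed Nei matrix — the default distance objective of
distance-based core samplers — at a 20% sampling fraction with
round-half-up sizing (0.20 x 214 = 42.8 selects 43). The search is
steepest-ascent over single swaps from 10 seeded random starts;
first-improvement search was tried and discarded because it stalls in
local optima that the exhaustive C(10,4) oracle exposes. E-NE punishes
redundancy directly, so duplicates are never jointly selected when the size
permits avoidance. In the pipeline, core selection runs after curation —
duplicates and mislabel candidates are removed first, duplicates dropping
the later-listed clone.

## Pedigree verification

`additive_matrix()` is the tabular method (A_ii = 1 + A_fm/2,
A_ij = (A_jf + A_jm)/2 in topological order, unknown parents contributing
zero), cross-checked in the tests against gene-dropping Monte Carlo.
`genomic_matrix()` is the dosage analogue of the VanRaden-style genomic
relationship: entries (x_i - 4p)(x_j - 4p) summed over shared markers,
normalized by the binomial variance sum 4p(1-p) restricted to the same
markers, with panel (not founder) allele frequencies — under that choice
the parent-offspring expectation is 0.5 on the same scale as A, which the
tests verify along with an A-on-G regression slope of 1 within 0.1. Panel
frequencies estimated from very small panels bias G downward by order 1/n;
the tests therefore embed trios in panels of ~100 clones, and users
verifying pedigrees should compute G on the full collection, not on
extracted trios.

`trio_conflict()` restricts to markers where both parents are monomorphic
(dosage 0 or 4) — the only markers where Mendelian inheritance fixes the
offspring exactly: 0x0 forces nulliplex, 4x4 quadruplex, 0x4 duplex.
"Conflict" means differing from that forced dosage, not merely from the
parents, which is what makes the 0x4-duplex case non-conflicting. Markers
with any missing call in the trio are excluded rather than imputed. Trios
under 1% conflict are labeled accurate (stray genotyping error), a
configurable threshold; truly wrong parents produce conflict rates an
order of magnitude higher. `single_parent_check()` covers the
one-parent-genotyped case: the putative parent must sit in the parent band
(G at least 0.5 - tau, tau = 0.15) and above every unrelated clone's G;
without pedigree context "unrelated" means outside the band, so a second
true parent in the panel cannot veto the verdict. The opposing-homozygote
rate (parent nulliplex, offspring quadruplex, or vice versa — impossible
under parentage) is reported alongside as the Mendelian smoking gun.

## The synthetic generator: what it emulates and what it does not

`simulate_structured_population()` is a Balding-Nichols model: ancestral
frequencies uniform on the post-QC MAF band [0.05, 0.5], subpopulation
frequencies Beta-distributed around them at the configured F, dosages
Binomial(4, p_k). Defaults emulate the study conditions: 214 clones in
three subpopulations sized like the collection's structure groups
(100/18/96), ~10,000 markers on 12 chromosomes, 5% missing calls, market
classes drawn from group-specific pools, and injected anomalies (2
duplicates, 5 mislabels, 1 diploid clone) mirroring the curation findings.
`simulate_cross()` draws gametes by random bivalent chromatid segregation
(hypergeometric, no double reduction — potato's double-reduction rates are
low and the flag is reserved); its offspring satisfy the trio-conflict
identity exactly, by arithmetic rather than by tolerance.

`simulate_sweep_panel()` creates EHH contrast by a copying construction,
not a coalescent: carriers copy one founder haplotype outward from the
sweep locus, switching back to the background with probability
(1 - homogeneity)(1 - exp(-d/decay)) at distance d, so the shared tract
decays smoothly; the derived allele marks carriers at the locus. Defaults
— 100 haplotypes, 2,000 markers on a 100 Mb chromosome (50 kb spacing,
close to the real array's 71 kb mean), carrier frequency 0.8, homogeneity
0.9, decay 50 kb — put the focal SNP's |z| in the chromosome-wide top 1%
with high power while leaving most of the chromosome neutral. Background
markers get MAF U(0.05, 0.5) with random derived-allele polarity so the
full derived-frequency spectrum, including the high bins where a sweep
lands, is populated with neutral markers; without that, frequency-bin
standardization would compare the sweep only against its own shadow.
Markers are independent outside the sweep window — there is no background
LD — so the iHS frequency-bin variances are narrower than on real data and
scan power here is an upper bound, not a forecast. Passing tests on these
panels demonstrate correctness of the statistics and calibrated behavior
under the stated models; they do not certify power on real breeding panels
with LD, genotyping error, and uneven marker density.

## Numerical choices and problem sizes

Ties in the BIC scan go to smaller K; ties in cross-validation to fewer
PCs; k-means uses 25 restarts under one seed. All generators require an
explicit seed and are pure functions of it. Distances that come out at
-1e-16 from floating-point cancellation are clamped to zero before the
zero-diagonal check. The test suite exercises the estimators at 200 clones
x 2,000 markers (structure, Fst, lambda_GC), 20 sweep replicates for scan
power, and exhaustively enumerable instances (at most 8 sequences, 16
haplotypes, C(10,4) subsets) for the oracle comparisons — sizes chosen so
the whole suite documents the package's behavior in minutes while the
statistical tolerances (Fst within 0.03, slope within 0.1, power at least
0.8) stay meaningful.
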
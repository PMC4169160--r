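---
title: "From a GBS lane to a QTL in an outcrossed F1: models and methods"
author: "gbsCrossMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a GBS lane to a QTL in an outcrossed F1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsCrossMap)
```

# The mapping problem

Highly heterozygous, self-incompatible crops (apple, grape, many forest
trees) cannot be mapped through inbred line crosses. Instead one crosses two
heterozygous parents and maps in the F1 — the *double pseudo-testcross*.
Only three parental genotype combinations at a SNP are informative:

* heterozygous × homozygous (`ABxAA`): the marker segregates 1:1 in the F1
  and tracks the meioses of parent 1 only (a backcross-type, "BC" marker);
* homozygous × heterozygous (`AAxAB`): 1:1, tracks parent 2;
* heterozygous × heterozygous (`ABxAB`): 1:2:1, tracks both parents (an
  intercross-type, "IC" marker).

Each parent therefore has its own linkage map built from its BC markers, and
the shared IC markers are the bridges that merge the two into one composite
map. Genotyping-by-sequencing (GBS) supplies the markers: a two-enzyme
reduced-representation library (a rare-cutting enzyme such as HindIII plus a
frequent cutter such as MspI) concentrates reads onto a reproducible subset
of restriction fragments so that one sequencing lane genotypes a whole
96-plex plate.

The cost of GBS is sparsity. Read depth per sample-by-site cell is low and
extremely uneven, so the raw genotype matrix is mostly missing or
shallowly supported, and confident heterozygote calls need substantial
depth. The pipeline in this package makes that sparsity a first-class
object: filters are explicit, auditable and tested against a simulator that
reproduces the sparsity structure.

# The simulator: what it emulates, and what it does not

`simParams()` / `simulatePopulation()` draw an F1 population with phased
heterozygous parents. Crossovers are placed under a no-interference model:
per meiosis, the crossover count on a chromosome of length $L$ cM is
Poisson($L/100$), breakpoint positions are uniform, and the transmitted
homolog flips at each breakpoint — so the recombination fraction between
loci $d$ cM apart is the Haldane value $r = (1 - e^{-2d/100})/2$. Map
*estimation* downstream uses the Kosambi function (the convention for plant
maps, and the one the pipeline reports); the deliberate mismatch between
generator and estimator is discussed under *Numerical behaviour* below.

Defaults mirror the design this pipeline was built around: 87 offspring
plus 2 parents, 17 chromosomes of 75 cM, a fully penetrant binary QTL
heterozygous in parent 2, and a marker-configuration mix of roughly
33% / 39% / 19% backcross-in-parent-1 / backcross-in-parent-2 / intercross
markers (plus 9% uninformative). The phenotype model is two-penetrance
Bernoulli on the QTL allele transmitted by the segregating parent —
the minimal model for an effectively Mendelian binary trait.

The observation model (`simulateGenotypes()`) is where GBS sparsity lives:

* per-sample scale factors are log-normal (sdlog 0.8 by default), so read
  totals across a plate span more than an order of magnitude;
* per-cell depth is negative-binomial (mean 3, size 0.3 by default) times
  the sample scale — shallow and overdispersed, leaving most cells with
  zero or near-zero depth, which reproduces the qualitative behaviour of
  real GBS matrices (most discovered SNPs unusable at stringent missingness
  thresholds). No published depth distribution was available to calibrate
  against, so these two knobs were set once to that qualitative target;
* given depth $d$ and true genotype, alternate-allele reads are binomial
  with an allele-sampling error rate (default 0.002), and the hard call is
  the maximum-likelihood genotype — so shallow heterozygotes are
  systematically miscalled as homozygotes, the dominant real error mode;
* `parentScale` multiplies the two parents' depth, emulating the common
  advice to sequence the parents of a mapping population deeper. The
  default (1) treats parents like any offspring.

`simulateReads()` emits the read layer: barcode + HindIII remnant `AGCTT` +
insert, with four artefact channels at calibrated rates — unreadable
barcodes (default 1.8%), corrupted remnants (1%), chimeric inserts carrying
one internal `AAGCTT`/`CCGG` junction (1.0%), and adapter read-through from
short fragments, `CCGG` + adapter (1.2%). Inserts are generated free of
internal full restriction sites, exactly as real digested fragments are —
chance sites would otherwise swamp the chimera channel. The simulator
records per sample which reads are assignable, so demultiplexing can be
audited read-for-read.

What the simulator does *not* emulate: reference-genome artefacts
(misassembly, paralogy, multi-mapping), position-dependent quality decay,
PCR duplicates, and allele-specific bias. Tests passing on simulated data
therefore validate the statistical machinery, not robustness to
reference-induced structure in real data.

# Filtering the sparse matrix

`loadVCF()` restricts to biallelic SNPs. `maskByDepth()` sets calls with
fewer than `minDP` supporting reads (default 6) to missing — a hard floor
on genotype confidence chosen as a quality/quantity trade-off.
`filterMarkers()` then applies a minor-allele-frequency floor (default
0.2; in an F1 the informative segregation patterns all imply MAF ≥ 0.25,
so this removes monomorphic and artefact-ridden sites) and a missingness
ceiling (default 20% per marker, computed over all samples). The MAF
denominator is called genotypes only, so missingness does not bias the
frequency; MAF is evaluated after depth masking (both orders are
available, the default reflects that masked cells are not genotypes).
`sparsityProfile()` reproduces the three standard sparsity summaries (SNP
counts across missingness thresholds; genotype counts across depth; SNP
counts across the minimum-depth threshold at fixed missingness) for any
matrix.

# Segregation analysis

`classifyMarkers()` assigns each marker its parental configuration.
`mendelianMask()` removes offspring calls that are impossible given the
parental genotypes (for example a hom-alt offspring under `ABxAA`);
masking precedes the ratio test because masked cells change the test
counts. `segregationTest()` is the Pearson goodness-of-fit chi-squared
without continuity correction — classes {het, hom-matching-the-homozygous-
parent} against 1:1 for BC markers (the third class was already masked,
keeping the degrees of freedom coherent), and {hom-ref, het, hom-alt}
against 1:2:1 for IC markers — with markers dropped at $P <$ 0.01.
Markers with a missing parental call are unusable for mapping and are
dropped. At $n = 87$ the chi-squared approximation is good but not exact:
the finite-sample rejection rate of the nominal 1% test, computed by exact
enumeration of the binomial (1:1) and trinomial (1:2:1) counts, is close
to but not exactly 0.01, and the calibration tests assert against that
exact value rather than the nominal one.

# Two-point linkage and phase

All pair-class likelihoods derive from one enumeration: each parent
transmits one homolog at the first locus (probability 1/2 each) and
recombines with probability $r$ between the loci; phases say which homolog
carries which allele. Collecting terms gives, for any pair of marker
configurations and phase assignment,
$P(\text{class} \mid r) = \sum_K w_K\, r^K (1-r)^{K_{\max}-K}$
over joint genotype classes, with $K_{\max}$ the number of heterozygous
parents. BC×BC pairs within one parent have closed-form estimates
($\hat r$ = folded discordance fraction); pairs involving IC markers are
fitted by EM with the per-meiosis recombination indicators as hidden data.
Meioses uninformative for $r$ are enumerated alongside — this leaves the
observed likelihood untouched, and the EM fixed point coincides with the
informative-only maximum-likelihood estimate, which the test suite verifies
against a $10^{-4}$ grid search. BC pairs from *different* parents share no
meiosis: they are flagged uninformative (LOD 0) and never create grouping
edges; IC markers are what holds the composite map together.

For each pair every admissible phase combination is evaluated and the
best-likelihood phase retained, folding $\hat r$ into $[0, 0.5]$. Phases
are then propagated marker-by-marker over high-LOD edges
(`assignPhases()`), giving each marker a 0/1 phase per parent relative to
the group's reference homolog; `switchPhase()` exposes the equivalent
manual relabelling operation.

# Binning, grouping, ordering

Markers with identical offspring genotypes carry no mutual recombination
information; `binCosegregating()` collapses them, requiring identity only
where both are called with at least 20 jointly called offspring (strict
all-cell identity would be meaningless under 20% missingness), stratified
by parental configuration so markers of different types are never merged.
Binning uses greedy complete linkage in marker order — deterministic, and
checked against an independent oracle in the tests.

`groupMarkers()` forms linkage groups as connected components over edges
with LOD ≥ 6 and $\hat r \le 0.35$ (the `rMax` threshold is read as the
largest recombination fraction allowed for a grouping edge).

Ordering (`orderGroup()`) is a seriation problem solved in three stages:

1. *Initialisation*: one-dimensional weighted metric scaling (SMACOF-style
   majorization) of the LOD-weighted Kosambi distances, started from
   classical scaling of a shortest-path-completed distance matrix
   (completion is needed because different-parent BC pairs have no
   distance).
2. *Stress refinement*: windowed 2-opt segment reversals and short-segment
   relocations minimizing the weighted squared mismatch between fitted map
   distances and two-point distances.
3. *Multipoint polish*: single-marker relocations and windowed reversals
   accepted when they raise the multipoint likelihood — both parents'
   transmission chains evaluated by forward recursion after two
   Baum-Welch re-estimations of the adjacent recombination fractions.
   A misplaced marker forces spurious double crossovers, which pairwise
   statistics barely notice but the chain likelihood punishes strongly.

Groups of up to 8 markers skip the heuristics and are ordered by exhaustive
enumeration of all permutations, which provably attains the minimum sum of
adjacent recombination fractions (SARF). All tie-breaks are by marker id,
so ordering is deterministic.

Map positions come from *regression mapping*: weighted non-negative least
squares of the Kosambi pair distances on the inter-marker steps, using
pairs up to 6 order positions apart and LOD weights. Local pairs carry the
distance scale deliberately: long-range pairs are noisier, their folded
estimates are biased at large $r$, and the Kosambi transform of
Haldane-generated data under-measures long distances, so including them
shrinks the map (a ~25% shortfall in experiments, against ~10% with the
local window). The normal equations are assembled in closed form by
two-dimensional cumulative sums, so a position fit costs $O(n^2)$ and the
stress objective stays cheap inside the refinement loops.

`dropMisfits()` is the guard against markers that inflate the map: each
marker's *triangle excess* over its nearest informative anchors,
$d(l,m) + d(m,r) - d(l,r)$, is near zero for a well-fitting marker however
long its real gaps are, but grows with accumulated genotyping error;
terminal markers are judged by their terminal gap instead, since the
ordering tends to push error-ridden markers to the group ends. The default
threshold (15 cM) tolerates ordinary terminal gaps and the modest excess
produced by unresolvable local order noise.

With 87 offspring and sub-2-cM marker spacing, marker order below roughly
2–5 cM is statistically unresolvable — adjacent intervals then carry of the
order of one expected recombinant, so the likelihood cannot distinguish
nearby permutations, and any ordering algorithm will produce local swaps at
that scale. The recovery tests therefore measure inversions as a function
of the true separation rather than demanding a perfect order.

# QTL mapping

Two independent routes, which should (and in the tests do) agree:

* `singleMarkerScan()` — the case/control allelic association test:
  per marker, a 2×2 allele-by-phenotype table (two alleles per called
  genotype), Pearson chi-squared with one degree of freedom, Bonferroni
  family-wise control (`alpha`/number of testable markers).
* `genotypeProbs()` + `intervalScan()` — binary-trait interval mapping on
  the genetic map. The homolog transmitted by one parent is a two-state
  Markov chain along each group; transition probabilities between adjacent
  chain nodes are inverse-Kosambi of the cM gap; emissions come from the
  phase-aligned transmissions observed at that parent's informative
  markers (BC markers reveal the transmission directly, homozygous calls
  at IC markers reveal it too, heterozygous IC calls and missing cells are
  marginalized, and a small emission error — default 1% — absorbs residual
  genotyping error). The chain is defined on the union of marker positions
  and the query grid; because Kosambi recombination fractions are not
  exactly Markov-consistent, posteriors are defined relative to that node
  set, and the tests enumerate exactly the same node set in their
  brute-force oracle. At each grid position the phenotype is a
  two-penetrance Bernoulli mixture weighted by the transmission
  posteriors; penetrances are fitted by EM, and
  LOD $= \log_{10} L_1 - \log_{10} L_0$ against the single-penetrance
  null. The genome-wide threshold is the 95th percentile of the maximum
  LOD over 1000 seeded phenotype permutations (1000 and the 0.05 level
  being the conventional choices), and a 2-LOD support interval is
  reported around the peak. The scan runs per segregating parent; for a
  Mendelian trait inherited from one parent, that parent's scan carries
  the signal.

The EM-weighted Bernoulli mixture was chosen over logistic regression on
expected genotype because it is the likelihood the binary single-QTL
model actually specifies; with full penetrance and complete marker data
the peak LOD reduces to the closed form $n \log_{10} 2$ for a balanced 1:1
marker, which the tests assert.

# Numerical behaviour, tolerances, degenerate inputs

* EM for two-point $r$: tolerance $10^{-10}$ on successive estimates,
  capped at 200 iterations (batch) — agreement with a $10^{-4}$-step grid
  oracle is part of the acceptance suite. Pairs with fewer than 2 jointly
  called offspring return $\hat r$ undefined and LOD 0.
* Penetrance EM: parameters clamped to $[10^{-6}, 1-10^{-6}]$; constant
  phenotypes abort with an informative error.
* Kosambi/Haldane conversions round-trip to $10^{-9}$; the simulator
  generates under Haldane while the map is measured in Kosambi, which
  compresses long distances — with window-6 regression mapping the
  realized total length on simulations sits about 8–12% below the
  generated length at $n = 87$, well within the 15% band the recovery
  tests allow.
* Zero-length chromosomes, empty VCF bodies, markers with no informative
  pairs, and groups that fail to form all degrade to defined results
  (no recombinants, empty matrices, unlinked markers, an empty map) rather
  than errors.
* Every stochastic step takes an explicit seed; per-stage child seeds are
  derived with a fixed linear-congruential scramble kept below $2^{31}$.

# Problem sizes used by the test and acceptance suites

The packaged checks run at desk scale, chosen to finish in minutes while
keeping every estimator in its intended regime: demultiplexing audits use
$10^5$ reads; filter oracles use 100 random 50×200 matrices; estimator
calibrations use 50 simulated pairs; full map recovery uses the complete
design (17 chromosomes × 50 simulated markers, 87 offspring) once, with
well-covered genotypes (negative-binomial mean 25, size 5, parents at 5×
depth) so that the mapping stage — not the depth filter — is what is being
tested; QTL-scan coverage uses 100 replicates of a 2-chromosome genome
scanned on the simulator's ground-truth map (`truthMap()`), so the
property measured is the scan's own 2-LOD coverage rather than the
compound of scan and map error; and null calibration draws 400 fresh null
phenotypes against one 1000-permutation threshold. The deeper-genotyping
scenario and the replicate counts are scenario choices of the test
design, documented here once; the simulator's own defaults (shallow,
sparse) remain the reference conditions for everything else.

Separating scan from map matters quantitatively: on the true map the
2-LOD support interval contains a fully penetrant planted QTL in
essentially every replicate (100/100 in our experiments), while with the
estimated map in the loop coverage drops to roughly 80–85% at $n = 87$ —
the intervals are narrow (median ~7 cM) and local map error of a few cM
shifts the coordinate frame. Support intervals on an estimated map should
therefore be read with the map's own local uncertainty in mind.

# Known limitations

* The two-point engine assumes biallelic SNPs and exactly two parents; no
  support for multi-parent or selfed designs.
* Ordering quality degrades gracefully but genuinely with marker density:
  below the ~2 cM information floor at $n = 87$, reported orders are one
  of many likelihood-equivalent permutations.
* The interval scan models a single QTL with no covariates; closely linked
  QTL will appear as one peak.
* Distorted markers are dropped, not modelled; segregation distortion that
  is biological (not artefactual) costs genome coverage.
* The pipeline treats alignment and variant calling as an external
  hand-off: it consumes whatever multi-sample VCF the caller provides and
  inherits its error modes.
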
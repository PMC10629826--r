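---
title: "Methods: barcode lineage tracking, fitness inference, and pleiotropy profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode lineage tracking, fitness inference, and pleiotropy profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiofit)
```

## The experimental design this package models

pleiofit analyses pooled competition ("bulk fitness assay", BFA)
experiments with double-barcoded budding-yeast lineages. Each lineage
carries two DNA tags read out by amplicon sequencing:

* a **lineage barcode** — a high-complexity random tag identifying the
  descendants of a single founding cell;
* an **environment barcode** — a low-complexity tag recording the
  evolution ("home") condition the lineage came from, which makes it
  possible to pool clones from many conditions into one assay.

A pool of evolved clones is mixed with its unadapted ancestor (typically
at a 9:1 or 4:1 ancestor:pool ratio), propagated by serial batch
transfer (about 8 generations per transfer), and sequenced at several
timepoints. The frequency trajectory of each barcode carries its
relative fitness; the ancestor-derived, putatively neutral lineages pin
the fitness zero.

## Fitness model

Let $f_i(t)$ be the read frequency of lineage $i$ at timepoint $t$.
Between two consecutive *valid* timepoints (both with at least 10 reads
for that lineage) separated by $\Delta g$ generations, the raw
per-generation log-slope is

$$m_{i,k} \;=\; \frac{\ln f_i(t_{k+1}) - \ln f_i(t_k)}{\Delta g_k}.$$

Raw slopes confound a lineage's own selection coefficient with the
rising mean fitness of the pool (and with batch effects of individual
timepoints). Both are removed by subtracting, at each timepoint pair,
the **median** slope of the neutral class:

$$\hat s_{i,k} \;=\; m_{i,k} - \operatorname{median}_{j \in \text{neutral}} m_{j,k}.$$

The per-replicate estimate $\hat s_i$ is the mean of the $\hat s_{i,k}$
over the lineage's valid pairs, with standard error
$\mathrm{sd}(\hat s_{i,k})/\sqrt{n}$ (missing when only one pair
contributes). Replicates are combined by inverse-variance weighting,

$$\hat s = \frac{\sum_r \hat s_r / \sigma_r^2}{\sum_r 1/\sigma_r^2},
\qquad \sigma^2 = \Big(\sum_r 1/\sigma_r^2\Big)^{-1}.$$

Replicates without a standard error are excluded from the weighting;
when no replicate has one, the unweighted mean is reported and flagged
(`method = "unweighted"`). Replicates whose scaled slopes are exactly
reproducible (zero standard error, which occurs in noise-free
validation runs) carry infinite weight, so the combined value is their
mean with zero standard error.

Because the median is subtracted per pair, the neutral class is centred
at zero by construction, and a handful of non-neutral contaminants in
the neutral set do not move the reference. In drug assays the neutral
(sensitive) lineages can go extinct; when fewer than 3 neutral lineages
are valid at a pair, the two lowest-total-count neutral lineages are
merged (their counts summed) repeatedly until at least 3 merged
lineages are valid. Pairs that still cannot field 3 valid neutral
lineages are marked unusable and excluded assay-wide — an estimate is
*missing*, never silently zero. We merge the two lowest-count lineages
first because that preserves the largest number of independent neutral
lineages; the merge order is not specified by the procedure itself.

All fitnesses are per generation (not per transfer cycle); generation
stamps are taken from the assay design (default 8 generations per
transfer, one transfer per timepoint).

## Barcode extraction

Reads are parsed with a fuzzy-flank regular expression: the barcode is
a 24–28 base run captured between `GGTACC` and `ATAACT` flanks, each
flank alternation tolerating one substitution (the right flank also one
deletion), searched in the barcode region plus 10 bases on either side.
The UMI of a read pair is the first 8 bases of read 1 plus the first 8
bases of read 2; inline library indices follow the UMI (their sequences
are assay-specific configuration, not something the method defines).
Read pairs whose mean Phred score over the extracted barcode regions is
below 30 are discarded (a mean of exactly 30 is kept); duplicate UMIs
are then removed within each library, keeping the first occurrence. We
filter on quality before UMI deduplication — the order is not dictated
by the procedure, but filtering first prevents a low-quality read from
shadowing a high-quality duplicate of the same molecule. By default
read 1 carries the lineage barcode and read 2 the environment barcode;
the assignment is configurable because the amplicon layout is a library
design choice.

## Error correction by deletion neighborhoods

Sequencing and PCR errors inflate the barcode list. Error correction
clusters observed barcodes by *deletion neighborhoods*: every barcode
contributes the set of strings obtained by deleting one base (plus the
barcode itself), and two barcodes are connected when their sets
overlap. Overlap indicates separation by about one edit (substitution,
insertion, or deletion). The set is self-inclusive by design: without
the barcode itself, the pure single-deletion sets of two strings of
different lengths can never intersect, so insertions/deletions would be
missed. A consequence is that some distance-2 pairs (e.g. adjacent
transpositions) also connect; this is harmless because final assignment
uses the true Levenshtein distance.

Within each connected component, barcodes are visited in descending
total count (lexicographic tie-break, for determinism) and accepted as
**peaks** when they (1) contain no `N`, (2) have no single-edit
neighbor with more total counts, (3) have more than 10 total counts,
and (4) are more than 3 edits from every already-accepted peak with
more total counts. Each non-peak corrects to a peak at Levenshtein
distance ≤ 3 (the higher-count peak when several qualify) or is
discarded; discarded counts are tallied, not redistributed, so reads
are conserved exactly. Count thresholds are evaluated on totals across
libraries. Environment and lineage barcodes are clustered separately —
the two classes have very different complexities.

Corrected (environment, lineage) combinations become **centroids**;
combinations with ≤ 10 total reads are dropped. Centroid tables from
different sequencing lanes are intersected (a barcode absent from any
lane is dropped, removing lane-specific contamination) and **chimeras**
— combinations sharing a lineage barcode, under a different environment
barcode, with a partner holding at least 100× more reads — are removed.

The Levenshtein kernel is a standard dynamic-programming edit distance
implemented in C++ with an early-abandon cap (distances above the
correction radius are never needed exactly); the test suite checks it
against `utils::adist` and checks the hashed neighborhood construction
against a naive all-pairs oracle.

## Quality filters

Amplification is biased against extremely AT-rich fragments, so
frequency measurements for such barcodes are unreliable. A lineage is
excluded when the minimum GC count over a 26 bp sliding window across
its barcode region falls below 4 (a minimum of exactly 4 is kept). The
barcode region is the concatenation of the environment and lineage
barcodes — the variable part of the amplicon where the bias arises.
Timepoints with pronounced residual bias (identified by eye from
neutral-class diagnostics in the original analyses) are excluded via an
explicit configuration table, which ships empty; the package supplies
the mechanism, not an automatic detector.

Home environments are assigned from sequencing of the per-environment
sub-pools: a barcode is assigned when it has at least 3 reads and
strictly more than 95% of them come from a single sub-pool; anything
else stays unassigned and is excluded from fitness and pleiotropy
outputs by default (carried with a flag).

## Mutation curation

Variant calling itself is out of scope — `filter_variants()` consumes
tables produced by external callers. The downstream filters:
mitochondrial variants and variants in *FLO1*/*FLO9* (chronically
misaligned) are dropped; clones with mean coverage below 10 (haploid)
or 15 (diploid) are dropped; variants in more than 12% of the clones
from one evolution condition are background, not de novo; variants with
quality below 150 are dropped unless whitelisted. Heterozygous variants
with ref:alt depth ratio above 3:1 are flagged as suspected
low-frequency contamination but kept for review. The original analyses
also involved manual BAM inspection; that human-in-the-loop curation
cannot be reproduced from rules, so it is represented by explicit
per-variant keep/drop override lists.

A gene is called an adaptive target in a condition when it acquired
distinct mutations in more than one lineage, the median home-condition
fitness of its carriers is positive, and at least one mutation is
coding; a pathway allowlist admits curated additions. The packaged
`adaptive_mutation_fixture()` table transcribes the curated
adaptive-mutation lists for the three focal conditions (clotrimazole,
fluconazole, glycerol/ethanol, haploid and diploid). Mutation classes
in the fixture follow the package's string dialect deterministically
(`X123Y` missense, `X123*` nonsense, `_fs` suffix frameshift,
`pos REF>ALT` non-coding, multi-residue strings in-frame in/dels,
start-codon changes counted as missense); per-cell totals are the
curated values, while a few per-class sub-splits differ from other
published splittings of the same lists, which are not internally
consistent under any single convention. Cross-condition deduplication
conventions differ as well, so the package reports per-condition
totals and does not define a global unique-mutation count.

## Pleiotropy profiles

A lineage's pleiotropic profile is its vector of fitness estimates
across assay environments. Effects are classified against measurement
noise: beneficial when $\hat s > k\,\sigma$, deleterious when
$\hat s < -k\,\sigma$, neutral otherwise, with $k = 2$ by default
(roughly a two-sided 95% envelope; $k$ is configurable, and a
fixed-cutoff mode is available for reproducing narrative thresholds
such as "fitness > 0.2"). Pleiotropy is *present* when any measured
non-home environment is non-neutral; adaptation is *cost-free* when the
home effect is beneficial and no measured non-home environment is
deleterious. Both calls are missing when no non-home environment was
measured — absence of data is never treated as neutrality.

Whether mutations in the same gene share pleiotropic profiles is tested
by permutation: the statistic is the mean within-gene pairwise profile
distance minus the mean between-gene distance (Euclidean over shared
measured environments; pairs sharing fewer than 3 environments are
skipped), and the null permutes gene labels across profiles within a
home environment. Distances are computed once and reused across
permutations. The one-sided p-value uses the add-one correction
$p = (1 + \#\{\text{null} \le \text{obs}\})/(B+1)$, so it is never
zero and is exactly $1/(B+1)$ in the fully separated limit. The
statistic itself is this package's construction — the underlying
observation ("same gene, similar profile") does not prescribe one — and
its type-I calibration is verified in the test suite.

## The synthetic-data generator

`simulate_pool()` provides the ground-truth channel that makes every
stage testable without external sequencing data. It realizes the model
the estimator assumes, plus the nuisance processes the pipeline must
remove:

* exponential selection dynamics per transfer,
  $f_i' \propto f_i e^{s_i \Delta g}$ (softmax update, so adding a
  constant to every $s$ changes nothing — only relative fitness is
  identifiable);
* a multinomial bottleneck of `bottleneck_size` cells at each transfer
  and multinomial read sampling of `read_depth` reads per timepoint.
  Both samplings are multinomial because serial dilution and library
  sampling are, to good approximation, sampling without replacement
  from a large pool;
* an ancestor spike-in: the neutral class collectively holds
  `spike_ratio/(spike_ratio+1)` of the initial pool (default 9:1);
* on the read level (`emit_reads()`): 8-base UMIs per mate, inline
  library indices, fixed construct context around each barcode matching
  the extraction flanks, iid per-base substitution errors applied once
  per molecule, UMI duplicates reusing the post-error sequence (PCR
  duplication after first-cycle errors is deliberately out of scope),
  and chimeras formed by re-pairing a molecule's environment barcode
  with another sampled molecule's — matching how chimeras present in
  real data as a lineage barcode shared across environment barcodes;
* an optional GC-content read-depth bias, a monotone multiplier
  $e^{\gamma(\text{GC}-0.5)}$ on sampling weights, renormalized per
  library.

Defaults follow the assay design: 8 generations per transfer, one
transfer between timepoints, 5 timepoints, 2 replicates, 26-base
barcodes, 9:1 spike. The sequenced interval per timepoint is a design
choice (the assays span roughly 40 generations overall); 5 timepoints
× 8 generations is the default grid. The default bottleneck is $10^5$
cells so that drift is visible at desk scale; validation runs in the
acceptance script use $10^7$, closer to the experiment's transfer
bottleneck of roughly $5\times10^7$ cells, with read depth $10^6$.
Barcodes are drawn uniformly over A/C/G/T; `N` bases never occur in
simulated reads and enter only through hand-built test inputs.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: realistic quality-score distributions
(all bases are emitted at Q40; the Q30 filter is exercised by
constructed reads), indel sequencing errors (substitutions only),
lineage-specific amplification biases beyond the GC model, ecological
interactions or frequency-dependent selection, and new mutations
arising during the assay itself.

## Numerical and degenerate-input choices

* Read counts are integers, but all downstream arithmetic is in
  doubles; frequencies use the post-filter library total at each
  timepoint, making estimates invariant to rescaling any timepoint's
  counts.
* A lineage with fewer than two valid consecutive timepoints has a
  missing fitness, and a single valid pair yields an estimate without a
  standard error — reported, excluded from inverse-variance weighting,
  and flagged.
* Equal-count barcodes in peak calling are processed in lexicographic
  order; since the "more total counts" criteria are strict, equal-count
  single-edit neighbors can both become peaks.
* Non-peak barcodes with no peak within 3 edits are discarded with
  their counts tallied; nothing is redistributed.
* `n_timepoints < 2`, empty neutral sets, empty barcode sequences,
  ambiguous index tables, and unknown exclusion-config or override keys
  are rejected with errors, not coerced.
* All randomness flows from explicit integer seeds; identical
  configuration and seed give byte-identical artifacts, which the
  pipeline manifest (file checksums, versions, parameters) makes
  auditable.

## Validation scale

The test suite and acceptance script size their simulations to run on a
single CPU in minutes while still leaving the statistical targets
non-trivial: fitness recovery uses 120 lineages (20 neutral), 5
timepoints, 2 replicates at depth $10^6$; error-correction recovery
uses 200 true barcodes with 50–5000 reads each at a per-base error rate
of 0.005 (about half a million reads); round-trip identity uses a
noise-free assay of 40 lineages at depth $3\times10^4$. These sizes are
the package's validation conditions, not limits of the implementation.

## Known limitations

* The fitness model assumes exponential dynamics between timepoints;
  strong frequency-dependence or ecological interactions would bias
  estimates in ways the generator cannot reveal.
* Error correction assumes true barcodes are well separated (random
  high-complexity tags); libraries with systematically similar barcodes
  would need the radius parameters revisited.
* The neutral-merging fallback trades variance for existence: merged
  references in antifungal-style assays are noisy, and absolute values
  there should be read with care even though rankings are robust.
* Mutation curation reproduces rule-based filters only; the manual
  curation layer is representable (overrides) but not derivable.
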
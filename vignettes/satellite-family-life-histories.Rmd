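---
title: "Methods: satellite DNA family life histories from short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite DNA family life histories from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Satellite DNA (satDNA) families are tandem arrays of a short monomer that
evolve by molecular drive: unequal crossing-over and gene conversion spread
variants through an array and, within a lineage, homogenize it (concerted
evolution).  Related species inherit a shared satDNA library from their
common ancestor; differential amplification, monomer mutation, and
higher-order repeat (HOR) formation then produce species-specific profiles.
`satfam` implements a desk-scale pipeline for reconstructing the life
history of one such family from shotgun reads or arrays: read clustering,
tandem-monomer detection, HOR decomposition, reconstruction of the
conserved ancestral monomer fragment, an alignment-free k-mer phylogeny of
the monomers, and a per-lineage classification into three evolutionary
modes — concerted with mutation/recombination only, concerted with a trend
toward longer and more complex units (HOR formation), and non-concerted
(suppressed homogenization, multidirectional divergence).

The package also contains the generator (`sim_config()`,
`evolve_library()`) that simulates these processes over a lineage tree and
provides ground truth for every claim the test-suite makes.

# The simulator and what it does (and does not) emulate

An array is an ordered list of monomer strings; flattening to one DNA
string happens only when reads are drawn.  Along each branch of a rooted
lineage tree, events are drawn from Poisson processes (counts at the
branch's rate x length; times uniform, i.e. a thinned Poisson process) and
applied in time order:

* **point mutation** (`point_mut_rate`, substitutions/site/unit time),
* **small indels** (`indel_rate`, events/site; geometric lengths, mean 1.5;
  per-monomer length change capped at ±20% of the ancestral length so
  monomers cannot degenerate),
* **unequal exchange** (`exchange_rate`, events/array): a contiguous run of
  monomers (geometric length, `exchange_run_mean`) is duplicated or
  deleted.  The choice is biased by a homeostatic term
  `p(dup) = t^2 / (t^2 + n^2)` around the target size `t`
  (`array_copies_target`), standing in for selection on array size;
  contraction never empties the array,
* **gene conversion** (`conversion_rate`, events/array): a tract of
  adjacent monomers (geometric, `conversion_run_mean`) is overwritten,
  monomer-by-monomer and position-aligned, from a donor region —
  nonreciprocal transfer, the main homogenizer,
* **HOR formation** (probability `hor_prob` per branch, optionally per
  branch label): a block of `hor_block_size` monomers is diversified
  (`hor_diversify` substitutions/site — units form from *modified*
  monomers) and then amplified as the new unit of repetition, with
  `hor_copy_noise` per-copy substitutions standing in for post-formation
  drift.  The event is applied at the end of its branch so later
  monomer-granularity homogenization does not scramble the freshly formed
  units; this is a deliberate simplification (after formation, the true
  unit of turnover becomes the HOR unit itself, which the event model does
  not track).

A leaf marked `non_concerted` has conversion and exchange scaled by
`suppression_factor` on its terminal branch, which is the package's model
of suppressed homogenization; no transposable-element biology is modeled.
Each species also carries `background_bp` of non-repetitive random
sequence so that a cluster's share of reads (its genome fraction) has a
meaningful denominator.

Reproducibility: one root seed; every branch (and every per-species read
draw) derives its own stream by hashing its label together with the root
seed, so per-branch results do not depend on traversal order.

**What passing tests do not show about real data:** reads are error-free
exact substrings (no sequencing-error model beyond an optional uniform
one), the background is uniform random rather than a real repeatome, and
arrays live on no chromosomes.  Detection performance on real reads will
be bounded by these idealizations.

## Study conditions frozen in the fixtures

`fixture()` provides the five named conditions used throughout the tests
and analysis scripts.  The uniform-array condition plants a 40-bp monomer
in 200 copies at 5% per-copy divergence (seed 1); the HOR worked example
plants a 117-bp unit of three 39-bp subrepeats at ~15% pairwise
inter-subrepeat and <5% inter-unit divergence, 35 units (seed 7); the
two-species condition embeds the 37-bp conserved ancestral fragment in a
40-bp monomer whose 3-bp species-specific spacer differs at the
core-adjacent bases, so the exact conserved core is recoverable by
construction (seed 3).  The seven-lineage tree has two sister-species
clades, two lineages with planted HOR formation besides one sister clade
member, and one early-branching suppressed lineage; its rates (mutation
0.05/site/unit, conversion 4000 events/array/unit with 30-monomer tracts,
exchange 20 events/array/unit, suppression factor 0.02, 300-monomer
arrays, 100 kb background, 250-bp reads at 0.8x) were chosen once so that
the concerted lineages stay internally >90% identical (reads must link at
the 90% clustering threshold), the suppressed lineage accumulates ~30%
intra-array divergence, and the planted family holds ~10% of each genome.
These are generator design choices, not estimates of any real genome; in
particular the suppression magnitude in the non-concerted lineage is a
free parameter of the simulation, not an inferred value.

# Clustering

All-vs-all comparison records a hit when the best local alignment (match
+1, mismatch −2, gap −3; either strand) exceeds 90% identity over at least
55% of the shorter read — identity is counted over all alignment columns.
Candidate pairs are restricted to reads sharing an exact 13-mer (either
strand); at these identity levels the prefilter loses almost no true hits,
and the suite checks >99% retention against an exhaustive run.  Clusters
are connected components with two or more reads (no community splitting:
family calls happen at component level); remaining reads are singlets.
Components come from `igraph`; an independent union-find oracle checks
them in the tests.  Contigs are greedy overlap-layout-consensus with a
twist for tandems: among qualifying placements (>=30 bp overlap, >=90%
identity) a read that *extends* the layout is preferred over an internal
placement, otherwise periodic reads all collapse onto one period.  Contigs
of tandem arrays can still be partially chimeric — variant combinations
that do not exist in the genome — and downstream stages treat them as
consensus material only.

At desk scale the published 0.01%-of-reads abundance cutoff admits chance
two-read clusters (0.01% of a few hundred is below one read), so the
pipeline keeps that cutoff for *reporting* but counts only clusters
holding at least 2% of the species' reads toward the multi-cluster
fragmentation signal used in classification (an "abundant" cluster at a
few hundred reads per species means roughly seven or more reads).

# Tandem detection

Candidate periods come from the recurrence distances of exact probe
k-mers (k = 5): support at distance d is the number of positions whose
k-mer reoccurs d bases downstream; candidates are local maxima exceeding a
binomial tail bound under the base-composition null.  For each candidate,
a consensus is refined by iterated wraparound alignment: cut the sequence
into period frames via the alignment, take per-column majorities (columns
present in under half the copies are dropped), realign, and stop at a
fixed point or after 10 iterations.  The wraparound dynamic programming
(match +2, mismatch −7, indel −7, the familiar tandem-repeat-finder
weights; all configurable) aligns the entire sequence against tandem
repetitions of the pattern with free phase at both ends; the in-row cyclic
dependency of the deletion move is resolved by sweeping each row to a
fixed point, which terminates because gaps cost.  The compiled
implementation is unbanded — at the package's contract sizes (<=100 kb)
banding buys nothing — and is checked against an independent plain-R
reference DP on small instances.  Percent matches and percent indels are
reported over all alignment columns against the consensus; copy number is
aligned length over period and may be fractional.

## Choosing the unit of duplication

A tandem array with a p-bp HOR unit of m diverged subrepeats also scores
well at p/m; conversely a uniform array scores equally at every multiple
of its monomer.  The unit choice starts from the smallest candidate and
promotes a larger candidate p over the current choice q if either

1. percent matches at p exceeds that at q by at least `margin` (10
   points), or
2. p is a near-integer multiple m of q and the mismatches are consistent
   with an m-frame unit: the per-frame mismatch profiles at period q
   correlate at lag m but not at lag 1 (`profile_margin`, default 0.5),
   *and* the p-consensus is genuinely built from diverged subrepeats — its
   internal frame identity at q sits at least `min_hor_gap` (3 points)
   below the inter-unit percent matches at p.

The second route is the package's operationalization of the qualitative
criterion that mismatches and indels must fit the longer monomer; the
extra divergence clause exists because harmonics of a uniform repeat score
as well as the fundamental.  The `profile_margin` value was calibrated on
simulated arrays: genuine HOR arrays (planted units, subrepeats 6–15%
diverged) show lag-m profile correlations of 0.7–1.0, while short contigs
of homogeneous arrays with local variant structure reach only ~0.3 —
mismatch recurrence there is block-like, not unit-periodic.  On an exact
repeat, profiles carry no mismatches and no promotion happens, so ties
break toward the shorter period.

One further safeguard operates at the pipeline level: before a family
cluster's long-period unit is proposed as a species-level HOR, it must be
reproduced in an independent assembly window (a contig built from half the
cluster's reads).  A single ~300-bp contig samples one locus of a
multi-kilobase array, and a recent local duplication of a few adjacent
monomer variants looks exactly like a young HOR in that window; a unit
that characterizes the species' array reappears in any window, a local
duplication almost never does.  Unconfirmed long units fall back to the
basic-period hit in the monomer table.

# HOR decomposition and inventory

`decompose_consensus()` scans subperiods p from 15 bp to half the
consensus length, keeping only p where the consensus length is a
near-integer multiple (one base of slack per subrepeat, accommodating
ragged units such as 118 = 3x39 + 1), cuts frames and returns the p
maximizing mean pairwise frame identity if it reaches 60%.  Family hits
whose consensus decomposes and whose unit exceeds 1.5x the reference
monomer length become proposed HOR units, deduplicated within species at
95% identity over canonical rotation/strand (cloned variants above ~95%
are treated as one unit; how the original study deduplicated its
"approximately 23" proposed units is unstated, so this count is not an
acceptance quantity).

# Ancestral fragment reconstruction

Monomers are circular: phase is arbitrary, so every monomer is doubled
(s+s truncated to 2L−1) before substring search and coordinates are
reported modulo the monomer length.  "100% similarity" is implemented as
exact string identity, with `min_len = 8` as the shortest fragment
distinguishable from chance among 40-bp monomers.  Pairwise maximal exact
shared substrings (both strands) between a reference species and every
other species are projected onto the reference monomer, positions
supported by every species are merged by run-length, and the longest
merged region that itself occurs exactly in at least one monomer of every
species is returned (ties: longest, then lexicographically smallest
canonical form).  This mirrors a pairwise-BLAST-then-combine procedure
rather than a multiple alignment, and it is combinatorial, not
probabilistic — no likelihood model of ancestral states is implied.  The
package ships the reconstructed 37-bp conserved fragment as the default
family reference for membership tests and tree rooting.

# k-mer phylogeny

Monomers are canonicalized (lexicographically smallest rotation over both
strands) and profiled as *distinct* k-mer sets, k = 9 by default — at
monomer lengths of ~40–400 bp a 9-mer rarely repeats within one monomer,
so presence/absence loses little; circular profiling appends the first
k−1 bases so rotation cannot change the profile.  The fractional common
k-mer count is F = |P1 ∩ P2| / min(|P1|, |P2|); the default distance is
1 − F, with −ln F provided as an alternative because the original
formulation leaves the transform open — neither form is claimed to
reproduce any published figure exactly.  Trees are minimum evolution:
neighbor-joining start, OLS branch lengths, NNI rearrangements
(`ape::fastme.ols`; taxon counts here are small enough for exhaustive NNI
passes), negative branches clamped to zero, rooted on the `ancestral`
leaf.

# Classification

Per lineage, three metrics feed a fixed rule: `non_concerted` iff the
family occupies at least `multi_cluster_min` (3) abundant clusters or the
homogenization index — mean pairwise monomer identity at the best
rotation/strand, sampled to at most 200 monomers — falls below `h_min`
(0.75); else `concerted_hor` iff at least one proposed HOR unit exists;
else `concerted_mutational`.  The thresholds are explicit stand-ins for a
qualitative published distinction, are configurable, and are recorded in
every classification's audit trail.  On simulations the index is computed
from the true monomer lists (the arrays are available); on real data it
comes from monomers cut from contigs at the detected period, which is
noisier.

# Numerical choices and degenerate inputs

Alignment identities are always counted over all alignment columns
including gaps.  Consensus ties break by fixed base order (A<C<G<T);
reported consensi use the canonical rotation.  `detect_tandem` returns an
empty table on sequences under 20 bp or without a qualifying candidate
period; contraction events keep at least one monomer; `wraparound_align`
refuses problems whose DP matrix would exceed ~6x10^7 cells (beyond the
package's contract).  The homogenization index refuses fewer than 10
monomers rather than returning a noisy value.  Reported problem sizes in
the analysis scripts (hundreds of reads per species, ~10 kb arrays) are
the package's chosen desk-scale study conditions.

# Known limitations

Genome-scale quantities (cluster counts and genome percentages of a real
repeatome) are out of reach of a desk-scale reimplementation and are
reproduced only qualitatively on simulations.  The clustering stage has no
mate-pair information and no graph-shape classification; the assembler is
a greedy layout, not a string graph; the simulator's HOR events freeze at
branch ends; and the classification thresholds, while calibrated on the
simulated regimes, have no claim of transferring to arbitrary real
genomes unadjusted.
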
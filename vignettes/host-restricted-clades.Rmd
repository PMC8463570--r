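---
title: "Host-restricted clades, null calibration and co-diversification tests"
author: "cophylorestrict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host-restricted clades, null calibration and co-diversification tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophylorestrict)
```

## The scientific problem

Wild great apes carry gut-bacterial lineages that are observed in only one
host species. Such *host-restricted* clades are often read as evidence of
co-diversification — parallel divergence of host and symbiont lineages. But
at least three other processes produce the same presence/absence pattern:
geographic isolation followed by within-host diversification after a host
switch, environmental or dietary filtering, and plain under-sampling. The
distance-based co-phylogenetic tests commonly used to certify
co-diversification (the Hommola correlation test, ParaFit, and PACo) react to
*any* association between symbiont relatedness and host identity, so data
rich in host-restricted clades can appear "co-diversifying" even against a
host phylogeny whose topology is random.

This package implements the full inference chain needed to make — and to
stress-test — such claims on binary ASV (amplicon sequence variant) incidence
data:

1. **Designation** of each ASV as host-restricted, mixed-host, or
   unique-to-captive, from its *wild profile*: the set of designation-relevant
   host groups (each wild-ape species, plus humans of either lifestyle) whose
   samples contain it. Captive-ape occurrences never alter the designation,
   because strains move freely between species in captivity.
2. **Maximal clade extraction** on a symbiont phylogeny: the largest
   monophyletic groups of same-category ASVs with bootstrap support above a
   threshold and presence in enough individuals.
3. **Null calibration** of clade sizes against a fixed-margins (curveball)
   permutation of the incidence matrix.
4. **Co-diversification statistics** (Hommola r, ParaFitGlobal, PACo m²)
   with their canonical permutation nulls, and a battery that re-runs all
   three against a randomized host phylogeny.
5. **Strain-sharing** among captive individuals (Sørenson index over
   presence sets) stratified by enclosure, zoo site and host species, with
   permutation t-tests.
6. A **synthetic-data generator** that plants known structure so every stage
   is testable end to end without external sequence data.

## Data model

The central container is `IncidenceExperiment`, a `SummarizedExperiment`
whose single assay `incidence` is a binary ASV × sample matrix and whose
`colData` carries `host_species`, `lifestyle`, `site`, `enclosure`, `study`.
Counts are binarized on construction (`value > 0`), matching the
presence/absence treatment required when amplicon and metagenome-derived
detections are merged: their abundances are not comparable, their detections
are. Validity enforces binary entries, no all-zero ASV rows, legal
host/lifestyle combinations, a site for every captive sample, and enclosures
nested within a single site.

Trees are plain `ape::phylo` objects — the interoperable standard — with two
package-level conventions checked by `readNewickTree()`: symbiont trees are
rooted with non-negative branch lengths and internal-node labels read as
bootstrap support; host trees are ultrametric divergence-time trees
(tolerance 1e-6 relative). Two support dialects occur in the wild, 0–100 and
0–1; when every numeric label is ≤ 1 the values are rescaled ×100, since all
thresholds are quoted on the 0–100 scale. A missing or non-numeric label
becomes `NA` and is treated as support 0 by the clade scan: an unsupported
node cannot anchor a clade. This is the conservative resolution of a
genuinely open convention question.

## The three-pass clade scan

`findMaximalClades()` makes three sequential greedy passes in the order the
categories are defined: host-restricted, then mixed-host on the remaining
tips, then unique-to-captive on what is left. Each pass walks the tree from
the root and accepts a node as soon as its (unconsumed) descendant tips
satisfy the pass predicate, the node's support exceeds `minSupport`
(strict `>`), and the members occur in at least `minIndividuals` distinct
samples; accepted subtrees are not descended, which is exactly maximality,
and their tips are invisible to later passes. Clades need an internal node
(≥ 2 tips): tips carry no bootstrap support, so single ASVs appear in the
classification table but never as clades.

Two documented interpretation choices: `n_individuals` counts distinct
samples of *any* group containing *any* member ASV (the source phrasing
"present in ≥ 5 individuals" does not restrict the group); and captive-only
tips are consumed by a mixed-host clade only when nested inside an accepted
pass-2 node — otherwise they remain available for pass 3.

The scan is verified against a brute-force oracle that evaluates the
predicate at every internal node and filters non-maximal candidates
explicitly; on hundreds of random trees the two agree exactly. One property
worth stating precisely: the *number* of accepted clades is not monotone in
`minSupport` — rejecting one maximal node can expose several supported
descendants. What is true, and tested, is that clades found under a stricter
support threshold nest within clades found under a looser one, and that the
host-restricted clade count is non-increasing in `minIndividuals`.

Defaults (`analysisConfig()`): support > 50 (0–100 scale), ≥ 5 individuals,
prominence threshold 0.25 (strict `>`, i.e. "present in more than 25% of the
individuals of at least one sample group"), 999 permutations.

## Fixed-margins calibration

Are host-restricted clades of the observed size surprising? The reference
distribution holds every ASV's prevalence and every sample's richness fixed
— a *fixed-fixed* binary null — and asks how large a host-restricted clade
can get by chance placement. The sampler is the curveball trade: pick two
rows, re-deal the symmetric difference of their presence columns at random
while keeping row totals. Margins are conserved exactly, by construction,
after any number of trades; the default `5 × nrow` trades is a standard
mixing heuristic (the source analysis names only a binary null "preserving
row and column frequencies", not an algorithm, so the sampler is this
package's choice). Uniformity over the reachable state space is tested by
enumeration on small matrices.

`cladeSizeNull()` re-runs classification plus the full clade scan on each
permuted matrix and reports, per observed host-restricted clade size `s`,
the add-one empirical p-value `(1 + #{permuted max ≥ s})/(1 + N)`. The
add-one form can never return 0 and has floor `1/(N+1)` — 0.001 at N = 999
— which is the attainable precision of the permutation design.

## Co-diversification tests and the randomized-host control

All three tests consume a host patristic matrix, a symbiont patristic
matrix, and a binary symbiont × host association matrix (built by
`buildAssociations()` from the designation groups). Taxa are aligned by
label throughout — note that some reference implementations align by
position instead.

* **Hommola** (`hommolaTest()`): Pearson correlation, over all unordered
  pairs of association links, between symbiont and host patristic distances;
  null = independent permutation of host and symbiont labels; large r =
  congruence. If either distance vector has zero variance the statistic is
  undefined; the result carries a degenerate flag and p = 1.
* **ParaFit** (`parafitGlobal()`): principal-coordinate embeddings B (hosts)
  and C (symbionts); ParaFitGlobal = ‖CᵀAB‖²_F; null = independent
  permutation of each symbiont's associations across hosts. Scaling all host
  branch lengths by c scales the statistic by c² (distances scale by c, so
  the embedding scales by c); p-values are scale-invariant.
* **PACo** (`pacoTest()`): one paired coordinate row per link; the symbiont
  configuration is Procrustes-superimposed onto the host configuration
  (translation, scaling, rotation — the asymmetric orientation, symbionts
  tracking hosts); m² is the residual sum of squares, small = congruent;
  null = re-drawing which host each link touches by permuting the host side
  of the link list. The residual is computed in closed form,
  m² = tr(XcᵀXc) − (Σσ)²/tr(YcᵀYc), and matches the standard Procrustes
  routine to 1e-10; it is invariant to rigid motion and global scaling of
  either configuration.

PCoA embeddings (`pcoaEmbed()`) keep all positive-eigenvalue axes; the
Cailliez additive correction is applied automatically when the smallest
eigenvalue falls below −1e−8 × the largest (patristic matrices need not be
Euclidean). Empirical p-values are add-one in the direction proper to each
statistic.

`hostRandomizationBattery()` runs the three tests against the true host tree
and against a randomization of it. The default randomization is a uniform
non-identity permutation of tip labels, which preserves the divergence-time
spectrum and isolates topology–label concordance; a Yule-style alternative
(random coalescent topology rescaled to the original root age) is offered as
a sensitivity mode. A test that stays significant under the randomized tree
is reacting to host-restriction itself, not to co-diversification.

## Sharing statistics

`pairwiseSharing()` computes the Sørenson index 2|A∩B|/(|A|+|B|) for every
unordered pair of captive samples and labels each pair `same_enclosure`,
`same_site_diff_enclosure`, `same_species_diff_site` or
`diff_species_diff_site`. Because the pair rows are not independent,
`pairSharingTests()` permutes *sample-level* identities — each sample is
dealt another sample's (species, site, enclosure) attributes and pair
relationships are recomputed — rather than permuting pair rows. Comparisons
that isolate the enclosure effect permute enclosure assignments within each
site (restricted permutations); the permutation scheme for the remaining
comparisons is the full captive set. Reported p-values are
Bonferroni-corrected across the family of comparisons.

## The synthetic-data generator

`simulateScenario()` plants known structure at three levels.

*Host tree*: the fixed hominid topology with divergence times (Myr) stored
in the configuration — chimpanzee–bonobo 1.8, human 6.4, gorilla 8.6,
orangutan 15.2 — consistent with commonly cited median estimates; they are
parameters, never hard-coded in logic.

*Symbiont tree*: `codiversification` mirrors the host topology
(`nCladesPerHost` backbone copies, like ancient duplicates), each host tip
subtending a shallow within-host radiation of `asvsPerClade` ASVs.
`host_switch` hangs the same radiations off a random backbone with the
generating host drawn independently of position. `filtering` assigns hosts
i.i.d. across the tips of a random tree. Depth choices model an order-level
amplicon phylogeny: radiations are strain-level (depth 0.05 substitution
units) while the host-switch backbone places lineages at deep, mutually
comparable distances (shallow internal structure of 0.1 plus pendant stems
of 0.45). The stems matter scientifically: between-lineage amplicon
distances in an order-level tree are near-saturated, and without that
saturation the replicate-to-replicate variance of all three test statistics
is dominated by the chance alignment of a few deep backbone blocks with the
five host labels rather than by the host-restriction signal the scenario is
meant to isolate. Bootstrap supports are simulated, not estimated — the
pipeline consumes supports, it does not infer trees: planted-radiation nodes
draw U[80, 100] and all other nodes U[0, 100] under the default `"high"`
setting.

*Incidence*: an ASV is present in each individual of its generating host
group with probability π (default 0.6, a realistic within-population
prevalence for prevalent gut strains), in other wild/human groups with
probability ε (default 0 — host restriction exact), and, under
`captive_mixing`, captive individuals carry human-origin ASVs with
probability ρ (default 0.8) and conspecific wild ASVs with probability
π(1−ρ). Groups have 20 individuals by default, matching the order of
magnitude of per-species sampling in the kind of survey this emulates.
All-zero ASVs are dropped with a warning rather than resampled, keeping the
draws i.i.d.-interpretable; `simulateScenario()` prunes them from the tree
and truth table consistently.

What the generator does *not* emulate: read counts and abundance structure,
sequencing error, correlated co-occurrence within enclosures (captive
presence draws are independent given the rates), unequal group sizes, and
phylogenetic signal in prevalence. Passing tests therefore demonstrate the
correctness and calibration of the inference machinery under known
generative conditions — not that any particular real dataset has these
properties.

## Numerical choices and degenerate inputs

* Empirical p-values are add-one in every test, hence never 0 and capped at 1.
* Zero-variance distance vectors (Hommola) and zero-spread symbiont
  configurations (PACo) are flagged degenerate with p = 1 rather than NaN.
* Non-finite statistics in permutation draws count as "at least as extreme"
  — a conservative tie rule.
* The pooled t statistic is defined as 0 when both the mean difference and
  the pooled spread vanish, and ±Inf when only the spread does.
* PCoA axes with eigenvalues below 1e−8 × the largest are discarded.
* All randomness flows through the session RNG; `set.seed()` (or
  `rngSeed` in `ScenarioConfig`) makes any pipeline run reproducible. This
  is the R idiom for the single-seedable-generator requirement.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use: 200 random trees of up to 32
tips for the clade-scan oracle; 10⁴ curveball permutations of 20 × 30
matrices plus 10⁴ draws on the 3 × 3 all-margins-one matrix; exhaustive
enumeration of all 36 relabelings of a 3 × 3 Hommola instance against 10⁴
Monte-Carlo permutations; a codiversification recovery run with 15 planted
clades × 4 ASVs over 100 samples with 199-permutation size calibration; and
20 replicates of the host-switch and filtering batteries at 999
permutations with 10 radiations per host. These sizes were chosen as the
smallest at which each property is sharply testable.
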
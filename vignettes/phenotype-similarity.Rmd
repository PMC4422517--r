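---
title: "Phenotype similarity, group closeness and gene discovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype similarity, group closeness and gene discovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclust)
```

# Overview

`phenoclust` quantifies phenotypic similarity between ontology-annotated
cases in a rare-disease collection and uses it three ways: testing
pre-defined case groups (pedigrees, suspected syndromes, variant
carriers) for unusual closeness, partitioning the cohort into phenotype
clusters, and ranking candidate genes by the closeness of their carrier
groups. This vignette records the model, its assumptions, the tunable
parameters, and the design decisions taken where more than one
reasonable reading existed.

# The similarity model

## Information content

For a collection of $n$ cases, each annotated with a set of ontology
terms, the frequency $p_t$ of a term $t$ is the proportion of cases
whose *ancestor-propagated* annotation set contains $t$ — a case
annotated with `thrombocytopenia` implicitly carries every ancestor up
to the root. The information content is $IC(t) = -\log p_t$, in natural
logarithm units (nats).

Two choices are deliberate:

* **Propagated counting.** Counting term-or-descendant occurrences
  guarantees $p_{\text{ancestor}} \ge p_{\text{descendant}}$, hence IC
  monotone non-decreasing from root to leaf and $IC = 0$ for any term
  covering the whole collection. Without propagation the
  most-informative-common-ancestor similarity below loses its
  interpretation (an ancestor could look rarer than its child). Whether
  the underlying method propagated is not documented anywhere we could
  rely on; we treat propagation as the only internally consistent
  option.
* **Collection-relative frequencies.** IC is computed from the cohort
  itself, not from external disease-annotation corpora. Rarity is
  therefore rarity *within this collection*, which is what makes shared
  rare terms between two cases informative about shared aetiology. The
  price is that IC values are not transferable between cohorts; the
  rank distance below removes that scale dependence where it matters.
* **Log base.** Natural log. Any base change multiplies all similarity
  values by a constant and cancels exactly in the rank distance (a
  property asserted by the test suite).

Terms annotated to no case have *undefined* IC; similarity queries on
them raise an error rather than imputing a value.

## Term and case similarity

Term similarity is the Resnik form: the IC of the most informative
common ancestor (MICA), with **reflexive** ancestor sets so that
$\mathrm{sim}(t,t) = IC(t)$. Reflexivity is an interpretation: the
conventional definition of the ancestor set ("the terms $y$ such that
$x$ *is-a* $y$") leaves self-membership unstated, but without it a
term's similarity to itself would be capped at its parent's IC, which
breaks both the self-similarity diagonal and the equality
$\mathrm{sim}(s,t) = \min(IC(s), IC(t))$ under ancestry. In
multi-rooted (sub-)ontologies, terms sharing no ancestor get similarity
0 with a warning.

Case similarity is the symmetric best-match average over the two term
sets; the self-similarity of a case is the mean IC of its terms.
Redundancy reduction (dropping a term that is a proper ancestor of
another term in the same case) is applied by default before similarity
computation: it cannot change best matches much — ancestors are
dominated — but it stabilises the $1/|D|$ normalisation against
annotation style.

## Rank distance and the Monte-Carlo group test

Raw similarity values depend on annotation depth and collection
composition. The rank distance replaces them with a count: for a pair
$(a,b)$, how many other cases $j$ satisfy
$\mathrm{sim}(D_i, D_j) \ge \mathrm{sim}(D_a, D_b)$ for each
$i \in \{a, b\}$, halved. Small distance = the pair is each other's
near-best match within the collection. A group's distance is the mean
over its pairs.

**Inequality direction.** The source material for this method prints
the rank indicator with $\le$, under which phenotypically tight pairs
would receive *large* distances and tight groups Monte-Carlo P values
near 1 — contradicting the accompanying description of a one-tail test
for distances *smaller* than chance and every reported small P value
for pedigree groups. We implement the only internally consistent
reading: $\ge$ in the rank indicator, $\le$ in the P value. This is
documented as a deliberate decision, not silently assumed intent.

The Monte-Carlo P for a group $Z$ is the fraction of `n_subsets`
(default 250,000) random subsets $W$ of size $|Z|$ with
$\mathrm{dist}(W) \le \mathrm{dist}(Z)$. Subsets are drawn from the
*index cases* in pipeline use — enrolled relatives share annotations
by construction and would distort the null — while $Z$ itself may
contain relatives. Subsets are drawn independently (duplicates across
draws allowed) and $Z$ is not excluded from the draw space. The plain
fraction may be exactly 0; a smoothed $(k+1)/(n+1)$ estimate is
available (`smoothed = TRUE`) but the plain fraction is the default.
P values of overlapping tests reuse the same similarity matrix and are
therefore weakly correlated; for groups small relative to the cohort
the correlation is negligible, and it is documented, not modelled.

Tied distances count as "at least as close" (non-strict inequality,
matched by a $10^{-9}$ floating-point tolerance; rank distances are
half-integers, so this tolerance cannot flip a genuine non-tie).

# Clustering and enrichment

PAM (k-medoids) runs on the dissimilarity $-\mathrm{sim}(D_a,D_b)$,
with the classic BUILD initialisation and best-improvement SWAP until
no single medoid exchange lowers the total cost. Ties break by case
order, so the algorithm is deterministic; `restarts > 0` adds seeded
random initialisations. Only index cases are clustered by default. The
number of clusters $k$ is a user parameter: there is no claim that any
particular published cluster count is recoverable, and
`silhouette_scan()` is provided as a transparent helper only.

Cluster labels come from two-sided Fisher exact tests of
(inside/outside cluster) × (has/lacks node) over every node present in
any propagated annotation set. The summary keeps the smallest-P node,
plus up to two more nodes with $P < 10^{-3}$ from *distinct lineages* —
operationalised as: no selected label is an ancestor or descendant
(reflexive) of an earlier one, so within a lineage only the most
significant node survives. "Two-sided" uses the standard
sum-of-probabilities-at-most-observed rule; the test suite checks it
against a full hypergeometric enumeration oracle. Carrier enrichment of
a cluster (`cluster_variant_enrichment`) is the same 2×2 machinery.

The leading-class association test (`class_association_chisq`)
compares the distribution of a set of feature terms inside a stratum
against all other cases by Pearson chi-squared without continuity
correction, Bonferroni-adjusted across strata.

# Variant triage

The six exclusion rules are predicates on one record: reference-cohort
allele frequency (strictly) above 0.1 %, non-protein-altering
consequence, segregation failure among sequenced affected relatives,
fewer than 3 alternate reads, in-house control allele count above 1,
cross-project allele count above 20. Thresholds are arguments with
these defaults. Conventions for missing data are conservative for
discovery: a missing reference frequency is treated as 0 (retain), a
missing read count fails rule 4 (a record with no read support is
uninterpretable), and a case with no sequenced relatives passes rule 3
vacuously. Each excluded record carries the first triggering rule id
and the full set. The per-cohort reference-frequency map is collapsed
to its maximum (`max_ref_af`), which is exactly equivalent under the
"any cohort" rule.

Inheritance-model grouping: autosomal dominant — any retained het/hom
variant; autosomal recessive — hom, or two distinct hets
(phase unknowable from a flat table; such cases are grouped but flagged
`phase_unverified`); X-linked — hemizygous males or homozygous
females. Only index cases form groups.

PV/LPV/VUS classification follows the curated-evidence scheme: PV =
known database variant with matched phenotype; LPV = novel variant in a
gene whose reported phenotype matches; everything else VUS; any PV/LPV
whose variant is also carried by a collection case with an *unmatched*
phenotype is demoted to VUS (all carriers together, with the demotion
recorded in the rationale trace). `phenotype_match` is a clinician /
curator input, never computed — an automated proxy would silently
change the meaning of the classification.

# The synthetic world

The simulator exists so that every claim the test suite makes is
checkable without patient data. Its defaults state one fixed world:

| Parameter | Default | Why |
|---|---|---|
| cohort size | 200 | large enough for stable rank distances, small enough for seconds-scale tests |
| terms/case | Poisson(7), truncated [1, 23] | echoes a reported real-cohort median of 7.5 terms (range 1–23) |
| ontology | 150 terms, 1 root, ≤ 2 parents | HPO-like shallow DAG at desk scale |
| background sampling | weight ∝ 1/(1 + #descendants) | real annotation favours specific terms over bare leading-class terms |
| planted group | 5 cases, 3-term core, 10 % dropout | a small pedigree/syndrome-scale group with imperfect annotation |
| planted gene | carriers = the planted group | the discovery target |
| background genes | 10, carrier rate 3 %, 30 % rule-violating records | gives the filter and the null scan work to do |

Planted groups receive their core minus independent dropouts plus
background noise; cores of different groups are drawn *disjointly* —
they model distinct syndromes, and overlapping cores would make a
"shared" term common to both groups, deflating its IC and blurring the
groups (this bit us in an early draft of the two-blob fixture). Truth
labels are emitted alongside the data and never consumed by analysis
code.

What the generator does **not** emulate: centre effects and annotation-
style heterogeneity, age- and gender-dependent term usage,
within-pedigree correlation beyond the shared core, linkage and
haplotype structure, sequencing error. A green end-to-end test
therefore establishes that the machinery recovers planted structure
under idealised annotation noise — not that it would on any particular
real cohort.

# Numerical choices and degenerate inputs

* IC and similarities in double precision; oracle agreement asserted to
  1e-12 on fixtures.
* Monte-Carlo comparisons use a 1e-9 tie tolerance (distances are
  half-integer means).
* PAM cost improvements must exceed 1e-12 to count, preventing tie
  cycling; identical rows are resolved by stable case order.
* Cases emptied by term filtering are dropped (with a warning) before
  similarity; `case_similarity` on an empty set is an error.
* A cluster equal to the whole cohort cannot be characterised (no
  outside group) and errors.
* Fisher's method returns 0 with a warning when an input P is exactly 0
  (below Monte-Carlo resolution).
* All randomness flows through a single seeded generator per call;
  callers' RNG state is saved and restored.

# Known limitations

* `similarity_matrix` is quadratic in cases with an R-level pair loop;
  fine to a few thousand cases, not for biobank scale.
* The Monte-Carlo test's draw space treats index cases as
  exchangeable; structured cohorts (strong centre effects) violate
  this, and the resulting P values inherit the distortion.
* Automatic lab-based annotation ships with platelet-count and
  mean-platelet-volume reference intervals only (100–400 ×10⁹/L,
  6–12 fL, strict inequalities); every other assay requires user
  configuration, and paediatric/pregnancy-specific intervals are the
  user's responsibility via `suggested` rules.
* The gender-specific term exclusion list is configuration, not code:
  which terms to exclude is a cohort-level curation decision.
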
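---
title: "Evaluating DNA barcode reference libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcode reference libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

# The problem

A DNA barcode reference library pairs short mitochondrial sequences
(classically a ~650 bp fragment of COI) with species labels. Its value
rests on the relationship between *intra-specific* variation (how far
conspecific barcodes diverge) and *inter-specific* divergence (how close
the nearest heterospecific sits). When the two ranges are disjoint — a
*barcoding gap* — a simple distance threshold identifies specimens and
delimits species; when they overlap, identification degrades in
criterion-specific ways and species boundaries must be inferred from
branching patterns instead. `barcodeval` implements both families of
analysis and a simulator that produces libraries with known truth, so
every stage can be validated end to end.

# Distances

All analyses build on the p-distance: the proportion of differing sites
among positions where *both* sequences carry an unambiguous base
(`A/C/G/T`). Gaps and IUPAC ambiguity codes are dropped per pair
(pairwise deletion), the convention of the distance software most barcode
studies use. A pair whose shared unambiguous overlap falls below
`min_overlap` (default 300 sites; 400/500/600 for sensitivity sweeps) is
*undefined* and excluded from every downstream summary. The engine
computes the full matrix with indicator-matrix cross-products, so
hundreds of sequences take well under a second.

Two conventions worth making explicit:

* **Percentile threshold.** The q-th percentile of pooled intra-specific
  distances (default q = 95) uses linear interpolation between order
  statistics (`stats::quantile` type 7), the most common definition;
  nearest-rank variants differ only at small sample sizes.
* **Inclusive thresholds.** All threshold comparisons ("within t") are
  inclusive (`<=`), with a relative `1e-9` guard because distances
  computed as `1 - matches/overlap` carry floating-point representation
  noise against literal thresholds such as `0.01`.

The *global* gap statistics summarise the overlap interval
`[min inter, max intra]`: its width, the fraction of all defined pairwise
distances inside it, and a gap flag (interval empty). A trimmed variant
discards the extreme 5% of each class before taking the interval; this is
offered as one plausible reading of the "90% overlap" statistic of
classic barcode-clustering software and is labelled an interpretation in
the output, since that statistic was never formally defined. The *local*
gap table compares, per species with at least two sequences, the furthest
conspecific against the nearest heterospecific — species with one
sequence have no intra-specific distance and are omitted rather than
zero-filled.

# Identification criteria

Every record is used once as a leave-one-out query (its own sequence is
excluded from the candidate set, otherwise every query trivially
self-matches). Distance ties are kept as a set — the *ambiguous* verdict
exists precisely for ties. The three distance-based criteria differ in
how demanding they are: *best match* looks only at the nearest (tied)
sequences; *best close match* additionally requires them within a
threshold, introducing *no match*; *all species barcodes* requires the
threshold neighbourhood to coincide exactly with the query's conspecific
set, so it fails (as *ambiguous*) whenever intra-specific variation
exceeds the threshold even without any heterospecific intrusion. This
ordering implies a nesting — success under the strictest criterion
implies success under the weaker ones at the same threshold — which the
test suite asserts on simulated libraries.

The tree-based criteria operate on any rooted tree whose tips are the
record ids (the pipeline builds an NJ tree from p-distances by default).
The strict criterion scores a species' queries successful only when the
species is monophyletic, misidentified when its sequences fall in more
than one cluster, and ambiguous for singletons. The relaxed criterion is
evaluated per query with the query's tip logically removed; the package
operationalises the published prose as: species with one or two
sequences → ambiguous; otherwise the verdict comes from the query's
sister group — all conspecific → success, none → misidentified, mixed →
ambiguous. "Cluster" means the smallest internal node satisfying the
membership condition; support values are ignored. Under this reading a
paraphyletic species whose members sit in conspecific sub-clusters is
fully recoverable by the relaxed criterion while the strict one marks all
its members misidentified — the qualitative contrast the two criteria
were designed to expose, and one the test suite reproduces on the
paraphyly preset.

Consensus barcodes use per-site majority with IUPAC codes for ties and
gaps when gaps dominate; the uniqueness check flags any two species whose
consensus sequences coincide.

# Threshold clustering

Clusters are the transitive closure of "some pair ≤ t": single linkage
cut at the threshold. This is the only linkage consistent with the
empirical observation that clusters can contain pairs *above* the
threshold (complete linkage could never violate); those *threshold
violations* are reported per cluster, with the violation percentage
computed over the number of clusters at that threshold. Taxonomic
accuracy is 100 × (# perfect clusters) / (# recognized species); the
denominator is configurable because the recognized-species count is an
external taxonomic fact, not a property of the sample. Undefined
distances are treated as non-edges with a warning. Cluster counts are
non-increasing in the threshold, which the sweep asserts.

# Single-threshold GMYC

The generalized mixed Yule coalescent model locates the age T* at which
branching on an ultrametric tree shifts from a between-species Yule
process to within-species coalescence. The likelihood is a
waiting-time product over inter-node intervals with total rate

$$b_i \;=\; \lambda_{\text{yule}}\, k_i \;+\;
\lambda_{\text{coal}} \sum_j n_{ij}(n_{ij}-1),$$

where \(k_i\) counts between-entity lineages (edges whose parent node is
older than T — entity stems therefore count in \(k\)) and \(n_{ij}\)
counts lineages inside entity \(j\). Intervals ending in a branching
event contribute \(\log b_i - b_i x_i\); the final interval contributes
its survival term; the root event is conditioned upon. The rate-scaling
exponents of the general model are fixed at 1 (linear in \(k\),
combinatorial in \(n\)), the common single-threshold default; they are
the only form the package fits.

Design choices that required a decision:

* **Candidates.** The likelihood changes only when T crosses a node age,
  so candidates are the node ages — specifically the *distinct* ages:
  average-linkage (UPGMA) trees routinely carry exactly tied ages, which
  are treated as one multi-event boundary with the appropriate
  multiplicity in the log-likelihood.
* **Null model and test.** The null is the same waiting-time likelihood
  with a single rate class over all lineages (\(b = \lambda k\), all
  edges between-entity). It coincides exactly with the
  everything-above-threshold candidate of the alternative, so the LR
  statistic is non-negative by construction, and pure-Yule trees are a
  true null for the test. The LR is referred to chi-square with 2
  degrees of freedom (threshold + second rate); mixture-type corrections
  exist but are not applied, and the package's calibration test shows
  the resulting test is, if anything, conservative on Yule trees
  (≥90% non-significant at α = 0.05 by construction of the suite).
* **Preprocessing.** Identical haplotypes are collapsed first
  (zero-length terminal branches carry no waiting-time information); the
  membership map re-expands entities to all sequences afterwards.
* **Partitions.** Fits run on the whole library (level A), per higher
  taxon (B), or per family (C). Groups with fewer than three unique
  haplotypes cannot be fitted and are carried as one entity each with a
  warning — mirroring how monospecific higher taxa are handled in
  practice. Externally dated ultrametric trees may be supplied per
  group; otherwise UPGMA trees stand in, which is adequate for the
  rate-shift signal at desk scale but is *not* a substitute for proper
  Bayesian dating on real data.

# The synthetic-data generator

The simulator composes three layers with a single seed:

1. **Species tree** — ultrametric, built by backward merging with
   waiting times `Exp((j−1)·birth_rate)` while j lineages remain, so a
   two-species tree has split age `~ Exp(birth_rate)`. Depth units are
   expected substitutions per site.
2. **Gene trees** — a Kingman coalescent per species
   (`Exp(choose(j,2)/coal_scale)`), grafted at the species tip;
   genealogies deeper than the terminal species branch are redrawn
   (bounded retries), i.e. coalescence is forced within the species
   branch and there is no deep coalescence across boundaries. Paraphyly
   is therefore *injected by label manipulation* (two non-sister clades
   share one species label), keeping the truth checkable.
3. **Sequences** — site-independent JC69 (default), K2P or HKY evolution
   from an equilibrium root sequence; under JC69 the expected p-distance
   at path length t is \((3/4)(1-e^{-4t/3})\), which the test suite
   checks against simulation within three standard errors.

Preset conditions (chosen once, stated here as the package's defaults):
sequence length 663 bp, K = 5 species with 4 individuals each,
`birth_rate = 5`, `coal_scale = 0.002`. The *clean_gap* preset demands
`min inter > gap_factor × max intra` with `gap_factor = 5` on the
realized distances — the operational form of "entity crown ages much
shallower than between-entity splits", which is what makes a gap *clean*
rather than merely present; generation retries with bounded sub-seeds
until the property holds and errors with diagnostics otherwise. The
*overlapping* preset raises `coal_scale` to 0.08 and the species-tree
rate to 20 so intra-specific variation overruns the shallowest splits.
These settings produce intra-specific distances up to roughly 1% and
intra-generic distances from a few percent upward — the divergence
structure typical of mitochondrial barcode libraries — though the
simulator deliberately omits rate heterogeneity across sites, codon
structure, saturation at deep divergences, and sequencing error. Passing
tests on these libraries therefore validate the *logic* of the
evaluation chain, not its behaviour under every real-data pathology.

# Problem sizes and determinism

The validation suite runs clean-gap recovery at K ∈ {3, 5, 8} species ×
20 seeds (threshold clustering at a mid-gap threshold and GMYC both
recover K entities with 100% taxonomic accuracy in at least 19 of 20),
and LR calibration on 50 thirty-tip Yule trees; these sizes give stable
pass/fail behaviour while keeping a full run to a few minutes on one
core. Every generator is deterministic under a fixed seed, and the
pipeline writes byte-identical report bundles on repeated runs with the
same configuration (the manifest records the configuration and seed, and
deliberately no timestamp).

# Known limitations

* The GMYC implementation fits the single-threshold model only; the
  multiple-threshold variant is deliberately out of scope (it is known
  to score worse on taxonomic accuracy).
* UPGMA ultrametric trees are a convenience stand-in; on real data the
  tree should come from proper dating software.
* The relaxed tree criterion's "sister group" reading is one
  operationalisation of published prose that leaves edge cases (e.g.
  a query sister to a mixed clade) to judgement; the package's choice is
  documented above and applied consistently.
* Ambiguity codes are excluded from base-frequency counts and treated as
  non-contradicting in conserved-site calls; alignments consisting
  mostly of ambiguity codes will yield fragile site statistics.
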
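---
title: "Taxonomically constrained OTU clustering for airborne fungal metabarcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Taxonomically constrained OTU clustering for airborne fungal metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporeclust)
library(dplyr)
```

## The problem

Air sampling with cyclone samplers followed by ITS2 metabarcoding yields
denoised amplicon sequence variants (ASVs). Because the ITS region carries
frequent intraspecific variation, ASVs are poor proxies for fungal species:
one species commonly produces several ASVs, and many airborne sequences
belong to taxa with no reference representation at all. `sporeclust`
implements the post-denoising stage of such a survey: it groups ASVs into
species-level operational taxonomic units (OTUs) under the guidance of
probabilistic taxonomic assignments, places every OTU in a seven-rank
taxonomy in which unattributable clusters receive `pseudo{rank}_{number}`
placeholders, screens out non-fungal material, converts spike-in read
ratios into semi-quantitative DNA amounts, and provides the validation
statistics used to assess such a dataset (depth filtering and rarefaction,
negative-control screening, classifier-vs-expert agreement summaries, and a
distance-weighted occurrence null model).

## The clustering model

Clustering proceeds rank by rank, phylum to species, and within each rank
in three stages inside every cluster of the rank above:

1. **Cluster cores.** ASVs assigned to a taxon at this rank with
   probability at least 0.90 seed one core per distinct taxon. Cores are
   never merged: confident but conflicting assignments always end up in
   different clusters, even when the sequences are similar.
2. **Closed-reference attachment.** Unassigned ASVs join the cluster of
   their closest clustered neighbour within the rank's threshold. The step
   iterates to a fixed point, and recruited members themselves act as
   attachment points in later iterations, so the result approximates
   single-linkage clusters that are not allowed to bridge two cores. All
   matches in one iteration are evaluated against the state at the start of
   the iteration and applied simultaneously, which makes the outcome
   independent of input order. Ties (an ASV equidistant to two clusters)
   go to the larger cluster, then to the lexicographically smaller label.
3. **De novo pseudotaxa.** Whatever remains is clustered by single linkage
   (connected components of the graph with edges at dissimilarity at most
   the threshold). Components become pseudotaxa, numbered zero-padded per
   rank in a deterministic order (parents by label, components by smallest
   member id).

Because stages at rank *r* operate inside rank *r−1* clusters, the
partition at each rank refines the one above by construction; two ASVs
confidently placed in different phyla can never share a pseudoclass, no
matter how similar their sequences are. Species-level clusters are the
final OTUs, each represented by its most abundant member ASV.

## Distances

The dissimilarity between two sequences is

> (mismatches + gap penalty × internal gap columns) / alignment columns,

computed on an optimal global alignment with terminal-gap columns excluded
from both numerator and denominator, so 0.0 means all overlapping bases
identical and 1.0 all bases different. Terminal gaps are *penalized during
alignment construction* (an ordinary Needleman–Wunsch with unit mismatch
cost and a uniform gap penalty, default 1) and *excluded during
evaluation*. Making terminal gaps free in the construction objective as
well would be degenerate — the empty, all-terminal-gap alignment then has
cost zero for every pair — while the penalize-then-exclude rule keeps the
optimization well posed and still gives dissimilarity 0 to sequences that
are identical except for end gaps. That consistency is what the end-gap
duplicate collapse relies on: merge classes are the connected components of
the "dissimilarity exactly 0" relation, with the most abundant member as
representative and read counts summed.

Among equally cheap alignments the implementation prefers more matches,
then fewer gap columns, with a fixed direction preference; because tied
optima can differ in how much of a gap run is terminal, symmetry is
guaranteed by canonicalizing the argument order before aligning. Pairs
whose dissimilarity exceeds 0.6 are omitted from the sparse matrix, and an
absent pair is interpreted as "farther than the cutoff" everywhere
downstream.

The k-mer prefilter (word length 8) is an admissible speedup only. The
shared-word fraction *F* between sequences at alignment divergence *d*
decays roughly like (1−d)^k, so a cutoff applied to the raw quantity
1−F would discard pairs that are only ~10% divergent. The prefilter
therefore applies its 0.4 cutoff on the calibrated scale 1 − F^(1/k),
which tracks the alignment divergence; near pairs are never skipped, and
every test that compares against the exhaustive oracle disables the
prefilter outright.

## Threshold optimization

Single-linkage thresholds are tuned per (supertaxon, subrank) on a
reference database with lineage annotations, by maximizing the multi-class
F-measure: the class-size-weighted mean over reference subtaxa of the best
harmonic mean of precision and recall against any cluster (the best-match
form; it is pinned by oracle tests that recompute precision and recall
directly on enumerated partitions). F is evaluated at every grid threshold
(step 0.001 over [0, 0.6] by default) with an incremental union-find, and
the smallest maximizer wins — the most conservative (most splitting)
optimum, and a deterministic one. A combination is eligible only when the
supertaxon holds at least five subtaxa and ten reference sequences;
clustering then resolves each rank's threshold through the most specific
eligible ancestor, falling back ancestor by ancestor to the all-Fungi root.
This fallback chain is why thresholds are computed for the whole hierarchy
(all Fungi into phylum…species, each phylum into class…species, and so on).

## Kingdom screening

Every non-spike ASV is matched against annotated reference sequences at a
global dissimilarity of at most 0.2 (similarity 0.8). A best hit in
*Fungi* makes it a known fungus, a hit in another named kingdom a known
non-fungus; no hit, or a hit with an unspecified kingdom, leaves the
kingdom unknown. Pseudotaxa with strictly more known non-fungal than known
fungal members are removed at every rank (a 1:1 tie is retained — "more"
is read literally); phylum-rank pseudotaxa whose members are all of
unknown kingdom are removed as well, at the phylum level only. Removed
ASVs are routed to the non-fungal pseudophylum table; retained ASVs in
pseudophyla appear in the fungal table with their OTU ids. Summaries group
pseudophyla by the most common best-hit taxon (ties lexicographic), with
member counts split into majority / minority / unspecified / no-match —
the four categories partition the total by construction.

## Spike-in quantification

Nine synthetic plasmids are spiked into each reaction; ASVs with best-hit
similarity strictly greater than 0.9 to a spike reference are labelled
spikes. The DNA amount per m³ of air is

> (non-spike reads / spike reads) × spike mass (ng) / air volume (m³),

reported as log10(ng/m³), with air volume 23.8 m³ (a 24-hour sampling
period) and spike mass `calib_mass × dilution / dilution_ref`: a 1:1000
reaction carries a tenth of the spike DNA of a 1:100 reaction, which is
exactly what makes the estimate invariant to the dilution level — the
package's tests check that invariance explicitly, and every comparison is
constructed to be invariant to the calibration constant itself, which
comes from the companion wet-lab calibration and is exposed as
configuration (`spike_config()`). Samples with zero spike reads are
flagged unquantifiable; zero non-spike reads flag "no fungal DNA
detected". Both flags suppress numeric output rather than propagating
infinities.

## Validation statistics

* **Depth.** Sample depth counts fungal *and* spike reads; the default
  inclusion threshold is 10,000 reads. Rarefaction uses the analytic
  hypergeometric expectation `S(m) = Σ_k [1 − C(N−N_k, m)/C(N, m)]`
  (via `vegan::rarefy`) rather than resampling — deterministic, and checked
  in the tests against a 100,000-draw Monte-Carlo oracle. Whether a curve
  subsamples fungal-only or total reads is decided by which count table the
  caller passes.
* **Negative controls.** Controls with only spike reads count as zero
  fungal reads. For a contaminated control, the co-run study sample with
  the highest total abundance over the control's units is reported as the
  candidate cross-contamination source.
* **Agreement summaries.** Classifier-vs-expert comparisons are aggregated
  per confidence band (reliable ≥ 0.9, plausible [0.5, 0.9), best hit
  [0.01, 0.5), no hit) into counts and inconsistency percentages.
* **Occurrence null model.** A species' per-site prevalence is correlated
  with a distance-weighted occurrence index `g_i = Σ exp(−d/1000 km)`
  (haversine distances, Earth radius 6371 km). The null distribution
  replaces the focal prevalence with every non-focal species' prevalence;
  the empirical p-value is the proportion of defined null correlations
  strictly exceeding the observed one (ties do not count, reading
  "exceeds" literally). Pearson correlation is the default — the
  conventional default of the computing environment — with Spearman as an
  option. A correlation is undefined, and the species excluded, when there
  are fewer than three complete site pairs or either vector has zero
  variance; this is one defensible reading of "too few datapoints", and
  complete pairs are used rather than requiring all sites.

## What the synthetic generator emulates — and what it does not

`simulate_references()` evolves sequences down a balanced taxonomy by
point substitutions with per-rank branch lengths chosen so that sister
taxa at each rank sit at strictly decreasing total divergences (defaults
0.32, 0.24, 0.18, 0.13, 0.09, 0.05 from phylum to species, 0.01
intraspecific; amplicon length 300, the ITS2 scale). The default tree has
6 phyla × 2 classes × 2 genera × 2 species (48 species): the root
threshold entries require at least five subtaxa per rank, which fixes the
minimum width at the top of the tree. `simulate_dataset()` adds
intraspecific ASV variants, terminal-truncation duplicates (exercising the
end-gap collapse), non-fungal contaminants from independent out-group
roots, sequences with no reference relative anywhere, spike reads
back-calculated from a known per-sample DNA amount at the two study
dilutions (1:100 for the early ~12% of samples, 1:1000 thereafter),
lognormal sequencing depths, negative controls (mostly clean, occasionally
receiving a scaled-down copy of a co-run sample's profile), a 47-site ×
2-samples-per-week design structured along a temperature gradient, and
occurrence records scattered around the sites where each species is
prevalent. Ground truth is emitted as a sidecar never read by the
pipeline.

The generator does not emulate ITS secondary structure, indel hotspots,
chimeras, length heterogeneity beyond terminal truncation, or reference
mislabelling. Passing tests therefore demonstrate the algorithmic
contracts — threshold recovery, cluster recovery under partial assignment,
purge behaviour, calibration of the null model — not robustness to every
artefact of real sequencing data. Desk-scale problem sizes are the
package's own choice: the default dataset holds 48 fungal species
(~110 ASVs) over 2,726 samples, and the test suite uses a narrower
24-species tree over 30 samples.

## Numerical and degenerate-input conventions

* The 0.6 matrix cutoff applies to the terminal-gap-free dissimilarity —
  the reported quantity, not the raw alignment cost.
* An alignment whose internal region is empty has dissimilarity 1.
* `optimize_threshold` treats pairs absent from the sparse matrix as
  farther than every threshold; single-linkage joins on `d ≤ t` (closed
  threshold), which makes the recovered optimum the maximal observed
  intra-taxon distance in the separable case.
* Empty inputs error early (`fmeasure`, `sparse_distances`); header-only
  tables round-trip as empty tables; a depth report over zero samples has
  an undefined discard percentage.
* Pseudotaxon counters, OTU ids and all tie-breaks are deterministic, so
  identical inputs produce byte-identical outputs in any input order.

## Known limitations

Pairwise alignment is exact (no banding), so distance matrices beyond a
few thousand sequences become the dominant cost; the sparse k-mer
prefilter mitigates but does not remove the quadratic pair enumeration.
The purge rule applies the non-fungal majority test independently at every
rank, the strictest defensible reading; a cluster whose kingdom evidence
is split 1:1 survives. Threshold optimization ignores uncertainty — no
confidence intervals are attached to the optimized thresholds — and the
probabilistic classifier itself is consumed as input, never re-estimated.
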
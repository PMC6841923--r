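---
title: "Cross-feeding, influence and degradation networks: methods and design"
author: "CrossFeedNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-feeding, influence and degradation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrossFeedNet)
```

# Scope and data model

CrossFeedNet analyses a gut microbial community from three curated
inputs: (i) a species–metabolite activity table, each row a species, a
compound and one of `import`, `export`, `both`, `degrades`, with an
optional literature count and KEGG flag; (ii) a species × compartment
relative-abundance table (percent), compartments ordered along the gut
axis; (iii) a species → glycoside-hydrolase annotation table. All three
are presence/absence-grade evidence: the package deliberately makes no
claims about transport rates or growth kinetics, and none of its scores
should be read as fluxes.

Two modelling conventions shape everything downstream:

* **Strain merging.** Strain-level rows sharing a species name are merged
  into one species; an import row and an export row for the same compound
  collapse to `both`. Merging is idempotent, so reloading a saved network
  is a fixed point.
* **Effective exports.** Macromolecule hydrolysis is extracellular, so
  degradation products are treated as exports of *every* degrader of that
  macromolecule. This single rule is what gives degraders their outsized
  positive influence later.

## Edge confidence

Each edge scores `(n/N)·70 + K·30` on a 0–100 scale, `N` being the global
maximum literature count across edges. Literature evidence deliberately
outweighs database corroboration 70:30 — the table is literature-curated
and KEGG serves as secondary validation. The score is monotone in both
inputs and is attached to every exported edge so that downstream networks
(including the degradation network) can weight by provenance quality.
When every edge has `n = 0`, the loader uses `N = 1` so the score
degrades gracefully to `K·30`.

# Segmentation of the gut axis

Compartments are merged left-to-right: the current block is extended by
the next compartment when a Kruskal–Wallis test across the block's
abundance columns fails to reject at `alpha` (default 0.05). Failing to
reject is read, as in the community-ecology practice this mirrors, as
"no detectable difference in abundance distribution", hence one habitat
segment. The statistic is the classical uncorrected form on mid-ranks;
the tie-corrected version (`tieCorrection = TRUE`) is available and
coincides with `stats::kruskal.test`. Species enter a test when they
reach the inclusion threshold (`minAbundance`, default 0.02%) in at least
one compartment of the candidate block; zeros of included species are
retained, because absence in one compartment *is* signal about the
distribution. No multiple-testing correction is applied across the (at
most five) sequential decisions — each merge is a local decision on the
gut axis, and every H and p is recorded in the returned
`SegmentPartition` for inspection. The last compartment's separateness is
decided by the same rule as every other boundary, never hard-coded.

# The influence score

The conceptual quantity is an elasticity: how much does *q*'s growth
respond to a change in *p*'s abundance, summed over the metabolites *q*
consumes. Partial derivatives are not identifiable from presence/absence
data, so the package defines a discretization and states it openly as its
model:

$$I_{pq} = \frac{n_p}{\mu_q}\,\frac{1}{|\mathrm{Imp}(q)|}
\sum_{m \in \mathrm{Imp}(q)} s_m(p,q), \qquad
s_m = \begin{cases} +1 & m \in \mathrm{EffExp}(p) \\
-1 & m \in \mathrm{Imp}(p)\setminus\mathrm{EffExp}(p) \\
0 & \text{otherwise} \end{cases}$$

Design choices worth spelling out:

* **Sign semantics first.** Pure cross-feeding with equal abundances gives
  exactly +1, pure competition −1, disjoint metabolite sets exactly 0.
  These anchors are contract-tested.
* **Providers are not competitors.** A species that both consumes and
  supplies a metabolite (degrader-fermenters being the canonical case)
  counts as a provider (+1) for it: its presence adds to the pool it
  draws from.
* **Import-set normalization** makes scores comparable between consumers
  with very different import repertoires; `normalization = "none"` turns
  it off.
* **Abundance proxies.** Within a segment, `n_p` and `mu_q` are segment
  means; cross-segment pairs fall back to global means so edges can span
  segments. The discretization is linear in `n_p`: doubling `n_p` doubles
  `I_pq`.
* **Confidence weighting** of the per-metabolite terms (by the confidence
  of *q*'s import edge) is available but off by default — it changes
  magnitudes, never signs.

The most abundant species per segment (a per-segment `topK` or an
abundance cutoff; both exposed because no canonical value exists) enter a
dense score matrix; thresholding `|I_pq|` yields the signed directed
influence network. The threshold default is 0 (every nonzero score is an
edge); any stricter value is a presentation choice, not a model one.

# Influencers

Out-degree measures direct influence; community-wide control is measured
by betweenness centrality on the directed, unweighted network, all
shortest paths counted, each node normalized by
`2 / ((P−1)(P−2))` with `P` the size of its weakly connected component.
This is the undirected-graph constant applied to directed path sums: on a
directed graph the value can reach 2, not 1. We keep this form because it
is the printed convention this analysis follows;
`normalization = "directed"` halves it for the usual [0, 1] scale, and
the production implementation is verified exactly against brute-force
path enumeration on small digraphs and against igraph's unnormalized
directed betweenness.

Influencers are nodes strictly above the mean centrality (`cutoff =
"auto"`; a numeric cutoff is accepted). They are classed `DEGRADER`
(degrades, no fermentation exports), `FERMENTER` (explicitly exports a
fermentation product — default list acetate, ethanol, butanol, lactate,
H2, CO2 — without degrading), `BOTH`, or `OTHER`. Fermenter status is
judged on explicit exports only: inherited degradation products are
sugars, and letting them trigger fermenter status would misclassify every
degrader.

Robustness removes a fraction (default 25%) of species — and, in the
default mode, of small metabolites — uniformly at random under a seed,
reruns the influence/centrality/influencer stages, and reports retention
with two denominators (original influencers that survived removal, and
all original influencers), since either convention is defensible. The
compartment partition is reused in the rerun: removal drops species, not
compartments. With a fixed seed the whole procedure is bit-reproducible,
and `removalFraction = 0` is the exact no-removal limit with 100%
retention.

# Degradation network

Influential degraders (influencers with `DEGRADES` edges, optionally
restricted to substrate classes) are joined with their enzyme
annotations: degrader → enzyme (`secretes`), enzyme → macromolecule
(`hydrolyzes`), macromolecule → product (`yields`), product → fermenter
(`consumes`), fermenter → byproduct (`excretes`). Rows sourced from
dbCAN2/Hotpep must pass the standard peptide-filter thresholds
(frequency > 2.6, hits > 6), enforced idempotently at load. Edge
confidence reuses the activity-edge score where an underlying activity
exists (consumes/excretes; yields takes the best score among the
macromolecule's degraders) and defaults to mid-scale 50 for purely
enzyme-derived edges, for which no activity-based score exists. Every
`consumes`/`excretes` edge is guaranteed to correspond to an
import/export activity in the source network.

# The synthetic community generator

`generateCommunity()` is first-class, tested code, not a fixture. It
emulates the statistical structure the analysis assumes, with ground
truth recorded for every planted relation:

* guild-structured activity: degraders whose dedicated degradation
  products feed their fermenters; fermenters sharing a sugar compete;
  specialist pairs share a dedicated import; generalists draw from a
  common pool and are left unlabeled;
* an optional hub degrader feeding 80% of the community through grouped
  sugars, itself importing the community's fermentation byproducts — so
  indirect paths between fed species route through the hub and the hub is
  recoverable by centrality;
* planted relations wired through *dedicated* metabolites, so every
  labelled pair is purely feeding, purely competing, or disjoint — which
  is what makes exact sign recovery a meaningful contract;
* geometric literature counts and Bernoulli KEGG flags, so confidence
  scoring is exercised over its whole range;
* log-normal abundances (long-tailed, as in real relative-abundance
  tables) with a per-segment active species set. Compartments within a
  planned segment share their active set up to small log-scale noise
  (sd 0.15); segments differ in richness (defaults 0.95 / 0.55 / 0.2
  along the gut, the rear segment markedly depauperate). Richness
  differences are what the rank test detects, because a segment-wide
  multiplicative shift cancels under relative-abundance normalization —
  a location shift alone would be invisible, which is why the generator
  plants compositional contrast instead. The dropout penalty (6 log
  units, 4 sd of the base distribution) makes inactive species
  effectively absent without hard zeros.

What the generator does *not* emulate: taxonomic structure, phylogenetic
correlation of metabolic repertoires, abundance–activity coupling (guild
wiring and abundances are independent draws), compositional count noise,
or curation error. Passing the recovery tests therefore demonstrates that
the pipeline's inferences are correct *given its model assumptions*, not
that those assumptions hold in any particular real community.

All randomness flows from one integer seed; identical seeds give
byte-identical tables.

# Numerical and testing choices

* Co-occurrence is Spearman correlation across the (six) compartments —
  with so few samples a rank correlation is the defensible choice; a
  presence/absence Jaccard alternative is provided. Zero-variance species
  are flagged and excluded rather than silently scored.
* Metabolic similarity is Jaccard on import sets (competition acts on
  shared inputs); a flag widens it to imports ∪ effective exports. Two
  empty sets score 0 by convention, not 1.
* Rank-correlation p-values: t approximation from 30 pairs, seeded
  permutation (10^4 resamples) below that. Groups are made disjoint by
  dropping their intersection before pairing.
* Degenerate inputs fail loudly: empty groups, fewer than three total
  observations, zero-variance profiles, missing abundances, infeasible
  generator specs all raise errors naming the offending rows where
  possible.
* Test problem sizes: oracle comparisons run on exhaustive enumerations
  (digraphs of at most 8 nodes), contract sweeps on communities of
  60–150 species with 15–100 seeds, and one full-pipeline run at the
  default 205-species scale — sizes chosen so each property is tested at
  the smallest scale at which it is informative.

# Known limitations

* The influence discretization is one defensible member of a family; the
  model object is pluggable precisely so alternative weightings can be
  swapped in without touching downstream stages. Published pairwise
  influence values from any given study are reproducible only with that
  study's curated tables and weighting.
* Sequential merge testing has no global error control; with six
  compartments this is at most five dependent decisions, all reported.
* Betweenness is computed on the unweighted graph; edge magnitudes do not
  affect path counts, only edge retention via the threshold.
* The degradation network is a projection of curated evidence, not a
  stoichiometric model; it cannot be used for yield predictions.
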
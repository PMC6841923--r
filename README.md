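# CrossFeedNet

Species-wide metabolic cross-feeding and inter-species influence analysis
for gut microbial communities.

Wood-feeding higher termites digest lignocellulose through a
compartmentalized gut microbiota in which macromolecule degraders release
sugars that feed fermenters, while species with overlapping substrate
ranges compete. CrossFeedNet turns a literature-curated table of
species-metabolite activities (import / export / both / macromolecule
degradation) and a species-by-compartment relative-abundance table into a
quantitative picture of that community: who feeds whom, who competes with
whom, which species hold the community together, and how the breakdown of
cellulose and hemicellulose flows through the food web. It is intended for
microbial ecologists and systems biologists working with curated
metabolic-activity data rather than raw reads.

## The model

**Edge confidence.** Every activity edge carries a literature confidence
score

    score = (n / N) * 70 + K * 30

with `n` the number of supporting publications, `N` the maximum publication
count over all edges, and `K` a 0/1 KEGG-corroboration flag.

**Effective exports.** Degradation products of a macromolecule count as
exports of every species that degrades it, since hydrolysis happens
extracellularly and the products enter the shared pool.

**Segmentation.** Adjacent gut compartments (C, M, P1, P3, P4, P5) are
merged greedily into segments whenever a Kruskal–Wallis test on their
per-species abundance distributions fails to reject at the chosen level,
using the classical uncorrected statistic on mid-ranks

    H = 12 / (N (N + 1)) * sum_i R_i^2 / n_i - 3 (N + 1)

(tie correction available behind a flag).

**Pairwise influence.** The net metabolic influence of species *p* on *q*
is an elasticity-style score discretized on presence/absence data:

    I_pq = (n_p / mu_q) * (1 / |Imp(q)|) * sum_m s_m(p, q)

where `s_m = +1` if *p* effectively exports a metabolite *q* imports
(cross-feeding), `-1` if both import *m* and *p* cannot supply it
(competition), else 0; `n_p` and `mu_q` are relative abundances (segment
means within a segment, global means across segments). Pure cross-feeding
at equal abundance gives exactly +1, pure competition exactly −1, disjoint
metabolite sets exactly 0.

**Influencers.** On the thresholded signed directed network, betweenness
centrality

    C_b(p) = [ sum_{x != p != y} sigma_xy(p) / sigma_xy ] / ((P-1)(P-2)) * 2

(`P` = size of *p*'s connected component) flags species that mediate
indirect metabolic influence; nodes strictly above the mean `C_b` are
influencers, subsequently classified as degraders, fermenters, or both.
Robustness is assessed by removing 25% of species (and optionally
metabolites) at random and measuring influencer retention, and the
influential degraders are joined with their glycoside-hydrolase annotations
into a degrader → enzyme → macromolecule → sugar → fermenter degradation
network.

## Worked example

The package ships a seeded synthetic-community generator with planted
guild structure, so the whole pipeline can be exercised without external
data:

```r
library(CrossFeedNet)

com  <- generateCommunity(communitySpec(nSpecies = 150, nMetabolites = 220,
                                        seed = 42))
com$network
#> CrossFeedingNetwork: 150 species, 187 metabolites, 10 macromolecules
#>    536 import/export events, 12 degradation events (nMax = 17 )

part <- partitionSegments(com$abundance)
part
#> SegmentPartition (alpha = 0.05 ):
#>   S1 = C, M, P1
#>   S2 = P3, P4
#>   S3 = P5

g   <- buildInfluenceNetwork(
         influenceMatrix(com$network, com$abundance, part, topK = Inf))
g
#> InfluenceNetwork: 150 nodes ( S1:58, S2:60, S3:32 ), 1101 edges
#>   ( 357 positive / 744 negative ), |I| > 0

rep <- centralityReport(g, com$network)
head(rep[order(-rep$betweenness), ], 3)
#>  species segment out_degree betweenness influencer functional_class
#>    sp001      S3        119      1.6411       TRUE         DEGRADER
#>    sp091      S2          6      0.0406       TRUE        FERMENTER
#>    sp106      S2          5      0.0365       TRUE            OTHER

robustnessSample(com$network, com$abundance, part, seed = 1)
#> RobustnessResult: seed 1 , removed 25 % ( species_and_metabolites )
#>   retained 75 % of surviving original influencers ( 50 % of all )
```

The six compartments are re-partitioned into the planted 3–2–1 segment
plan; the planted hub degrader `sp001` (whose degradation products feed
80% of the community) tops the centrality ranking by an order of
magnitude; and three quarters of the surviving influencers keep their
status after a 25% random data reduction. Real curated tables enter the
same way through `loadNetwork()`, `loadAbundanceTable()` and
`loadEnzymeTable()`, and `runPipeline(pipelineConfig(...))` executes every
stage and writes the TSV/SIF/GraphML bundle (Cytoscape-ready) plus a
provenance record.

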
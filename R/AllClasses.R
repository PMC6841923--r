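#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

ACTIVITY_LEVELS <- c("IMPORT", "EXPORT", "BOTH", "DEGRADES")
COMPOUND_CLASSES <- c("SMALL_METABOLITE", "MACROMOLECULE")

#' CrossFeedingNetwork: species-wide metabolic interaction network
#'
#' Container for a curated bipartite species--metabolite network. Each
#' activity row links one species to one compound with an activity
#' (`IMPORT`, `EXPORT`, `BOTH`, or `DEGRADES`), a literature count, a KEGG
#' availability flag, and the derived confidence score. Compounds are either
#' small metabolites or macromolecules; macromolecules carry a set of
#' degradation products. The effective export set of a species is its
#' explicit `EXPORT`/`BOTH` compounds plus the degradation products of every
#' macromolecule it degrades, reflecting that breakdown products enter the
#' shared metabolite pool as exports of every degrader.
#'
#' @slot activities data.frame with columns `species`, `compound`,
#'   `activity`, `n_publications`, `kegg_flag`, `confidence`.
#' @slot compounds data.frame with columns `compound`, `klass`.
#' @slot degradationProducts named list: macromolecule -> character vector
#'   of small-metabolite product names.
#' @slot speciesGroups named character vector mapping species to an optional
#'   functional group label (possibly empty).
#' @slot nMax integer, the global maximum literature count over all edges
#'   (the N of the confidence score).
#'
#' @seealso [loadNetwork()], [confidenceScore()], [transportProfile()]
#' @export
setClass("CrossFeedingNetwork",
  slots = c(
    activities = "data.frame",
    compounds = "data.frame",
    degradationProducts = "list",
    speciesGroups = "character",
    nMax = "integer"
  )
)

setValidity("CrossFeedingNetwork", function(object) {
  act <- object@activities
  cmp <- object@compounds
  msgs <- character()
  need <- c("species", "compound", "activity", "n_publications",
            "kegg_flag", "confidence")
  if (!all(need %in% names(act)))
    return(paste("activities must have columns:", paste(need, collapse = ", ")))
  if (!all(c("compound", "klass") %in% names(cmp)))
    return("compounds must have columns compound, klass")
  if (nrow(act)) {
    if (!all(act$activity %in% ACTIVITY_LEVELS))
      msgs <- c(msgs, "unknown activity levels present")
    if (!all(act$compound %in% cmp$compound))
      msgs <- c(msgs, "activity rows reference unknown compounds")
    if (anyDuplicated(act[, c("species", "compound", "activity")]))
      msgs <- c(msgs, "duplicate (species, compound, activity) triples")
    if (any(act$n_publications < 0))
      msgs <- c(msgs, "n_publications must be non-negative")
    if (!all(act$kegg_flag %in% c(0, 1)))
      msgs <- c(msgs, "kegg_flag must be 0 or 1")
    conf <- act$confidence[!is.na(act$confidence)]
    if (length(conf) && (min(conf) < 0 || max(conf) > 100))
      msgs <- c(msgs, "confidence scores must lie in [0, 100]")
    deg <- act[act$activity == "DEGRADES", , drop = FALSE]
    if (nrow(deg)) {
      kl <- cmp$klass[match(deg$compound, cmp$compound)]
      if (!all(kl == "MACROMOLECULE"))
        msgs <- c(msgs, "DEGRADES activities must target macromolecules")
      prods <- object@degradationProducts[deg$compound]
      if (any(!lengths(prods)))
        msgs <- c(msgs, "degraded macromolecules must have degradation products")
    }
  }
  if (!all(cmp$klass %in% COMPOUND_CLASSES))
    msgs <- c(msgs, "compound klass must be SMALL_METABOLITE or MACROMOLECULE")
  dp <- object@degradationProducts
  if (length(dp)) {
    if (is.null(names(dp)) || !all(names(dp) %in% cmp$compound))
      msgs <- c(msgs, "degradationProducts names must be registered compounds")
    else {
      kl <- cmp$klass[match(names(dp)[lengths(dp) > 0], cmp$compound)]
      if (length(kl) && !all(kl == "MACROMOLECULE"))
        msgs <- c(msgs, "only macromolecules may have degradation products")
    }
  }
  if (length(object@speciesGroups) && is.null(names(object@speciesGroups)))
    msgs <- c(msgs, "speciesGroups must be a named character vector")
  if (object@nMax < 1L) msgs <- c(msgs, "nMax must be >= 1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' AbundanceTable: species-by-compartment relative abundances
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `abundance`
#' assay holding relative abundances in percent, rows = species, columns =
#' gut compartments in anatomical order (for the termite gut:
#' C, M, P1, P3, P4, P5). `minAbundance` is the inclusion threshold (in
#' percent) used when species are selected for distribution tests.
#'
#' @slot minAbundance numeric inclusion threshold, percent (default 0.02).
#' @export
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  slots = c(minAbundance = "numeric")
)

setValidity("AbundanceTable", function(object) {
  a <- SummarizedExperiment::assay(object, "abundance")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("abundance matrix must have species rownames and compartment colnames")
  if (anyDuplicated(colnames(a))) return("compartments must be unique")
  if (anyDuplicated(rownames(a))) return("species must be unique")
  if (any(a < 0)) return("abundances must be non-negative")
  if (length(object@minAbundance) != 1L || object@minAbundance < 0)
    return("minAbundance must be a single non-negative number")
  TRUE
})

#' SegmentPartition: compartment-to-segment assignment
#'
#' Result of the greedy Kruskal--Wallis merging of adjacent gut compartments
#' into segments. `mapping` assigns every compartment a segment label
#' (S1, S2, ...), always contiguous along the gut axis; `tests` records each
#' merge decision with its H statistic and p-value.
#'
#' @slot mapping named character vector, compartment -> segment label.
#' @slot tests data.frame with columns `compartments`, `H`, `p_value`,
#'   `merged` (one row per candidate-block test).
#' @slot alpha significance level used for the merge rule.
#' @export
setClass("SegmentPartition",
  slots = c(mapping = "character", tests = "data.frame", alpha = "numeric")
)

setValidity("SegmentPartition", function(object) {
  if (is.null(names(object@mapping))) return("mapping must be named")
  segs <- object@mapping
  # contiguity: each segment label occupies one run of adjacent compartments
  if (any(rle(segs)$values != unique(segs)))
    return("segments must be contiguous runs of compartments")
  TRUE
})

#' InfluenceModel: operationalization of the pairwise influence score
#'
#' Parameters of the signed, abundance-scaled discretization of the
#' elasticity-style influence score I_pq. A metabolite m contributes +1 when
#' p effectively exports m and q imports it (cross-feeding), -1 when both
#' import m and p cannot supply it (competition), 0 otherwise; contributions
#' are optionally averaged over q's import set and scaled by n_p / mu_q.
#'
#' @slot abundanceMode `"segment"` (abundances averaged over the segment a
#'   species was selected in; cross-segment pairs fall back to global means)
#'   or `"global"` (mean over all compartments).
#' @slot normalization `"import"` (divide by |Imp(q)|) or `"none"`.
#' @slot confidenceWeighting logical; weight each metabolite term by the
#'   confidence (0-1) of q's import edge instead of 1.
#' @export
setClass("InfluenceModel",
  slots = c(
    abundanceMode = "character",
    normalization = "character",
    confidenceWeighting = "logical"
  )
)

setValidity("InfluenceModel", function(object) {
  if (!object@abundanceMode %in% c("segment", "global"))
    return("abundanceMode must be 'segment' or 'global'")
  if (!object@normalization %in% c("import", "none"))
    return("normalization must be 'import' or 'none'")
  TRUE
})

#' InfluenceMatrix: dense pairwise influence scores
#'
#' @slot scores numeric matrix of I_pq values (rows = influencing species p,
#'   columns = influenced species q); diagonal is NA.
#' @slot segments named character vector, species -> segment label.
#' @slot model the [InfluenceModel] used.
#' @export
setClass("InfluenceMatrix",
  slots = c(scores = "matrix", segments = "character", model = "InfluenceModel")
)

setValidity("InfluenceMatrix", function(object) {
  s <- object@scores
  if (nrow(s) != ncol(s)) return("scores must be square")
  if (!identical(rownames(s), colnames(s)))
    return("scores dimnames must agree")
  off <- s[row(s) != col(s)]
  if (length(off) && any(!is.finite(off)))
    return("off-diagonal influence scores must be finite")
  if (!all(rownames(s) %in% names(object@segments)))
    return("every species needs a segment label")
  TRUE
})

#' InfluenceNetwork: thresholded signed directed influence graph
#'
#' @slot nodes data.frame with columns `species`, `segment`.
#' @slot edges data.frame with columns `from`, `to`, `weight`, `sign`
#'   (+1 or -1).
#' @slot threshold magnitude threshold used to retain edges.
#' @export
setClass("InfluenceNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame", threshold = "numeric")
)

setValidity("InfluenceNetwork", function(object) {
  e <- object@edges
  n <- object@nodes
  if (!all(c("species", "segment") %in% names(n)))
    return("nodes needs columns species, segment")
  if (!all(c("from", "to", "weight", "sign") %in% names(e)))
    return("edges needs columns from, to, weight, sign")
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-edges are not allowed")
    if (!all(c(e$from, e$to) %in% n$species))
      return("edge endpoints must be nodes")
    if (!all(e$sign == sign(e$weight)))
      return("edge sign must equal sign(weight)")
  }
  TRUE
})

#' RobustnessResult: influencer retention under random data reduction
#'
#' @slot seed integer seed of the resampling run.
#' @slot removalFraction fraction of data removed.
#' @slot mode `"species_and_metabolites"` or `"species_only"`.
#' @slot retainedPct percent of original influencers that survive removal and
#'   are re-identified as influencers (denominator: original influencers that
#'   survived removal).
#' @slot retainedPctAll same numerator over all original influencers.
#' @slot influencersOriginal,influencersReduced character vectors.
#' @export
setClass("RobustnessResult",
  slots = c(
    seed = "integer", removalFraction = "numeric", mode = "character",
    retainedPct = "numeric", retainedPctAll = "numeric",
    influencersOriginal = "character", influencersReduced = "character"
  )
)

setValidity("RobustnessResult", function(object) {
  ok <- function(x) is.na(x) || (x >= 0 && x <= 100)
  if (!ok(object@retainedPct) || !ok(object@retainedPctAll))
    return("retention percentages must lie in [0, 100]")
  TRUE
})

DEGRADATION_NODE_TYPES <- c("degrader", "enzyme", "macromolecule",
                            "small_metabolite", "fermenter")
DEGRADATION_EDGE_TYPES <- c("secretes", "hydrolyzes", "yields",
                            "consumes", "excretes")

#' DegradationNetwork: degrader-enzyme-macromolecule-sugar-fermenter graph
#'
#' Typed multipartite network describing extracellular lignocellulose
#' breakdown: influential degraders secrete glycoside hydrolases, enzymes
#' hydrolyze macromolecules, macromolecules yield small metabolites, small
#' metabolites are consumed by fermenters, fermenters excrete fermentation
#' byproducts. Edges carry confidence weights.
#'
#' @slot nodes data.frame with columns `name`, `type`.
#' @slot edges data.frame with columns `from`, `to`, `type`, `confidence`.
#' @export
setClass("DegradationNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame")
)

setValidity("DegradationNetwork", function(object) {
  n <- object@nodes; e <- object@edges
  if (!all(n$type %in% DEGRADATION_NODE_TYPES)) return("unknown node type")
  if (!all(e$type %in% DEGRADATION_EDGE_TYPES)) return("unknown edge type")
  if (nrow(e)) {
    if (!all(c(e$from, e$to) %in% n$name)) return("dangling edge endpoint")
    ty <- function(x) n$type[match(x, n$name)]
    if (!all(ty(e$from[e$type == "hydrolyzes"]) == "enzyme") ||
        !all(ty(e$to[e$type == "hydrolyzes"]) == "macromolecule"))
      return("hydrolyzes edges must join enzyme -> macromolecule")
    if (!all(ty(e$from[e$type == "yields"]) == "macromolecule") ||
        !all(ty(e$to[e$type == "yields"]) == "small_metabolite"))
      return("yields edges must join macromolecule -> small metabolite")
    if (any(e$confidence < 0 | e$confidence > 100))
      return("edge confidence must lie in [0, 100]")
  }
  TRUE
})

#' CommunitySpec: parameters of the synthetic community generator
#'
#' Defines a synthetic gut community with planted ecological structure:
#' guilds (macromolecule degraders, fermenters, specialist competitor pairs,
#' generalists), planted cross-feeding and competition wired through
#' dedicated metabolites, an optional planted hub degrader whose degradation
#' products feed a large fraction of the community, and compartment
#' abundances following a segment plan (same active species set and
#' log-normal profile within a segment, differing richness between
#' segments). All randomness flows from `seed`.
#'
#' @slot nSpecies,nMetabolites,nMacromolecules integers.
#' @slot guildProportions named numeric (degrader, fermenter, specialist,
#'   generalist); remainder of the community has private imports only.
#' @slot crossFeedingDensity,competitionDensity expected number of extra
#'   planted feed / compete pairs per species (each via a dedicated
#'   metabolite).
#' @slot compartments character vector of compartment names in gut order.
#' @slot segmentPlan integer vector (one entry per compartment) giving the
#'   planned segment of each compartment, e.g. `c(1,1,1,2,2,3)`.
#' @slot segmentRichness numeric, fraction of species active per planned
#'   segment.
#' @slot abundanceMeanlog,abundanceSdlog log-normal parameters of the
#'   species base abundances.
#' @slot withinSegmentNoise sd of log-scale compartment noise within a
#'   segment.
#' @slot dropoutPenalty log-scale abundance penalty for species inactive in
#'   a segment.
#' @slot plantedHub logical; plant a hub degrader feeding
#'   `hubFeedFraction` of the community through dedicated sugar groups.
#' @slot hubFeedFraction fraction of species fed by the hub.
#' @slot pubProb geometric success probability for literature counts.
#' @slot keggProb Bernoulli probability of KEGG support per edge.
#' @slot seed integer seed.
#' @export
setClass("CommunitySpec",
  slots = c(
    nSpecies = "integer", nMetabolites = "integer", nMacromolecules = "integer",
    guildProportions = "numeric",
    crossFeedingDensity = "numeric", competitionDensity = "numeric",
    compartments = "character", segmentPlan = "integer",
    segmentRichness = "numeric",
    abundanceMeanlog = "numeric", abundanceSdlog = "numeric",
    withinSegmentNoise = "numeric", dropoutPenalty = "numeric",
    plantedHub = "logical", hubFeedFraction = "numeric",
    pubProb = "numeric", keggProb = "numeric", seed = "integer"
  )
)

setValidity("CommunitySpec", function(object) {
  msgs <- character()
  if (object@nSpecies < 3L) msgs <- c(msgs, "nSpecies must be >= 3")
  if (object@nMetabolites < 1L && (object@crossFeedingDensity > 0 ||
                                   object@competitionDensity > 0))
    msgs <- c(msgs, "zero metabolites with nonzero planted density")
  p <- object@guildProportions
  need <- c("degrader", "fermenter", "specialist", "generalist")
  if (!all(need %in% names(p)))
    msgs <- c(msgs, paste("guildProportions needs:", paste(need, collapse = ", ")))
  else if (any(p < 0) || sum(p) > 1 + 1e-9)
    msgs <- c(msgs, "guild proportions must be non-negative and sum to <= 1")
  if (length(object@segmentPlan) != length(object@compartments))
    msgs <- c(msgs, "segmentPlan must label every compartment")
  if (any(diff(object@segmentPlan) < 0))
    msgs <- c(msgs, "segmentPlan must be non-decreasing (contiguous segments)")
  if (length(object@segmentRichness) != length(unique(object@segmentPlan)))
    msgs <- c(msgs, "segmentRichness needs one value per planned segment")
  dens <- c(object@crossFeedingDensity, object@competitionDensity)
  if (any(dens < 0) || any(dens > 1))
    msgs <- c(msgs, "densities must lie in [0, 1]")
  if (object@hubFeedFraction < 0 || object@hubFeedFraction > 1)
    msgs <- c(msgs, "hubFeedFraction must lie in [0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
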
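#' Restrict a cross-feeding network to subsets of species and metabolites
#'
#' Drops activity rows of removed species and rows touching removed small
#' metabolites, removes dropped metabolites from macromolecule product
#' lists, and drops DEGRADES rows whose macromolecule retains no products.
#'
#' @param net a [CrossFeedingNetwork].
#' @param keepSpecies,keepCompounds character vectors (compounds default to
#'   all).
#' @return a reduced [CrossFeedingNetwork].
#' @export
subsetNetwork <- function(net, keepSpecies = NULL, keepCompounds = NULL) {
  act <- net@activities
  cmp <- net@compounds
  prods <- net@degradationProducts
  if (is.null(keepSpecies)) keepSpecies <- .speciesOf(net)
  if (is.null(keepCompounds)) keepCompounds <- cmp$compound
  keepCompounds <- union(keepCompounds,
                         cmp$compound[cmp$klass == "MACROMOLECULE"])
  cmp <- cmp[cmp$compound %in% keepCompounds, , drop = FALSE]
  prods <- lapply(prods[cmp$compound], intersect, y = keepCompounds)
  act <- act[act$species %in% keepSpecies &
               act$compound %in% cmp$compound, , drop = FALSE]
  emptyMacro <- names(prods)[lengths(prods) == 0 &
    cmp$klass[match(names(prods), cmp$compound)] == "MACROMOLECULE"]
  act <- act[!(act$activity == "DEGRADES" &
                 act$compound %in% emptyMacro), , drop = FALSE]
  rownames(act) <- NULL
  grp <- net@speciesGroups[names(net@speciesGroups) %in% keepSpecies]
  new("CrossFeedingNetwork", activities = act, compounds = cmp,
      degradationProducts = prods, speciesGroups = grp, nMax = net@nMax)
}

.influencePipeline <- function(net, ab, partition, model = InfluenceModel(),
                               topK = Inf, threshold = 0, cutoff = "auto") {
  mat <- influenceMatrix(net, ab, partition, model = model, topK = topK)
  g <- buildInfluenceNetwork(mat, threshold = threshold)
  report <- centralityReport(g, net, cutoff = cutoff)
  list(matrix = mat, network = g, report = report,
       influencers = report$species[report$influencer])
}

#' Influencer retention under random data reduction
#'
#' Removes a fraction of the species (and, in the default mode, of the
#' small metabolites) uniformly at random, reruns the influence-matrix,
#' network and influencer stages, and reports how many of the original
#' influencers keep their influencer status. Two denominators are reported:
#' original influencers that survived the removal (`retainedPct`, the
#' headline statistic) and all original influencers (`retainedPctAll`).
#'
#' @param net a [CrossFeedingNetwork].
#' @param ab an [AbundanceTable].
#' @param partition a [SegmentPartition] (reused for the reduced rerun; the
#'   compartments are unchanged by species removal).
#' @param model,topK,threshold,cutoff pipeline settings, as in
#'   [influenceMatrix()], [buildInfluenceNetwork()] and
#'   [centralityReport()].
#' @param removalFraction fraction removed, in \[0, 1); 0 is the no-removal
#'   limit (retention 100%).
#' @param mode remove `"species_and_metabolites"` (default) or
#'   `"species_only"`.
#' @param seed integer seed; identical seeds give identical results.
#' @return a [RobustnessResult].
#' @export
robustnessSample <- function(net, ab, partition, model = InfluenceModel(),
                             topK = Inf, threshold = 0, cutoff = "auto",
                             removalFraction = 0.25,
                             mode = c("species_and_metabolites",
                                      "species_only"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (removalFraction < 0 || removalFraction >= 1)
    stop("removalFraction must lie in [0, 1)")
  orig <- .influencePipeline(net, ab, partition, model, topK, threshold, cutoff)

  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(seed)
  sp <- .speciesOf(net)
  nDrop <- round(removalFraction * length(sp))
  if (length(sp) - nDrop < 3)
    stop("removal would leave fewer than 3 species")
  keepSp <- sort(setdiff(sp, sample(sp, nDrop)))
  keepCmp <- NULL
  if (mode == "species_and_metabolites") {
    mets <- .smallMetabolites(net)
    mDrop <- round(removalFraction * length(mets))
    keepCmp <- sort(setdiff(net@compounds$compound, sample(mets, mDrop)))
  }
  if (removalFraction == 0) { keepSp <- sp; keepCmp <- NULL }

  redNet <- subsetNetwork(net, keepSpecies = keepSp, keepCompounds = keepCmp)
  redAb <- AbundanceTable(
    abundances(ab)[intersect(rownames(ab), .speciesOf(redNet)), , drop = FALSE],
    minAbundance = ab@minAbundance)
  red <- .influencePipeline(redNet, redAb, partition, model, topK,
                            threshold, cutoff)

  surviving <- intersect(orig$influencers, red$report$species)
  kept <- intersect(orig$influencers, red$influencers)
  pct <- function(num, den) if (den) 100 * num / den else NA_real_
  new("RobustnessResult",
      seed = as.integer(seed), removalFraction = removalFraction, mode = mode,
      retainedPct = pct(length(kept), length(surviving)),
      retainedPctAll = pct(length(kept), length(orig$influencers)),
      influencersOriginal = orig$influencers,
      influencersReduced = red$influencers)
}

setMethod("show", "RobustnessResult", function(object) {
  cat("RobustnessResult: seed", object@seed, ", removed",
      100 * object@removalFraction, "% (", object@mode, ")\n  retained",
      round(object@retainedPct, 1), "% of surviving original influencers (",
      round(object@retainedPctAll, 1), "% of all )\n")
})

#' Summarize robustness over several seeds
#'
#' @param net,ab,partition,model,topK,threshold,cutoff,removalFraction,mode
#'   as in [robustnessSample()].
#' @param seeds integer vector of seeds.
#' @return data.frame with one row per seed (`seed`, `retained_pct`,
#'   `retained_pct_all`, `n_influencers_original`, `n_influencers_reduced`).
#' @export
robustnessSweep <- function(net, ab, partition, model = InfluenceModel(),
                            topK = Inf, threshold = 0, cutoff = "auto",
                            removalFraction = 0.25,
                            mode = "species_and_metabolites",
                            seeds = 1:20) {
  rows <- lapply(seeds, function(s) {
    r <- robustnessSample(net, ab, partition, model, topK, threshold, cutoff,
                          removalFraction, mode, seed = s)
    data.frame(seed = s, retained_pct = r@retainedPct,
               retained_pct_all = r@retainedPctAll,
               n_influencers_original = length(r@influencersOriginal),
               n_influencers_reduced = length(r@influencersReduced))
  })
  do.call(rbind, rows)
}
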
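#' Construct a CommunitySpec
#'
#' Defaults are sized to a termite-gut-scale study community: 205 species,
#' 265 metabolites, 10 macromolecules, six compartments (C, M, P1, P3, P4,
#' P5) planned as three segments of 3, 2 and 1 compartments with decreasing
#' richness towards the rear gut, long-tailed (log-normal) abundances, and
#' one planted hub degrader feeding 80% of the community. All sizes scale
#' down for fast tests.
#'
#' @param nSpecies,nMetabolites,nMacromolecules community sizes.
#' @param guildProportions named numeric; see [CommunitySpec-class].
#' @param crossFeedingDensity,competitionDensity expected extra planted
#'   feed/compete pairs per species.
#' @param compartments compartment names in gut order.
#' @param segmentPlan planned segment of each compartment (non-decreasing
#'   integers).
#' @param segmentRichness fraction of species active per planned segment.
#' @param abundanceMeanlog,abundanceSdlog log-normal base abundance
#'   parameters.
#' @param withinSegmentNoise sd of log-scale noise between compartments of
#'   one segment.
#' @param dropoutPenalty log-scale penalty for species inactive in a
#'   segment.
#' @param plantedHub plant a hub degrader.
#' @param hubFeedFraction fraction of species fed by the hub.
#' @param pubProb,keggProb literature-count and KEGG-flag parameters.
#' @param seed integer seed driving all randomness.
#' @return a validated [CommunitySpec].
#' @export
communitySpec <- function(nSpecies = 205L, nMetabolites = 265L,
                          nMacromolecules = 10L,
                          guildProportions = c(degrader = 0.08,
                                               fermenter = 0.45,
                                               specialist = 0.20,
                                               generalist = 0.07),
                          crossFeedingDensity = 0.1,
                          competitionDensity = 0.1,
                          compartments = c("C", "M", "P1", "P3", "P4", "P5"),
                          segmentPlan = c(1L, 1L, 1L, 2L, 2L, 3L),
                          segmentRichness = c(0.95, 0.55, 0.2),
                          abundanceMeanlog = 0, abundanceSdlog = 1.5,
                          withinSegmentNoise = 0.15, dropoutPenalty = 6,
                          plantedHub = TRUE, hubFeedFraction = 0.8,
                          pubProb = 0.3, keggProb = 0.6, seed = 1L) {
  new("CommunitySpec",
      nSpecies = as.integer(nSpecies),
      nMetabolites = as.integer(nMetabolites),
      nMacromolecules = as.integer(nMacromolecules),
      guildProportions = guildProportions,
      crossFeedingDensity = crossFeedingDensity,
      competitionDensity = competitionDensity,
      compartments = compartments, segmentPlan = as.integer(segmentPlan),
      segmentRichness = segmentRichness,
      abundanceMeanlog = abundanceMeanlog, abundanceSdlog = abundanceSdlog,
      withinSegmentNoise = withinSegmentNoise,
      dropoutPenalty = dropoutPenalty,
      plantedHub = plantedHub, hubFeedFraction = hubFeedFraction,
      pubProb = pubProb, keggProb = keggProb, seed = as.integer(seed))
}

setMethod("show", "CommunitySpec", function(object) {
  cat("CommunitySpec:", object@nSpecies, "species,", object@nMetabolites,
      "metabolites,", object@nMacromolecules, "macromolecules; segments",
      paste(rle(object@segmentPlan)$lengths, collapse = "-"),
      "; seed", object@seed, "\n")
})

GH_POOL <- data.frame(
  enzyme = c("endoglucanase", "exoglucanase", "cellobiohydrolase",
             "beta-glucosidase", "endo-1,4-beta-xylanase", "beta-xylosidase",
             "alpha-l-arabinofuranosidase", "polygalacturonase",
             "alpha-amylase", "mannanase"),
  ghfamily = c("GH5", "GH6", "GH48", "GH1", "GH10", "GH43",
               "GH51", "GH28", "GH13", "GH26"),
  stringsAsFactors = FALSE)

#' Generate a synthetic community with planted ecological structure
#'
#' Builds the three pipeline inputs from a [CommunitySpec], with ground
#' truth for every planted relation:
#' * **Degraders** degrade macromolecules whose dedicated degradation
#'   products feed the imports of their fermenters (planted cross-feeding);
#'   fermenters of the same macromolecule sharing a sugar compete.
#' * **Specialist pairs** share a dedicated import (planted competition).
#' * An optional **hub degrader** degrades its own macromolecule whose
#'   sugars (one per hub group) feed `hubFeedFraction` of the community;
#'   fed species export fermentation byproducts the hub imports, so paths
#'   between fed species route through the hub.
#' * **Generalists** draw random imports/exports from a shared pool; their
#'   pairs are not labelled (excluded from sign-recovery checks).
#' * Extra feed/compete pairs are planted at the configured densities, each
#'   through a dedicated metabolite.
#'
#' Planted relations are wired through dedicated, non-overlapping
#' metabolites so that every labelled pair is purely cross-feeding, purely
#' competing, or metabolically disjoint. Per-edge literature counts are
#' geometric and KEGG flags Bernoulli so that confidence scoring is
#' exercised. Abundances are log-normal; each planned segment has its own
#' active species set (fraction `segmentRichness`), compartments within a
#' segment share that set up to small log-scale noise, which is what the
#' Kruskal--Wallis partitioning recovers.
#'
#' @param spec a [CommunitySpec].
#' @return list with `network` ([CrossFeedingNetwork]), `abundance`
#'   ([AbundanceTable]), `enzymes` (annotation data.frame) and `truth`
#'   (list: `feed` and `compete` pair data.frames, `unlabeled` species,
#'   `hub`, `guilds`, `segmentPlan`).
#' @export
generateCommunity <- function(spec) {
  validObject(spec)
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(spec@seed)

  n <- spec@nSpecies
  sp <- sprintf("sp%03d", seq_len(n))
  p <- spec@guildProportions
  nDeg <- max(if (spec@nMacromolecules > 0) 1L else 0L, round(p["degrader"] * n))
  nFer <- round(p["fermenter"] * n)
  nSpc <- 2L * (round(p["specialist"] * n) %/% 2L)
  nGen <- round(p["generalist"] * n)
  if (nDeg + nFer + nSpc + nGen > n)
    stop("guild counts exceed nSpecies")
  degraders <- sp[seq_len(nDeg)]
  fermenters <- sp[nDeg + seq_len(nFer)]
  specialists <- sp[nDeg + nFer + seq_len(nSpc)]
  generalists <- sp[nDeg + nFer + nSpc + seq_len(nGen)]
  guilds <- stats::setNames(rep("plain", n), sp)
  guilds[degraders] <- "degrader"; guilds[fermenters] <- "fermenter"
  guilds[specialists] <- "specialist"; guilds[generalists] <- "generalist"
  hub <- if (spec@plantedHub && nDeg > 0) degraders[1] else NA_character_

  byproducts <- c("acetate", "ethanol", "lactate", "h2", "co2", "propionate")
  nFed <- if (!is.na(hub)) round(spec@hubFeedFraction * n) else 0L
  hubGroupSize <- 4L
  nHubSugar <- if (nFed) ceiling(nFed / hubGroupSize) else 0L
  nMacro <- spec@nMacromolecules
  nRegMacro <- max(nMacro - as.integer(!is.na(hub)), 0L)
  sugarsPerMacro <- 3L
  nExtraFeed <- round(spec@crossFeedingDensity * n)
  nExtraComp <- round(spec@competitionDensity * n)
  # private imports for non-hub degraders and unguilded species only
  regDeg <- setdiff(degraders, hub)
  plain <- sp[guilds == "plain"]
  privateOwners <- c(regDeg, plain)
  nPrivate <- length(privateOwners)

  need <- length(byproducts) + nHubSugar + nRegMacro * sugarsPerMacro +
    nSpc / 2 + nExtraFeed + nExtraComp + nPrivate
  if (need > spec@nMetabolites)
    stop("infeasible spec: needs at least ", need, " metabolites, has ",
         spec@nMetabolites)

  pool <- sprintf("met%04d", seq_len(spec@nMetabolites - length(byproducts)))
  take <- local({
    i <- 0L
    function(k) { out <- pool[i + seq_len(k)]; i <<- i + k; out }
  })
  hubSugars <- take(nHubSugar)
  macroSugars <- if (nRegMacro) split(take(nRegMacro * sugarsPerMacro),
                                      rep(seq_len(nRegMacro),
                                          each = sugarsPerMacro)) else list()
  pairMets <- take(nSpc / 2)
  extraFeedMets <- take(nExtraFeed)
  extraCompMets <- take(nExtraComp)
  privateMets <- stats::setNames(take(nPrivate), privateOwners)
  generalPool <- setdiff(pool, c(hubSugars, unlist(macroSugars), pairMets,
                                 extraFeedMets, extraCompMets, privateMets))

  rows <- list()
  feed <- list(); compete <- list()
  addRow <- function(species, compound, activity)
    rows[[length(rows) + 1L]] <<- data.frame(
      species = species, compound = compound, activity = activity,
      stringsAsFactors = FALSE)
  addFeed <- function(from, to, met)
    feed[[length(feed) + 1L]] <<- data.frame(from = from, to = to, met = met,
                                             stringsAsFactors = FALSE)
  addCompete <- function(a, b, met)
    compete[[length(compete) + 1L]] <<- data.frame(a = a, b = b, met = met,
                                                   stringsAsFactors = FALSE)

  macroNames <- character(); macroProducts <- list()
  # regular macromolecules and their degraders
  if (nRegMacro && length(regDeg)) {
    macroNames <- sprintf("macro%02d", seq_len(nRegMacro))
    macroProducts[macroNames] <- macroSugars
    for (i in seq_along(regDeg)) {
      m <- macroNames[((i - 1L) %% nRegMacro) + 1L]
      addRow(regDeg[i], m, "degrades")
    }
  }
  # hub macromolecule
  if (!is.na(hub)) {
    macroNames <- c(macroNames, "macrohub")
    macroProducts[["macrohub"]] <- hubSugars
    addRow(hub, "macrohub", "degrades")
    for (b in byproducts) addRow(hub, b, "import")
  }
  # private imports for degraders and plain species
  for (s in privateOwners) addRow(s, privateMets[[s]], "import")

  # fermenters: import sugars of their macromolecule, export a byproduct
  degOfMacro <- if (nRegMacro && length(regDeg))
    split(regDeg, macroNames[((seq_along(regDeg) - 1L) %% nRegMacro) + 1L])
  else list()
  if (length(fermenters) && nRegMacro && length(regDeg)) {
    fermSugars <- list()
    fermMacro <- character(length(fermenters))
    for (i in seq_along(fermenters)) {
      f <- fermenters[i]
      m <- macroNames[((i - 1L) %% nRegMacro) + 1L]
      fermMacro[i] <- m
      sug <- sample(macroProducts[[m]], sample(1:2, 1))
      fermSugars[[f]] <- sug
      for (s in sug) addRow(f, s, "import")
      bp <- sample(byproducts, 1)
      addRow(f, bp, "export")
      for (d in degOfMacro[[m]]) for (s in sug) addFeed(d, f, s)
      if (!is.na(hub)) addFeed(f, hub, bp)
    }
    # fermenters of one macromolecule sharing a sugar compete for it
    for (m in unique(fermMacro)) {
      fs <- fermenters[fermMacro == m]
      if (length(fs) < 2) next
      prs <- utils::combn(fs, 2)
      for (j in seq_len(ncol(prs))) {
        shared <- intersect(fermSugars[[prs[1, j]]], fermSugars[[prs[2, j]]])
        for (s in shared) addCompete(prs[1, j], prs[2, j], s)
      }
    }
  } else if (length(fermenters)) {
    for (f in fermenters) {
      bp <- sample(byproducts, 1)
      addRow(f, bp, "export")
      if (!is.na(hub)) addFeed(f, hub, bp)
    }
  }

  # specialists: dedicated shared import per pair
  if (nSpc) {
    for (k in seq_len(nSpc / 2)) {
      a <- specialists[2 * k - 1]; b <- specialists[2 * k]
      addRow(a, pairMets[k], "import"); addRow(b, pairMets[k], "import")
      addCompete(a, b, pairMets[k])
    }
  }

  # hub feeding: groups of species importing one hub sugar each; fed
  # species export a byproduct (the hub imports all byproducts)
  fed <- character()
  if (nFed) {
    fed <- sample(setdiff(sp, hub), nFed)
    grp <- rep(seq_len(nHubSugar), each = hubGroupSize, length.out = nFed)
    for (i in seq_along(fed)) {
      f <- fed[i]
      addRow(f, hubSugars[grp[i]], "import")
      addFeed(hub, f, hubSugars[grp[i]])
      if (guilds[f] %in% c("plain", "specialist", "degrader")) {
        bp <- sample(byproducts, 1)
        addRow(f, bp, "export")
        addFeed(f, hub, bp)
      }
    }
    for (g in unique(grp)) {
      members <- fed[grp == g]
      if (length(members) > 1) {
        prs <- utils::combn(members, 2)
        for (j in seq_len(ncol(prs)))
          addCompete(prs[1, j], prs[2, j], hubSugars[g])
      }
    }
  }

  # extra planted relations at the configured densities
  labeledPool <- setdiff(sp, generalists)
  if (nExtraFeed && length(labeledPool) > 1) {
    for (k in seq_len(nExtraFeed)) {
      pq <- sample(labeledPool, 2)
      addRow(pq[1], extraFeedMets[k], "export")
      addRow(pq[2], extraFeedMets[k], "import")
      addFeed(pq[1], pq[2], extraFeedMets[k])
    }
  }
  if (nExtraComp && length(labeledPool) > 1) {
    for (k in seq_len(nExtraComp)) {
      pq <- sample(labeledPool, 2)
      addRow(pq[1], extraCompMets[k], "import")
      addRow(pq[2], extraCompMets[k], "import")
      addCompete(pq[1], pq[2], extraCompMets[k])
    }
  }

  # generalists: random imports/exports from the shared general pool
  if (length(generalists) && length(generalPool) > 1) {
    for (g in generalists) {
      im <- sample(generalPool, min(3, length(generalPool)))
      for (m in im) addRow(g, m, "import")
      ex <- sample(generalPool, min(2, length(generalPool)))
      for (m in ex) addRow(g, m, "export")
    }
  }

  act <- do.call(rbind, rows)
  act$n_publications <- stats::rgeom(nrow(act), spec@pubProb)
  act$kegg_flag <- stats::rbinom(nrow(act), 1, spec@keggProb)

  cmpTable <- data.frame(
    compound = c(macroNames,
                 setdiff(unique(c(act$compound, unlist(macroProducts))),
                         macroNames)),
    stringsAsFactors = FALSE)
  cmpTable$class <- ifelse(cmpTable$compound %in% macroNames,
                           "MACROMOLECULE", "SMALL_METABOLITE")
  cmpTable$degradation_products <- vapply(cmpTable$compound, function(m)
    paste(macroProducts[[m]], collapse = ";"), character(1))

  groups <- data.frame(species = sp, group = unname(guilds[sp]),
                       stringsAsFactors = FALSE)
  net <- makeCrossFeedingNetwork(act, cmpTable, groups)

  # ---- enzyme annotations for degraders --------------------------------
  degRows <- act[act$activity == "degrades", , drop = FALSE]
  enz <- if (nrow(degRows)) do.call(rbind, lapply(seq_len(nrow(degRows)),
    function(i) {
      k <- sample(nrow(GH_POOL), sample(1:3, 1))
      data.frame(species = degRows$species[i],
                 enzyme = GH_POOL$enzyme[k], ghfamily = GH_POOL$ghfamily[k],
                 substrate = degRows$compound[i],
                 source = sample(ENZYME_SOURCES, length(k), replace = TRUE),
                 frequency = round(stats::runif(length(k), 2.7, 9), 2),
                 hits = sample(7:40, length(k), replace = TRUE),
                 stringsAsFactors = FALSE)
    })) else data.frame(species = character(), enzyme = character(),
                        ghfamily = character(), substrate = character(),
                        source = character(), frequency = numeric(),
                        hits = numeric(), stringsAsFactors = FALSE)
  rownames(enz) <- NULL

  # ---- abundances ------------------------------------------------------
  segOfComp <- spec@segmentPlan
  nSeg <- length(unique(segOfComp))
  z <- stats::rnorm(n, spec@abundanceMeanlog, spec@abundanceSdlog)
  names(z) <- sp
  if (!is.na(hub)) z[hub] <- spec@abundanceMeanlog + 3 * spec@abundanceSdlog
  active <- matrix(FALSE, n, nSeg, dimnames = list(sp, NULL))
  for (k in seq_len(nSeg))
    active[, k] <- stats::runif(n) < spec@segmentRichness[k]
  if (!is.na(hub)) active[hub, ] <- TRUE
  active[rowSums(active) == 0, sample(nSeg, 1)] <- TRUE
  ab <- matrix(0, n, length(spec@compartments),
               dimnames = list(sp, spec@compartments))
  for (j in seq_along(spec@compartments)) {
    k <- segOfComp[j]
    lw <- z - spec@dropoutPenalty * (1 - active[, k]) +
      stats::rnorm(n, 0, spec@withinSegmentNoise)
    w <- exp(lw)
    ab[, j] <- 100 * w / sum(w)
  }
  abundance <- AbundanceTable(ab, minAbundance = 0.02)

  feed <- if (length(feed)) unique(do.call(rbind, feed)) else
    data.frame(from = character(), to = character(), met = character())
  compete <- if (length(compete)) unique(do.call(rbind, compete)) else
    data.frame(a = character(), b = character(), met = character())

  list(network = net, abundance = abundance, enzymes = enz,
       truth = list(feed = feed, compete = compete,
                    unlabeled = generalists, hub = hub,
                    guilds = guilds, segmentPlan = segOfComp,
                    fed = fed))
}

#' Planted pairwise sign matrix from generator ground truth
#'
#' Expected sign of the influence score for every ordered species pair:
#' +1 for purely cross-feeding pairs, -1 for purely competing pairs, 0 for
#' labelled pairs with no planted relation; NA (degenerate, excluded from
#' recovery checks) for pairs with both relations or involving unlabeled
#' species.
#'
#' @param truth the `truth` element of [generateCommunity()]'s result.
#' @param species character vector of all species.
#' @return integer matrix with NA diagonal.
#' @export
plantedSignMatrix <- function(truth, species) {
  m <- matrix(0L, length(species), length(species),
              dimnames = list(species, species))
  fd <- truth$feed; cp <- truth$compete
  F <- matrix(FALSE, length(species), length(species),
              dimnames = dimnames(m))
  C <- F
  if (nrow(fd)) F[cbind(fd$from, fd$to)] <- TRUE
  if (nrow(cp)) {
    C[cbind(cp$a, cp$b)] <- TRUE
    C[cbind(cp$b, cp$a)] <- TRUE
  }
  m[F & !C] <- 1L
  m[C & !F] <- -1L
  m[F & C] <- NA_integer_
  if (length(truth$unlabeled)) {
    m[truth$unlabeled, ] <- NA_integer_
    m[, truth$unlabeled] <- NA_integer_
  }
  diag(m) <- NA_integer_
  m
}

#' Write synthetic community inputs to a directory
#'
#' Emits the three delimited inputs (activity, compound, abundance, enzyme
#' tables and group labels) plus a ground-truth JSON.
#'
#' @param community result of [generateCommunity()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCommunity <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- community$network
  act <- net@activities
  .writeTSV(act[, c("species", "compound", "activity", "n_publications",
                    "kegg_flag")], file.path(dir, "activities.tsv"))
  cmp <- net@compounds
  cmp$degradation_products <- vapply(cmp$compound, function(m)
    paste(net@degradationProducts[[m]], collapse = ";"), character(1))
  names(cmp)[names(cmp) == "klass"] <- "class"
  .writeTSV(cmp, file.path(dir, "compounds.tsv"))
  a <- abundances(community$abundance)
  .writeTSV(data.frame(species = rownames(a), a, check.names = FALSE),
            file.path(dir, "abundance.tsv"))
  .writeTSV(community$enzymes, file.path(dir, "enzymes.tsv"))
  .writeTSV(data.frame(species = names(community$truth$guilds),
                       group = unname(community$truth$guilds)),
            file.path(dir, "groups.tsv"))
  jsonlite::write_json(community$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
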
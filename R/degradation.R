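ENZYME_SOURCES <- c("CAZY", "DBCAN2_HOTPEP", "CURATED")

#' Load and filter a glycoside-hydrolase annotation table
#'
#' Columns: `species, enzyme, ghfamily, substrate, source, frequency, hits`.
#' Rows sourced from dbCAN2/Hotpep are screened with the standard peptide
#' filters (frequency > 2.6 and hits > 6); CAZy- and literature-curated rows
#' pass unfiltered. The filter is idempotent.
#'
#' @param x path to a delimited table, or a data.frame.
#' @param enforceFilters apply the Hotpep thresholds (default TRUE).
#' @return data.frame of enzyme annotations with normalized species and
#'   substrate names.
#' @export
loadEnzymeTable <- function(x, enforceFilters = TRUE) {
  d <- if (is.character(x)) .readTable(x) else as.data.frame(x)
  need <- c("species", "enzyme", "substrate", "source")
  if (!all(need %in% names(d)))
    stop("enzyme table must have columns: ", paste(need, collapse = ", "))
  if (is.null(d$ghfamily)) d$ghfamily <- NA_character_
  if (is.null(d$frequency)) d$frequency <- NA_real_
  if (is.null(d$hits)) d$hits <- NA_real_
  d$species <- .normalizeSpecies(d$species)
  d$substrate <- normalizeCompound(d$substrate)
  d$source <- toupper(trimws(d$source))
  bad <- setdiff(unique(d$source), ENZYME_SOURCES)
  if (length(bad)) stop("unknown enzyme source(s): ", paste(bad, collapse = ", "))
  if (enforceFilters) {
    hp <- d$source == "DBCAN2_HOTPEP"
    keep <- !hp | (!is.na(d$frequency) & !is.na(d$hits) &
                     d$frequency > 2.6 & d$hits > 6)
    d <- d[keep, , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Select influential lignocellulose degraders
#'
#' Influencers of a centrality report that carry DEGRADES activities
#' (optionally restricted to a substrate class such as cellulose,
#' hemicellulose, pectin), ranked by betweenness centrality.
#'
#' @param report a centrality report from [centralityReport()].
#' @param net a [CrossFeedingNetwork].
#' @param substrates optional character vector of macromolecule names; NULL
#'   accepts any degraded macromolecule.
#' @param topN optional cap on the ranked list.
#' @return data.frame: `species`, `betweenness`, `substrates` (semicolon
#'   separated), ordered by decreasing centrality.
#' @export
selectDegraders <- function(report, net, substrates = NULL, topN = NULL) {
  act <- net@activities
  deg <- act[act$activity == "DEGRADES", , drop = FALSE]
  if (!is.null(substrates))
    deg <- deg[deg$compound %in% normalizeCompound(substrates), , drop = FALSE]
  infl <- report[report$influencer & report$species %in% deg$species, ,
                 drop = FALSE]
  infl <- infl[order(-infl$betweenness, infl$species), , drop = FALSE]
  if (!is.null(topN)) infl <- utils::head(infl, topN)
  subs <- vapply(infl$species, function(s)
    paste(sort(unique(deg$compound[deg$species == s])), collapse = ";"),
    character(1))
  data.frame(species = infl$species, betweenness = infl$betweenness,
             substrates = unname(subs), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Assemble the lignocellulose degradation network
#'
#' Joins the selected degraders with their extracellular enzymes and the
#' community's metabolite flow: degrader --secretes--> enzyme
#' --hydrolyzes--> macromolecule --yields--> small metabolite
#' --consumes--> fermenter --excretes--> fermentation byproduct. Consumes
#' and excretes edges inherit the confidence score of the underlying
#' import/export activity; enzyme-derived edges default to mid-scale (50);
#' yields edges carry the best confidence among the macromolecule's
#' DEGRADES activities.
#'
#' @param degraders character vector of degrader species, or the data.frame
#'   from [selectDegraders()].
#' @param enzymes enzyme annotation table (see [loadEnzymeTable()]).
#' @param net a [CrossFeedingNetwork].
#' @param fermenters optional character vector; by default, species that
#'   import one of the yielded sugars and explicitly export a fermentation
#'   product.
#' @param products fermentation-product list for the excretes edges.
#' @return a [DegradationNetwork]. A degrader absent from the enzyme table
#'   is kept as a node without enzyme edges, with a warning.
#' @export
buildDegradationNetwork <- function(degraders, enzymes, net,
                                    fermenters = NULL,
                                    products = fermentationProducts()) {
  if (is.data.frame(degraders)) degraders <- degraders$species
  degraders <- .normalizeSpecies(degraders)
  enzymes <- loadEnzymeTable(enzymes)
  act <- net@activities
  products <- normalizeCompound(products)

  nodes <- data.frame(name = degraders, type = "degrader",
                      stringsAsFactors = FALSE)
  edges <- list()
  addEdge <- function(from, to, type, confidence)
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, confidence = confidence,
      stringsAsFactors = FALSE)
  addNodes <- function(name, type) {
    new <- setdiff(name, nodes$name)
    if (length(new))
      nodes <<- rbind(nodes, data.frame(name = new, type = type,
                                        stringsAsFactors = FALSE))
  }

  enz <- enzymes[enzymes$species %in% degraders, , drop = FALSE]
  missing <- setdiff(degraders, enz$species)
  if (length(missing))
    warning("degrader(s) without enzyme annotation: ",
            paste(missing, collapse = ", "))

  macros <- character()
  if (nrow(enz)) {
    # one enzyme node per enzyme name; secretes and hydrolyzes edges
    addNodes(unique(enz$enzyme), "enzyme")
    addNodes(unique(enz$substrate), "macromolecule")
    macros <- unique(enz$substrate)
    for (i in seq_len(nrow(enz))) {
      addEdge(enz$species[i], enz$enzyme[i], "secretes", 50)
      addEdge(enz$enzyme[i], enz$substrate[i], "hydrolyzes", 50)
    }
  }
  # macromolecules degraded by the selected degraders (even if unannotated)
  deg <- act[act$activity == "DEGRADES" & act$species %in% degraders, ,
             drop = FALSE]
  addNodes(unique(deg$compound), "macromolecule")
  macros <- union(macros, unique(deg$compound))

  yields <- character()
  degAll <- act[act$activity == "DEGRADES", , drop = FALSE]
  for (m in macros) {
    prods <- net@degradationProducts[[m]]
    if (is.null(prods) || !length(prods)) next
    conf <- degAll$confidence[degAll$compound == m]
    conf <- if (length(conf)) max(conf) else 50
    addNodes(prods, "small_metabolite")
    for (p in prods) addEdge(m, p, "yields", conf)
    yields <- union(yields, prods)
  }

  imp <- act[act$activity %in% c("IMPORT", "BOTH") &
               act$compound %in% yields, , drop = FALSE]
  if (is.null(fermenters)) {
    expF <- act$species[act$activity %in% c("EXPORT", "BOTH") &
                          act$compound %in% products]
    fermenters <- setdiff(intersect(unique(imp$species), unique(expF)),
                          degraders)
  } else fermenters <- .normalizeSpecies(fermenters)

  if (length(fermenters)) {
    addNodes(fermenters, "fermenter")
    impF <- imp[imp$species %in% fermenters, , drop = FALSE]
    for (i in seq_len(nrow(impF)))
      addEdge(impF$compound[i], impF$species[i], "consumes",
              impF$confidence[i])
    exc <- act[act$species %in% fermenters &
                 act$activity %in% c("EXPORT", "BOTH") &
                 act$compound %in% products, , drop = FALSE]
    addNodes(unique(exc$compound), "small_metabolite")
    for (i in seq_len(nrow(exc)))
      addEdge(exc$species[i], exc$compound[i], "excretes", exc$confidence[i])
  }

  e <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(from = character(), to = character(), type = character(),
               confidence = numeric(), stringsAsFactors = FALSE)
  rownames(e) <- NULL
  new("DegradationNetwork", nodes = nodes, edges = e)
}

#' @rdname accessors
setMethod("edges", "DegradationNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("nodes", "DegradationNetwork", function(x) x@nodes)

setMethod("show", "DegradationNetwork", function(object) {
  nt <- table(object@nodes$type)
  et <- table(object@edges$type)
  cat("DegradationNetwork:",
      paste(names(nt), nt, sep = ":", collapse = ", "), "\n  edges:",
      paste(names(et), et, sep = ":", collapse = ", "), "\n")
})
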
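# Brandes' accumulation for betweenness on a directed, unweighted graph.
# adj: list of integer out-neighbour vectors, n nodes. Returns the raw sum
# over (x, y) pairs of sigma_xy(p) / sigma_xy.
.brandesBetweenness <- function(adj, n) {
  cb <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order <- c(order, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb
}

# weakly connected component sizes per node
.weakComponentSizes <- function(adj, n) {
  und <- vector("list", n)
  for (v in seq_len(n)) for (w in adj[[v]]) {
    und[[v]] <- c(und[[v]], w); und[[w]] <- c(und[[w]], v)
  }
  comp <- rep(0L, n); k <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    k <- k + 1L
    queue <- s; comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in und[[v]]) if (!comp[w]) { comp[w] <- k; queue <- c(queue, w) }
    }
  }
  sizes <- tabulate(comp)
  sizes[comp]
}

.adjFromEdges <- function(from, to, nodeNames) {
  n <- length(nodeNames)
  adj <- rep(list(integer()), n)
  if (length(from)) {
    fi <- match(from, nodeNames); ti <- match(to, nodeNames)
    for (i in seq_along(fi)) adj[[fi[i]]] <- c(adj[[fi[i]]], ti[i])
    adj <- lapply(adj, unique)
  }
  adj
}

#' Betweenness centrality with component-wise normalization
#'
#' `C_b(p) = sum over x != p != y of sigma_xy(p) / sigma_xy, divided by
#' (P - 1)(P - 2) / 2`, where `sigma_xy` counts shortest directed paths from
#' x to y, `sigma_xy(p)` those passing through p, and P is the number of
#' nodes of the (weakly) connected component p belongs to. Pairs with no
#' connecting path contribute 0; all shortest paths are counted (no
#' arbitrary tie-breaking). The default divisor is the undirected-graph
#' constant applied to the directed path sums; `normalization = "directed"`
#' uses `(P - 1)(P - 2)` (half the value) and `"none"` returns the raw sums.
#'
#' @param x an [InfluenceNetwork], or a data.frame of directed edges with
#'   columns `from`, `to`.
#' @param nodeNames for the data.frame method, optional character vector of
#'   all nodes (including isolated ones).
#' @param normalization `"component"` (default), `"directed"`, or `"none"`.
#' @return named numeric vector of centralities. Under the default
#'   normalization a directed graph can reach 2 (the divisor is the
#'   undirected pair count); the `"directed"` divisor bounds values by 1.
#' @export
setGeneric("betweennessCentrality",
           function(x, ...) standardGeneric("betweennessCentrality"))

#' @rdname betweennessCentrality
setMethod("betweennessCentrality", "InfluenceNetwork",
  function(x, normalization = c("component", "directed", "none")) {
    .betweenness(x@edges$from, x@edges$to, x@nodes$species,
                 match.arg(normalization))
  })

#' @rdname betweennessCentrality
setMethod("betweennessCentrality", "data.frame",
  function(x, nodeNames = NULL,
           normalization = c("component", "directed", "none")) {
    if (is.null(nodeNames)) nodeNames <- sort(unique(c(x$from, x$to)))
    .betweenness(x$from, x$to, nodeNames, match.arg(normalization))
  })

.betweenness <- function(from, to, nodeNames, normalization = "component") {
  n <- length(nodeNames)
  if (!n) return(stats::setNames(numeric(0), character(0)))
  adj <- .adjFromEdges(from, to, nodeNames)
  raw <- .brandesBetweenness(adj, n)
  if (normalization == "none") return(stats::setNames(raw, nodeNames))
  P <- .weakComponentSizes(adj, n)
  denom <- (P - 1) * (P - 2)
  scale <- if (normalization == "component") 2 else 1
  cb <- ifelse(denom > 0, raw / denom * scale, 0)
  stats::setNames(cb, nodeNames)
}

#' Identify network influencers from centrality values
#'
#' @param cb named numeric vector of betweenness centralities (or a
#'   centrality report data.frame with columns `species`, `betweenness`).
#' @param cutoff numeric cutoff, or `"auto"` for the mean centrality; nodes
#'   strictly above the cutoff are influencers.
#' @return list: `influencers` (character), `cutoff`, `fraction_pct`
#'   (percent of nodes that are influencers).
#' @export
identifyInfluencers <- function(cb, cutoff = "auto") {
  if (is.data.frame(cb)) cb <- stats::setNames(cb$betweenness, cb$species)
  if (identical(cutoff, "auto")) cutoff <- mean(cb)
  infl <- names(cb)[cb > cutoff]
  list(influencers = infl, cutoff = cutoff,
       fraction_pct = 100 * length(infl) / max(length(cb), 1))
}

#' Default fermentation byproducts
#'
#' @return character vector of the fermentation end products used to flag
#'   fermentative species.
#' @export
fermentationProducts <- function()
  c("acetate", "ethanol", "butanol", "lactate", "h2", "co2")

.classifySpecies <- function(species, net,
                             products = fermentationProducts()) {
  act <- net@activities
  products <- normalizeCompound(products)
  degraders <- unique(act$species[act$activity == "DEGRADES"])
  fermenters <- unique(act$species[
    act$activity %in% c("EXPORT", "BOTH") & act$compound %in% products])
  d <- species %in% degraders
  f <- species %in% fermenters
  ifelse(d & f, "BOTH", ifelse(d, "DEGRADER", ifelse(f, "FERMENTER", "OTHER")))
}

#' Functional classification of influencers
#'
#' `DEGRADER`: degrades macromolecules without exporting fermentation
#' products; `FERMENTER`: explicitly exports a fermentation product (by
#' default acetate, ethanol, butanol, lactate, H2, CO2) without degrading;
#' `BOTH`: does both; `OTHER`: neither. Fermentation status is judged on
#' explicit exports, not on inherited degradation products.
#'
#' @param influencers character vector of species (subset of the network).
#' @param net a [CrossFeedingNetwork].
#' @param products fermentation-product list.
#' @return list: `classes` (named character) and `fractions_pct` (named
#'   numeric over DEGRADER/FERMENTER/BOTH/OTHER).
#' @export
classifyInfluencers <- function(influencers, net,
                                products = fermentationProducts()) {
  influencers <- .normalizeSpecies(influencers)
  miss <- setdiff(influencers, .speciesOf(net))
  if (length(miss))
    stop("influencers not in network: ", paste(miss, collapse = ", "))
  cls <- stats::setNames(.classifySpecies(influencers, net, products),
                         influencers)
  lv <- c("DEGRADER", "FERMENTER", "BOTH", "OTHER")
  frac <- 100 * table(factor(cls, levels = lv)) / max(length(cls), 1)
  list(classes = cls, fractions_pct = stats::setNames(as.numeric(frac), lv))
}

#' Per-node centrality report of an influence network
#'
#' @param g an [InfluenceNetwork].
#' @param net optional [CrossFeedingNetwork] for functional classification.
#' @param cutoff influencer cutoff (`"auto"` = mean betweenness).
#' @param normalization passed to [betweennessCentrality()].
#' @return data.frame with one row per node: `species`, `segment`,
#'   `out_degree`, `betweenness`, `influencer`, `positive_influence_pct` and
#'   `negative_influence_pct` (percent of the other nodes receiving a
#'   positive / negative edge from the node), and `functional_class` when
#'   `net` is given.
#' @export
centralityReport <- function(g, net = NULL, cutoff = "auto",
                             normalization = "component") {
  sp <- g@nodes$species
  cb <- betweennessCentrality(g, normalization = normalization)
  e <- g@edges
  outd <- table(factor(e$from, levels = sp))
  posN <- table(factor(e$from[e$sign > 0], levels = sp))
  negN <- table(factor(e$from[e$sign < 0], levels = sp))
  denom <- max(length(sp) - 1, 1)
  rep <- data.frame(
    species = sp,
    segment = g@nodes$segment,
    out_degree = as.integer(outd[sp]),
    betweenness = unname(cb[sp]),
    positive_influence_pct = 100 * as.integer(posN[sp]) / denom,
    negative_influence_pct = 100 * as.integer(negN[sp]) / denom,
    stringsAsFactors = FALSE)
  infl <- identifyInfluencers(stats::setNames(rep$betweenness, rep$species),
                              cutoff = cutoff)
  rep$influencer <- rep$species %in% infl$influencers
  if (!is.null(net))
    rep$functional_class <- .classifySpecies(rep$species, net)
  attr(rep, "cutoff") <- infl$cutoff
  rep
}

#' Segment-wise byproduct production and consumption profile
#'
#' For every segment of the influence network, the percentage of that
#' segment's species that (effectively) produce and that consume each
#' metabolite; the five most commonly exported byproducts per segment are
#' ranked.
#'
#' @param g an [InfluenceNetwork] whose nodes carry segment labels.
#' @param net a [CrossFeedingNetwork].
#' @return data.frame: `segment`, `compound`, `producer_pct`,
#'   `consumer_pct`, `producer_rank` (NA outside the top 5).
#' @export
segmentByproductProfile <- function(g, net) {
  imp <- importMatrix(net)
  exp <- effectiveExportMatrix(net)
  out <- list()
  for (s in sort(unique(g@nodes$segment))) {
    sp <- intersect(g@nodes$species[g@nodes$segment == s], rownames(imp))
    if (!length(sp)) next
    prod <- 100 * colMeans(exp[sp, , drop = FALSE])
    cons <- 100 * colMeans(imp[sp, , drop = FALSE])
    keep <- prod > 0 | cons > 0
    d <- data.frame(segment = s, compound = names(prod)[keep],
                    producer_pct = unname(prod[keep]),
                    consumer_pct = unname(cons[keep]),
                    stringsAsFactors = FALSE)
    d <- d[order(-d$producer_pct, d$compound), , drop = FALSE]
    d$producer_rank <- NA_integer_
    top <- which(d$producer_pct > 0)[seq_len(min(5, sum(d$producer_pct > 0)))]
    d$producer_rank[top] <- seq_along(top)
    out[[s]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
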
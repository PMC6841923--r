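# Shared fixtures and independent oracles for the test suite.

# Two-species toy: A imports glucose / exports acetate, B degrades cellulose
# into glucose.
toyNetwork <- function() {
  act <- data.frame(
    species = c("A", "A", "B"),
    compound = c("glucose", "acetate", "cellulose"),
    activity = c("import", "export", "degrades"),
    n_publications = c(2L, 1L, 4L),
    kegg_flag = c(1L, 0L, 1L))
  cmp <- data.frame(
    compound = c("glucose", "acetate", "cellulose"),
    class = c("SMALL_METABOLITE", "SMALL_METABOLITE", "MACROMOLECULE"),
    degradation_products = c("", "", "glucose"))
  makeCrossFeedingNetwork(act, cmp)
}

# Degrader feeding two fermenters that compete for glucose.
triadNetwork <- function() {
  act <- data.frame(
    species = c("deg", "f1", "f1", "f2", "f2"),
    compound = c("cellulose", "glucose", "acetate", "glucose", "ethanol"),
    activity = c("degrades", "import", "export", "import", "export"))
  cmp <- data.frame(
    compound = c("cellulose", "glucose", "acetate", "ethanol"),
    class = c("MACROMOLECULE", rep("SMALL_METABOLITE", 3)),
    degradation_products = c("glucose", "", "", ""))
  makeCrossFeedingNetwork(act, cmp)
}

flatAbundance <- function(species, compartments = c("C", "M", "P1"),
                          value = 1) {
  m <- matrix(value, length(species), length(compartments),
              dimnames = list(species, compartments))
  AbundanceTable(m)
}

# Brute-force betweenness oracle: exhaustive enumeration of all shortest
# directed paths (DFS bounded by BFS distance), normalized per the
# component rule. Independent of the production Brandes implementation.
bruteBetweenness <- function(edges, nodes,
                             normalization = c("component", "none")) {
  normalization <- match.arg(normalization)
  n <- length(nodes)
  adj <- lapply(nodes, function(v)
    unique(edges$to[edges$from == v]))
  names(adj) <- nodes
  bfsDist <- function(s) {
    d <- stats::setNames(rep(Inf, n), nodes); d[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) if (!is.finite(d[w])) {
        d[w] <- d[v] + 1; q <- c(q, w)
      }
    }
    d
  }
  raw <- stats::setNames(numeric(n), nodes)
  for (x in nodes) {
    d <- bfsDist(x)
    for (y in nodes) {
      if (x == y || !is.finite(d[y])) next
      # enumerate all paths x -> y of length d[y]
      paths <- list()
      dfs <- function(path) {
        v <- path[length(path)]
        if (v == y) { paths[[length(paths) + 1]] <<- path; return() }
        if (length(path) - 1 >= d[y]) return()
        for (w in adj[[v]])
          if (d[w] == length(path) && !(w %in% path)) dfs(c(path, w))
      }
      dfs(x)
      sigma <- length(paths)
      if (!sigma) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tt <- table(inner) / sigma
        raw[names(tt)] <- raw[names(tt)] + as.numeric(tt)
      }
    }
  }
  if (normalization == "none") return(raw)
  # weak component sizes
  und <- lapply(nodes, function(v)
    unique(c(adj[[v]], nodes[vapply(nodes, function(w)
      v %in% adj[[w]], logical(1))])))
  names(und) <- nodes
  compSize <- stats::setNames(integer(n), nodes)
  seen <- character()
  for (s in nodes) {
    if (s %in% seen) next
    comp <- s; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in und[[v]]) if (!(w %in% comp)) { comp <- c(comp, w); q <- c(q, w) }
    }
    compSize[comp] <- length(comp)
    seen <- c(seen, comp)
  }
  denom <- (compSize - 1) * (compSize - 2)
  ifelse(denom > 0, raw / denom * 2, 0)
}

randomDigraph <- function(nNodes, pEdge = 0.3) {
  nodes <- letters[seq_len(nNodes)]
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < pEdge
  pairs[keep, , drop = FALSE]
}

smallCommunitySpec <- function(seed, nSpecies = 60L, nMetabolites = 110L,
                               ...) {
  communitySpec(nSpecies = nSpecies, nMetabolites = nMetabolites,
                nMacromolecules = 4L, seed = seed, ...)
}
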
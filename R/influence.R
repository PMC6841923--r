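#' Construct an InfluenceModel
#'
#' @param abundanceMode `"segment"` or `"global"`; see
#'   [InfluenceModel-class].
#' @param normalization `"import"` (average metabolite contributions over
#'   the influenced species' import set) or `"none"`.
#' @param confidenceWeighting weight each metabolite term by the confidence
#'   (0--1) of q's import edge.
#' @return an [InfluenceModel].
#' @export
InfluenceModel <- function(abundanceMode = c("segment", "global"),
                           normalization = c("import", "none"),
                           confidenceWeighting = FALSE) {
  new("InfluenceModel",
      abundanceMode = match.arg(abundanceMode),
      normalization = match.arg(normalization),
      confidenceWeighting = confidenceWeighting)
}

setMethod("show", "InfluenceModel", function(object) {
  cat("InfluenceModel: abundance =", object@abundanceMode,
      "| normalization =", object@normalization,
      "| confidence weighting =", object@confidenceWeighting, "\n")
})

# Signed contribution matrix S[p, q] = sum_m w_m * s_m(p, q) with
# s_m = +1 if m in EffExp(p) n Imp(q)          (cross-feeding)
#       -1 if m in Imp(p) n Imp(q) \ EffExp(p) (competition)
#        0 otherwise.
# A species that can itself supply a shared metabolite is counted as a
# provider, not a competitor, for that metabolite.
.signedContributions <- function(net, model, species = NULL) {
  I <- importMatrix(net) * 1
  E <- effectiveExportMatrix(net) * 1
  if (!is.null(species)) {
    I <- I[species, , drop = FALSE]
    E <- E[species, , drop = FALSE]
  }
  Iq <- I
  if (model@confidenceWeighting) {
    act <- net@activities
    imp <- act[act$activity %in% c("IMPORT", "BOTH"), , drop = FALSE]
    W <- matrix(0, nrow(I), ncol(I), dimnames = dimnames(I))
    keep <- imp$species %in% rownames(I)
    W[cbind(match(imp$species[keep], rownames(I)),
            match(imp$compound[keep], colnames(I)))] <-
      imp$confidence[keep] / 100
    Iq <- W
  }
  S <- E %*% t(Iq) - (I * (1 - E)) %*% t(Iq)
  if (model@normalization == "import") {
    nImp <- rowSums(I)
    S <- sweep(S, 2, pmax(nImp, 1), "/")
    S[, nImp == 0] <- 0
  }
  S
}

#' Pairwise metabolic influence score
#'
#' Net metabolic influence of species p on species q, the discretized form
#' of the elasticity-style score `I_pq = (n_p / mu_q) * sum_m
#' (dmu_q/dx_mq)(dx_mq/dn_p)` evaluated on presence/absence data: each
#' metabolite q imports contributes +1 when p can (effectively) supply it,
#' -1 when p competes for it without supplying it, and the sum is averaged
#' over q's import set and scaled by the abundance ratio `n_p / mu_q`. Pure
#' cross-feeding gives a positive score, pure competition a negative one,
#' disjoint metabolite sets exactly 0.
#'
#' @param p,q species names (p != q).
#' @param net a [CrossFeedingNetwork] containing both species.
#' @param abundance named numeric vector of relative abundances providing
#'   `n_p` and `mu_q` (e.g. segment or global means), or an
#'   [AbundanceTable] whose row means are used.
#' @param model an [InfluenceModel].
#' @return a single number; 0 with a warning when q imports nothing.
#' @export
influenceScore <- function(p, q, net, abundance, model = InfluenceModel()) {
  if (p == q) stop("influenceScore needs two distinct species")
  if (is(abundance, "AbundanceTable")) abundance <- rowMeans(abundances(abundance))
  sp <- .speciesOf(net)
  if (!all(c(p, q) %in% sp)) stop("both species must be in the network")
  if (!all(c(p, q) %in% names(abundance)) ||
      any(!is.finite(abundance[c(p, q)])))
    stop("missing abundance for ", paste(setdiff(c(p, q),
         names(abundance)[is.finite(abundance)]), collapse = ", "))
  S <- .signedContributions(net, model, species = c(p, q))
  if (sum(importMatrix(net)[q, ]) == 0) {
    warning("species '", q, "' imports nothing; influence is 0")
    return(0)
  }
  unname(abundance[p] / abundance[q] * S[p, q])
}

#' Species-wide influence matrix per segment
#'
#' Selects the most abundant species in every segment and evaluates the
#' pairwise influence score for all ordered pairs of the selected set.
#' Within-segment pairs use abundances averaged over the segment's
#' compartments (`"segment"` mode); cross-segment pairs fall back to global
#' mean abundances, so edges can span segments.
#'
#' @param net a [CrossFeedingNetwork].
#' @param ab an [AbundanceTable] covering the network's species.
#' @param partition a [SegmentPartition] of `ab`'s compartments.
#' @param model an [InfluenceModel].
#' @param topK species retained per segment: a single integer, a vector
#'   named by segment label, or `Inf` for all species with positive segment
#'   abundance.
#' @param minAbundance alternative selection rule: retain species whose
#'   segment mean abundance reaches this percent (overrides `topK`).
#' @return an [InfluenceMatrix]; the diagonal is NA. A species abundant in
#'   several segments is assigned to the segment where its mean abundance
#'   is highest.
#' @export
influenceMatrix <- function(net, ab, partition, model = InfluenceModel(),
                            topK = Inf, minAbundance = NULL) {
  a <- abundances(ab)
  if (!all(names(segments(partition)) %in% colnames(a)))
    stop("partition does not cover the abundance table's compartments")
  segComp <- segmentCompartments(partition)
  segNames <- names(segComp)
  inNet <- intersect(rownames(a), .speciesOf(net))
  if (!length(inNet)) stop("no species shared by network and abundances")
  segMeans <- matrix(
    unlist(lapply(segComp, function(cc) rowMeans(a[inNet, cc, drop = FALSE]))),
    nrow = length(inNet), dimnames = list(inNet, segNames))

  if (length(topK) == 1L && is.null(names(topK)))
    topK <- stats::setNames(rep(topK, length(segNames)), segNames)
  selected <- character(); segOf <- character()
  for (s in segNames) {
    v <- segMeans[, s]
    v <- v[v > 0]
    pick <- if (!is.null(minAbundance)) names(v)[v >= minAbundance]
            else {
              k <- topK[[s]]
              if (is.finite(k) && k > length(v))
                warning("segment ", s, ": only ", length(v),
                        " species available (topK = ", k, ")")
              names(sort(v, decreasing = TRUE))[seq_len(min(k, length(v)))]
            }
    new <- setdiff(pick, selected)
    selected <- c(selected, new)
    segOf <- c(segOf, stats::setNames(rep(s, length(new)), new))
    # species already selected keep the segment where they are most abundant
    dup <- intersect(pick, names(segOf)[segOf != s])
    for (d in dup) if (segMeans[d, s] > segMeans[d, segOf[[d]]]) segOf[[d]] <- s
  }
  if (length(selected) < 2) {
    m <- matrix(NA_real_, length(selected), length(selected),
                dimnames = list(selected, selected))
    return(new("InfluenceMatrix", scores = m, segments = segOf, model = model))
  }

  nSeg <- segMeans[cbind(selected, segOf[selected])]
  nGlob <- rowMeans(a[selected, , drop = FALSE])
  if (model@abundanceMode == "global") nSeg <- nGlob
  if (any(nSeg <= 0) || any(nGlob <= 0))
    stop("selected species must have positive abundance")

  S <- .signedContributions(net, model, species = selected)
  sameSeg <- outer(segOf[selected], segOf[selected], "==")
  np <- ifelse(sameSeg, nSeg[row(sameSeg)], nGlob[row(sameSeg)])
  mq <- ifelse(sameSeg, nSeg[col(sameSeg)], nGlob[col(sameSeg)])
  scores <- np / mq * S
  diag(scores) <- NA_real_
  dimnames(scores) <- list(selected, selected)
  new("InfluenceMatrix", scores = scores, segments = segOf[selected],
      model = model)
}

#' @rdname accessors
setMethod("scores", "InfluenceMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("segments", "InfluenceMatrix", function(x) x@segments)
#' @rdname accessors
setMethod("speciesNames", "InfluenceMatrix", function(x) rownames(x@scores))

setMethod("show", "InfluenceMatrix", function(object) {
  tab <- table(object@segments[rownames(object@scores)])
  cat("InfluenceMatrix:", nrow(object@scores), "species (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
})

#' Threshold an influence matrix into a signed directed network
#'
#' @param mat an [InfluenceMatrix].
#' @param threshold non-negative magnitude threshold; an edge p -> q is kept
#'   iff `|I_pq| > threshold`. Isolated nodes are retained with their
#'   segment label.
#' @return an [InfluenceNetwork].
#' @export
buildInfluenceNetwork <- function(mat, threshold = 0) {
  if (threshold < 0) stop("threshold must be >= 0")
  s <- scores(mat)
  keep <- which(!is.na(s) & abs(s) > threshold, arr.ind = TRUE)
  e <- data.frame(from = rownames(s)[keep[, 1]],
                  to = colnames(s)[keep[, 2]],
                  weight = s[keep],
                  sign = sign(s[keep]),
                  stringsAsFactors = FALSE)
  n <- data.frame(species = rownames(s),
                  segment = unname(segments(mat)[rownames(s)]),
                  stringsAsFactors = FALSE)
  new("InfluenceNetwork", nodes = n, edges = e, threshold = threshold)
}

#' @rdname accessors
setMethod("edges", "InfluenceNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("nodes", "InfluenceNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("speciesNames", "InfluenceNetwork", function(x) x@nodes$species)

setMethod("show", "InfluenceNetwork", function(object) {
  tab <- table(object@nodes$segment)
  cat("InfluenceNetwork:", nrow(object@nodes), "nodes (",
      paste(names(tab), tab, sep = ":", collapse = ", "), "),",
      nrow(object@edges), "edges (",
      sum(object@edges$sign > 0), "positive /",
      sum(object@edges$sign < 0), "negative ), |I| >",
      object@threshold, "\n")
})
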
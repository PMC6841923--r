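#' Pairwise metabolic similarity of species
#'
#' Jaccard overlap of import sets: species competing for the same metabolic
#' inputs score high. `sim(p, q) = |Imp(p) n Imp(q)| / |Imp(p) u Imp(q)|`,
#' with similarity 0 by convention when both import sets are empty.
#' `mode = "import_export"` uses the union of imports and effective exports
#' instead.
#'
#' @param net a nonempty [CrossFeedingNetwork].
#' @param mode `"import"` (default) or `"import_export"`.
#' @return symmetric numeric matrix in \[0, 1\]; diagonal is 1 for species
#'   with a nonempty set.
#' @export
metabolicSimilarity <- function(net, mode = c("import", "import_export")) {
  mode <- match.arg(mode)
  if (!nrow(net@activities)) stop("metabolicSimilarity needs a nonempty network")
  m <- importMatrix(net)
  if (mode == "import_export") m <- m | effectiveExportMatrix(net)
  m <- m * 1
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(union > 0, inter / union, 0)
  dimnames(sim) <- list(rownames(m), rownames(m))
  sim
}

#' Pairwise co-occurrence of species across compartments
#'
#' Default score: Spearman rank correlation of the two species' relative
#' abundance vectors across the gut compartments (only a handful of samples
#' exist per gut, so a rank correlation is used). `method = "jaccard"`
#' scores presence/absence overlap instead (presence = abundance at or above
#' the table's inclusion threshold).
#'
#' @param ab an [AbundanceTable] with at least 3 compartments.
#' @param method `"spearman"` (default) or `"jaccard"`.
#' @return symmetric matrix; Spearman scores in \[-1, 1\] with diagonal 1.
#'   Species with zero abundance variance across compartments are undefined
#'   under Spearman: their rows/columns are NA and their names are recorded
#'   in the `"excluded"` attribute.
#' @export
cooccurrenceScore <- function(ab, method = c("spearman", "jaccard")) {
  method <- match.arg(method)
  a <- abundances(ab)
  if (ncol(a) < 3) stop("cooccurrenceScore needs >= 3 compartments")
  if (method == "spearman") {
    v <- apply(a, 1, stats::var)
    flat <- rownames(a)[v == 0]
    cc <- suppressWarnings(stats::cor(t(a), method = "spearman"))
    cc[flat, ] <- NA_real_
    cc[, flat] <- NA_real_
    diag(cc)[!rownames(a) %in% flat] <- 1
    attr(cc, "excluded") <- flat
    cc
  } else {
    pres <- (a >= ab@minAbundance) * 1
    inter <- tcrossprod(pres)
    sizes <- rowSums(pres)
    union <- outer(sizes, sizes, "+") - inter
    cc <- ifelse(union > 0, inter / union, 0)
    dimnames(cc) <- list(rownames(a), rownames(a))
    attr(cc, "excluded") <- character()
    cc
  }
}

#' Rank correlation between metabolic similarity and co-occurrence
#'
#' Collects every cross-group species pair (one from each group, groups made
#' disjoint by dropping their intersection) and correlates the pairs'
#' metabolic similarity with their co-occurrence score by Spearman's rho.
#' A positive rho between metabolically similar guilds is the signature of
#' habitat filtering; between producer and consumer guilds it indicates
#' metabolic interdependency.
#'
#' @param sim similarity matrix from [metabolicSimilarity()].
#' @param cooc co-occurrence matrix from [cooccurrenceScore()].
#' @param groupA,groupB character vectors of species.
#' @param nPerm permutation count for the small-sample p-value.
#' @param seed seed for the permutation p-value.
#' @return list: `rho`, `p_value`, `n_pairs`, `p_method` (`"t"` for the
#'   large-sample t approximation when >= 30 pairs, else `"permutation"`).
#' @export
groupCorrelation <- function(sim, cooc, groupA, groupB,
                             nPerm = 10000L, seed = 1L) {
  shared <- intersect(rownames(sim), rownames(cooc))
  groupA <- setdiff(intersect(.normalizeSpecies(groupA), shared),
                    .normalizeSpecies(groupB))
  groupB <- setdiff(intersect(.normalizeSpecies(groupB), shared),
                    .normalizeSpecies(groupA))
  # note: intersection species removed from both (guilds treated as disjoint)
  pairs <- expand.grid(p = groupA, q = groupB, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$p != pairs$q, , drop = FALSE]
  if (!nrow(pairs)) stop("no cross-group pairs")
  x <- sim[cbind(pairs$p, pairs$q)]
  y <- cooc[cbind(pairs$p, pairs$q)]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 cross-group pairs with defined scores")
  rho <- stats::cor(x, y, method = "spearman")
  if (n >= 30) {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    meth <- "t"
  } else {
    p <- local({
      old <- .saveRNG(); on.exit(.restoreRNG(old))
      set.seed(seed)
      perm <- replicate(nPerm,
        stats::cor(x, sample(y), method = "spearman"))
      (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (nPerm + 1)
    })
    meth <- "permutation"
  }
  list(rho = rho, p_value = p, n_pairs = n, p_method = meth)
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
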
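#' Kruskal--Wallis rank test
#'
#' H is computed on mid-ranks in the classical uncorrected form
#' `H = 12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)`,
#' where `R_i` is the rank sum of group i, `n_i` its size and `N` the total
#' number of observations; the p-value uses the chi-square approximation
#' with `k - 1` degrees of freedom. The tie-corrected statistic (H divided
#' by `1 - sum(t^3 - t) / (N^3 - N)` over tie groups of size t) is available
#' behind `tieCorrection = TRUE`; the two agree whenever no ties exist.
#'
#' @param groups list of (at least two) nonempty numeric vectors.
#' @param tieCorrection logical, apply the tie correction (default FALSE).
#' @return list: `H`, `p_value`, `df`.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))$H  # 27/7
#' @export
kruskalWallis <- function(groups, tieCorrection = FALSE) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskalWallis needs a list of >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must contain observations")
  x <- unlist(groups, use.names = FALSE)
  if (!is.numeric(x)) stop("observations must be numeric")
  N <- length(x)
  if (N < 3) stop("need at least 3 observations in total")
  r <- rank(x)  # mid-ranks for ties
  g <- rep(seq_along(groups), sizes)
  Ri <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Ri^2 / sizes) - 3 * (N + 1)
  if (tieCorrection) {
    t <- table(x)
    denom <- 1 - sum(t^3 - t) / (N^3 - N)
    H <- if (denom > 0) H / denom else 0
  }
  H <- max(H, 0)  # guard tiny negative rounding when all ranks tie
  df <- length(groups) - 1
  list(H = H, p_value = stats::pchisq(H, df = df, lower.tail = FALSE), df = df)
}

#' Partition gut compartments into segments
#'
#' Greedy left-to-right merging along the gut axis: the current block of
#' adjacent compartments is extended by the next compartment when a
#' Kruskal--Wallis test across the block's per-species abundance vectors
#' fails to reject at `alpha` (p > alpha read as "similar abundance
#' distribution"); otherwise the block is closed as a segment and a new one
#' starts. Observations entering each test are the abundance values of the
#' species reaching `minAbundance` in at least one compartment of the
#' candidate block (zeros for included species are retained).
#'
#' @param ab an [AbundanceTable] with compartments in anatomical order.
#' @param alpha significance level (default 0.05).
#' @param minAbundance inclusion threshold in percent; defaults to the
#'   table's threshold.
#' @param tieCorrection passed to [kruskalWallis()].
#' @return a [SegmentPartition]; segment labels are S1, S2, ... and every
#'   merge decision is recorded with its H and p.
#' @export
partitionSegments <- function(ab, alpha = 0.05, minAbundance = NULL,
                              tieCorrection = FALSE) {
  a <- abundances(ab)
  if (is.null(minAbundance)) minAbundance <- ab@minAbundance
  comps <- colnames(a)
  block <- 1L
  segEnd <- integer()
  tests <- list()
  testBlock <- function(cols) {
    sub <- a[, cols, drop = FALSE]
    keep <- apply(sub, 1, function(v) any(v >= minAbundance))
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) * length(cols) < 3 || all(sub == sub[1]))
      return(list(H = 0, p_value = 1, df = length(cols) - 1))
    kruskalWallis(asplit(sub, 2), tieCorrection = tieCorrection)
  }
  if (length(comps) > 1) {
    for (j in 2:length(comps)) {
      cand <- c(block, j)
      kw <- testBlock(cand)
      merged <- kw$p_value > alpha
      tests[[length(tests) + 1L]] <- data.frame(
        compartments = paste(comps[cand], collapse = "+"),
        H = kw$H, p_value = kw$p_value, merged = merged,
        stringsAsFactors = FALSE)
      if (merged) block <- cand
      else { segEnd <- c(segEnd, block[length(block)]); block <- j }
    }
  }
  segEnd <- c(segEnd, block[length(block)])
  seg <- cumsum(seq_along(comps) %in% c(1L, utils::head(segEnd, -1) + 1L))
  mapping <- stats::setNames(paste0("S", seg), comps)
  new("SegmentPartition", mapping = mapping,
      tests = if (length(tests)) do.call(rbind, tests) else
        data.frame(compartments = character(), H = numeric(),
                   p_value = numeric(), merged = logical()),
      alpha = alpha)
}

#' @rdname accessors
setMethod("segments", "SegmentPartition", function(x) x@mapping)

#' Merge-decision records of a partition
#'
#' @param partition a [SegmentPartition].
#' @return data.frame of the Kruskal--Wallis tests behind each decision.
#' @export
partitionTests <- function(partition) partition@tests

setMethod("show", "SegmentPartition", function(object) {
  segs <- split(names(object@mapping), object@mapping)
  cat("SegmentPartition (alpha =", object@alpha, "):\n")
  for (s in names(segs))
    cat(" ", s, "=", paste(segs[[s]], collapse = ", "), "\n")
})

#' Segment label of each species' context
#'
#' Helper mapping segment label -> compartments.
#'
#' @param partition a [SegmentPartition].
#' @return named list segment -> character vector of compartments.
#' @export
segmentCompartments <- function(partition)
  split(names(partition@mapping), partition@mapping)
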
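#' Normalize compound names
#'
#' Curated metabolic tables are hand-typed; names are matched
#' case-insensitively with whitespace collapsed. Stereo prefixes such as
#' "D-"/"L-" are preserved (lowercased along with the rest of the name,
#' which keeps them distinct from the unprefixed sugar).
#'
#' @param x character vector of compound names.
#' @return normalized names.
#' @export
normalizeCompound <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

.normalizeSpecies <- function(x) gsub("\\s+", " ", trimws(as.character(x)))

#' Construct a CrossFeedingNetwork from in-memory tables
#'
#' @param activityTable data.frame with columns `species`, `compound`,
#'   `activity` and optionally `n_publications`, `kegg_flag`.
#' @param compoundTable optional data.frame with columns `compound`, `class`
#'   (`SMALL_METABOLITE`/`MACROMOLECULE`, case-insensitive; `metabolite` and
#'   `macromolecule` accepted) and `degradation_products`
#'   (semicolon-separated). Compounds appearing only in the activity table
#'   are registered as small metabolites.
#' @param groups optional named character vector or two-column data.frame
#'   (`species`, `group`) with functional group labels.
#' @return a validated [CrossFeedingNetwork]. Strain-level rows carrying the
#'   same species name are merged; an IMPORT and an EXPORT row for the same
#'   (species, compound) collapse to BOTH.
#' @details Activity keywords are matched case-insensitively
#'   (`import|export|both|degrades`). A `DEGRADES` row whose compound has no
#'   registered degradation products is a validation error. Duplicate rows
#'   that agree in all fields are deduplicated; duplicates that conflict in
#'   `n_publications` or `kegg_flag` raise an error listing them.
#' @export
makeCrossFeedingNetwork <- function(activityTable, compoundTable = NULL,
                                    groups = NULL) {
  act <- as.data.frame(activityTable)
  need <- c("species", "compound", "activity")
  if (!all(need %in% names(act)))
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  if (is.null(act$n_publications)) act$n_publications <- rep(0L, nrow(act))
  if (is.null(act$kegg_flag)) act$kegg_flag <- rep(0L, nrow(act))

  act$species <- .normalizeSpecies(act$species)
  act$compound <- normalizeCompound(act$compound)
  keyword <- tolower(trimws(as.character(act$activity)))
  bad <- which(!keyword %in% c("import", "export", "both", "degrades"))
  if (length(bad))
    stop("unknown activity keyword in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(keyword[bad]), collapse = ", "))
  act$activity <- toupper(keyword)
  act$n_publications <- as.integer(act$n_publications)
  act$kegg_flag <- as.integer(act$kegg_flag)

  # compound registry
  if (!is.null(compoundTable)) {
    cmp <- as.data.frame(compoundTable)
    if (!all(c("compound", "class") %in% names(cmp)))
      stop("compound table must have columns compound, class")
    cmpName <- normalizeCompound(cmp$compound)
    kl <- toupper(trimws(as.character(cmp$class)))
    kl[kl %in% c("METABOLITE", "SMALL", "SMALL METABOLITE")] <- "SMALL_METABOLITE"
    if (!all(kl %in% COMPOUND_CLASSES))
      stop("unknown compound class: ",
           paste(setdiff(kl, COMPOUND_CLASSES), collapse = ", "))
    prodRaw <- if (!is.null(cmp$degradation_products))
      as.character(cmp$degradation_products) else rep("", nrow(cmp))
    prodRaw[is.na(prodRaw)] <- ""
    products <- lapply(strsplit(prodRaw, ";", fixed = TRUE), function(p) {
      p <- normalizeCompound(p)
      p[nzchar(p)]
    })
    names(products) <- cmpName
    compounds <- data.frame(compound = cmpName, klass = kl,
                            stringsAsFactors = FALSE)
  } else {
    compounds <- data.frame(compound = character(), klass = character(),
                            stringsAsFactors = FALSE)
    products <- list()
  }
  extra <- setdiff(unique(act$compound), compounds$compound)
  if (length(extra)) {
    compounds <- rbind(compounds,
                       data.frame(compound = extra, klass = "SMALL_METABOLITE",
                                  stringsAsFactors = FALSE))
    products[extra] <- list(character())
  }
  # register product compounds that were never listed themselves
  allProds <- setdiff(unique(unlist(products)), compounds$compound)
  if (length(allProds)) {
    compounds <- rbind(compounds,
                       data.frame(compound = allProds,
                                  klass = "SMALL_METABOLITE",
                                  stringsAsFactors = FALSE))
    products[allProds] <- list(character())
  }
  products <- products[compounds$compound]

  deg <- act$activity == "DEGRADES"
  if (any(deg)) {
    noprod <- !lengths(products[act$compound[deg]])
    if (any(noprod))
      stop("DEGRADES rows for compound(s) without degradation products: ",
           paste(unique(act$compound[deg][noprod]), collapse = ", "))
  }

  # strain merging: collapse duplicate triples, IMPORT + EXPORT -> BOTH
  key <- paste(act$species, act$compound, act$activity, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- function(v, f) as.integer(tapply(v, key, f)[unique(key)])
    chk <- tapply(seq_len(nrow(act)), key, function(i)
      length(unique(act$n_publications[i])) > 1L ||
        length(unique(act$kegg_flag[i])) > 1L)
    if (any(chk))
      stop("conflicting duplicate rows for: ",
           paste(gsub("\r", " / ", names(chk)[chk]), collapse = "; "))
    first <- !duplicated(key)
    act <- act[first, , drop = FALSE]
  }
  # IMPORT + EXPORT (or either + BOTH) for the same species/compound -> BOTH
  sc <- paste(act$species, act$compound, sep = "\r")
  io <- act$activity %in% c("IMPORT", "EXPORT", "BOTH")
  tab <- split(which(io), sc[io])
  both <- vapply(tab, function(i) length(i) > 1L, logical(1))
  if (any(both)) {
    dropIdx <- integer()
    for (i in tab[both]) {
      act$activity[i[1]] <- "BOTH"
      act$n_publications[i[1]] <- max(act$n_publications[i])
      act$kegg_flag[i[1]] <- max(act$kegg_flag[i])
      dropIdx <- c(dropIdx, i[-1])
    }
    act <- act[-dropIdx, , drop = FALSE]
  }
  rownames(act) <- NULL

  nmax <- max(1L, act$n_publications)
  act$confidence <- if (nrow(act))
    confidenceScore(act$n_publications, nmax, act$kegg_flag) else numeric()

  if (!is.null(groups)) {
    if (is.data.frame(groups)) {
      g <- as.character(groups$group)
      names(g) <- .normalizeSpecies(groups$species)
      groups <- g
    }
    names(groups) <- .normalizeSpecies(names(groups))
  } else groups <- character()

  new("CrossFeedingNetwork", activities = act, compounds = compounds,
      degradationProducts = products, speciesGroups = groups, nMax = nmax)
}

.readTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    quote = "\"", comment.char = "", check.names = TRUE,
                    fileEncoding = "UTF-8")
}

#' Load a cross-feeding network from delimited files
#'
#' @param activityFile path to a UTF-8 delimited table (TSV, or CSV by
#'   extension) with columns `species, compound, activity, n_publications,
#'   kegg_flag`.
#' @param compoundFile optional path to a table with columns
#'   `compound, class, degradation_products` (semicolon-separated products).
#' @param groupsFile optional path to a two-column `species, group` table.
#' @return a [CrossFeedingNetwork].
#' @export
loadNetwork <- function(activityFile, compoundFile = NULL, groupsFile = NULL) {
  act <- .readTable(activityFile)
  cmp <- if (!is.null(compoundFile)) .readTable(compoundFile)
  grp <- if (!is.null(groupsFile)) .readTable(groupsFile)
  makeCrossFeedingNetwork(act, cmp, grp)
}

#' Read a sheet of a curated spreadsheet workbook
#'
#' Thin convenience wrapper for workbook-distributed curated tables
#' (requires the readxl package).
#'
#' @param path workbook path (.xlsx).
#' @param sheet sheet name or index.
#' @return a data.frame.
#' @export
readWorkbookSheet <- function(path, sheet) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("readWorkbookSheet requires the readxl package")
  as.data.frame(readxl::read_excel(path, sheet = sheet))
}

#' Literature confidence score of a network edge
#'
#' The confidence of an annotated metabolic activity combines its literature
#' support with KEGG corroboration:
#' `score = (n / n_max) * 70 + kegg_flag * 30`,
#' where `n` is the number of publications supporting the edge, `n_max` the
#' maximum publication count over all edges of the network, and `kegg_flag`
#' indicates KEGG support (0/1). Scores lie in \[0, 100\].
#'
#' @param n non-negative integer publication count(s).
#' @param nMax positive integer, global maximum publication count.
#' @param keggFlag 0/1 indicator(s).
#' @return numeric score(s) in \[0, 100\].
#' @examples
#' confidenceScore(7, 10, 0)   # 49
#' confidenceScore(10, 10, 1)  # 100
#' @export
confidenceScore <- function(n, nMax, keggFlag) {
  if (any(nMax < 1)) stop("nMax must be >= 1")
  if (any(n < 0) || any(n > nMax)) stop("need 0 <= n <= nMax")
  if (!all(keggFlag %in% c(0, 1))) stop("keggFlag must be 0 or 1")
  (n / nMax) * 70 + keggFlag * 30
}

# ---- incidence matrices -------------------------------------------------

.speciesOf <- function(net) sort(unique(net@activities$species))
.smallMetabolites <- function(net)
  net@compounds$compound[net@compounds$klass == "SMALL_METABOLITE"]

.incidence <- function(net, acts, compounds = net@compounds$compound) {
  sp <- .speciesOf(net)
  m <- matrix(FALSE, length(sp), length(compounds),
              dimnames = list(sp, compounds))
  a <- net@activities[net@activities$activity %in% acts, , drop = FALSE]
  keep <- a$compound %in% compounds
  if (any(keep))
    m[cbind(match(a$species[keep], sp), match(a$compound[keep], compounds))] <- TRUE
  m
}

#' Import / export incidence matrices
#'
#' Logical species-by-compound matrices. `importMatrix` marks compounds a
#' species imports (`IMPORT` or `BOTH`); `exportMatrix` marks explicit
#' exports (`EXPORT` or `BOTH`); `effectiveExportMatrix` additionally marks
#' the degradation products of every macromolecule the species degrades.
#'
#' @param net a [CrossFeedingNetwork].
#' @return logical matrix, rows = species, columns = compounds.
#' @export
importMatrix <- function(net) .incidence(net, c("IMPORT", "BOTH"))

#' @rdname importMatrix
#' @export
exportMatrix <- function(net) .incidence(net, c("EXPORT", "BOTH"))

#' @rdname importMatrix
#' @export
effectiveExportMatrix <- function(net) {
  m <- exportMatrix(net)
  deg <- net@activities[net@activities$activity == "DEGRADES", , drop = FALSE]
  if (nrow(deg)) {
    for (i in seq_len(nrow(deg))) {
      prods <- net@degradationProducts[[deg$compound[i]]]
      prods <- intersect(prods, colnames(m))
      m[deg$species[i], prods] <- TRUE
    }
  }
  m
}

# ---- profiling ----------------------------------------------------------

#' Per-species metabolite transport profile
#'
#' Counts, for every species, the number of imported compounds
#' (`IMPORT` or `BOTH`) and the size of the effective export set (explicit
#' exports plus degradation products of degraded macromolecules).
#'
#' @param net a nonempty [CrossFeedingNetwork].
#' @return a list with `profile` (data.frame: `species`, `n_imported`,
#'   `n_exported`) and `summary` (named vector: mean/median of both counts).
#' @export
transportProfile <- function(net) {
  if (!nrow(net@activities)) stop("transportProfile needs a nonempty network")
  imp <- rowSums(importMatrix(net))
  exp <- rowSums(effectiveExportMatrix(net))
  profile <- data.frame(species = names(imp),
                        n_imported = as.integer(imp),
                        n_exported = as.integer(exp),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(profile = profile,
       summary = c(mean_imported = mean(imp), mean_exported = mean(exp),
                   median_imported = stats::median(imp),
                   median_exported = stats::median(exp)))
}

#' Consumer and producer fractions per metabolite
#'
#' Fraction of the considered species that import (consume) and effectively
#' export (produce) each compound, reported in percent.
#'
#' @param net a [CrossFeedingNetwork].
#' @param restrictTo optional character vector restricting the species set.
#' @return data.frame: `compound`, `consumer_pct`, `producer_pct`.
#' @export
metaboliteUsage <- function(net, restrictTo = NULL) {
  imp <- importMatrix(net)
  exp <- effectiveExportMatrix(net)
  if (!is.null(restrictTo)) {
    restrictTo <- .normalizeSpecies(restrictTo)
    if (!length(restrictTo)) stop("empty species restriction set")
    miss <- setdiff(restrictTo, rownames(imp))
    if (length(miss))
      stop("restrictTo species not in network: ", paste(miss, collapse = ", "))
    imp <- imp[restrictTo, , drop = FALSE]
    exp <- exp[restrictTo, , drop = FALSE]
  }
  data.frame(compound = colnames(imp),
             consumer_pct = 100 * colMeans(imp),
             producer_pct = 100 * colMeans(exp),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between abundance and transport activity
#'
#' R-squared of a simple linear fit of the total transport count
#' (`n_imported + n_exported`) on a species' overall relative abundance
#' (by default the mean across compartments).
#'
#' @param net a [CrossFeedingNetwork].
#' @param ab an [AbundanceTable].
#' @param aggregate `"mean"` (default) or `"max"` across compartments.
#' @return squared Pearson correlation coefficient.
#' @export
abundanceTransportCorrelation <- function(net, ab, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  tp <- transportProfile(net)$profile
  a <- abundances(ab)
  common <- intersect(tp$species, rownames(a))
  if (length(common) < 3)
    stop("need at least 3 species shared between network and abundance table")
  x <- switch(aggregate,
              mean = rowMeans(a[common, , drop = FALSE]),
              max = apply(a[common, , drop = FALSE], 1, max))
  y <- tp$n_imported[match(common, tp$species)] +
    tp$n_exported[match(common, tp$species)]
  stats::cor(x, y)^2
}

# ---- AbundanceTable -----------------------------------------------------

#' Construct an AbundanceTable
#'
#' @param abundance numeric matrix of relative abundances (percent); rows =
#'   species, columns = compartments in anatomical gut order.
#' @param minAbundance inclusion threshold in percent (default 0.02): a
#'   species enters distribution tests when it reaches this abundance in at
#'   least one compartment under consideration.
#' @return an [AbundanceTable].
#' @export
AbundanceTable <- function(abundance, minAbundance = 0.02) {
  abundance <- as.matrix(abundance)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance),
    colData = S4Vectors::DataFrame(compartment = colnames(abundance),
                                   row.names = colnames(abundance)))
  new("AbundanceTable", se, minAbundance = minAbundance)
}

#' Load an abundance table from a delimited file
#'
#' @param file TSV/CSV path; first column species, remaining columns
#'   compartments.
#' @param minAbundance inclusion threshold in percent.
#' @return an [AbundanceTable].
#' @export
loadAbundanceTable <- function(file, minAbundance = 0.02) {
  d <- .readTable(file)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- .normalizeSpecies(d[[1]])
  AbundanceTable(m, minAbundance = minAbundance)
}

# ---- accessors & show ---------------------------------------------------

#' @rdname accessors
setMethod("speciesNames", "CrossFeedingNetwork", function(x) .speciesOf(x))
#' @rdname accessors
setMethod("speciesNames", "AbundanceTable", function(x) rownames(x))
#' @rdname accessors
setMethod("compoundNames", "CrossFeedingNetwork",
          function(x) x@compounds$compound)
#' @rdname accessors
setMethod("activities", "CrossFeedingNetwork", function(x) x@activities)
#' @rdname accessors
setMethod("nMax", "CrossFeedingNetwork", function(x) x@nMax)
#' @rdname accessors
setMethod("speciesGroups", "CrossFeedingNetwork", function(x) x@speciesGroups)
#' @rdname accessors
setMethod("abundances", "AbundanceTable",
          function(x) SummarizedExperiment::assay(x, "abundance"))
#' @rdname accessors
setMethod("compartments", "AbundanceTable", function(x) colnames(x))

#' Degradation products of the network's macromolecules
#'
#' @param net a [CrossFeedingNetwork].
#' @return named list macromolecule -> character vector of products.
#' @export
degradationProducts <- function(net)
  net@degradationProducts[lengths(net@degradationProducts) > 0]

#' Summary counts of a cross-feeding network
#'
#' @param net a [CrossFeedingNetwork].
#' @return named vector: species, compounds, small metabolites,
#'   macromolecules, import/export events (IMPORT, EXPORT or BOTH rows) and
#'   degradation events, counted separately.
#' @export
networkSummary <- function(net) {
  act <- net@activities
  c(n_species = length(.speciesOf(net)),
    n_compounds = nrow(net@compounds),
    n_metabolites = sum(net@compounds$klass == "SMALL_METABOLITE"),
    n_macromolecules = sum(net@compounds$klass == "MACROMOLECULE"),
    n_transport_events = sum(act$activity %in% c("IMPORT", "EXPORT", "BOTH")),
    n_degradation_events = sum(act$activity == "DEGRADES"))
}

setMethod("show", "CrossFeedingNetwork", function(object) {
  s <- networkSummary(object)
  cat("CrossFeedingNetwork:", s["n_species"], "species,",
      s["n_metabolites"], "metabolites,", s["n_macromolecules"],
      "macromolecules\n  ", s["n_transport_events"],
      "import/export events,", s["n_degradation_events"],
      "degradation events (nMax =", object@nMax, ")\n")
})

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable:", nrow(object), "species x", ncol(object),
      "compartments (", paste(colnames(object), collapse = ", "),
      "), inclusion threshold", object@minAbundance, "%\n")
})
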
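#' Accessors for CrossFeedNet classes
#'
#' `speciesNames()` returns the species in an object, `compoundNames()` the
#' compounds of a network, `activities()` the activity table, `nMax()` the
#' global maximum literature count, `speciesGroups()` the functional group
#' labels, `abundances()` the relative-abundance matrix, `compartments()`
#' the compartment names, `segments()` the compartment -> segment mapping,
#' `scores()` the influence-score matrix, `edges()` / `nodes()` the edge and
#' node tables of a network object.
#'
#' @param x an object of the corresponding class.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("compoundNames", function(x) standardGeneric("compoundNames"))

#' @rdname accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname accessors
#' @export
setGeneric("nMax", function(x) standardGeneric("nMax"))

#' @rdname accessors
#' @export
setGeneric("speciesGroups", function(x) standardGeneric("speciesGroups"))

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))

#' @rdname accessors
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Export a network to SIF or GraphML
#'
#' `writeSIF()` writes the simple interaction format used by Cytoscape
#' (`source<TAB>interaction<TAB>target`); `writeGraphML()` writes GraphML
#' with edge (and, where applicable, node) attributes via igraph.
#'
#' @param x a [CrossFeedingNetwork], [InfluenceNetwork] or
#'   [DegradationNetwork].
#' @param file output path.
#' @return `file`, invisibly.
#' @name network-export
NULL

#' @rdname network-export
#' @export
setGeneric("writeSIF", function(x, file) standardGeneric("writeSIF"))

#' @rdname network-export
#' @export
setGeneric("writeGraphML", function(x, file) standardGeneric("writeGraphML"))
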
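#' @importFrom igraph graph_from_data_frame write_graph
NULL

.writeLines <- function(lines, file) {
  con <- file(file, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

.sifVerb <- c(IMPORT = "imports", EXPORT = "exports", BOTH = "imports-exports",
              DEGRADES = "degrades")

#' @rdname network-export
setMethod("writeSIF", "CrossFeedingNetwork", function(x, file) {
  a <- x@activities
  .writeLines(paste(a$species, .sifVerb[a$activity], a$compound, sep = "\t"),
              file)
})

#' @rdname network-export
setMethod("writeSIF", "InfluenceNetwork", function(x, file) {
  e <- x@edges
  lines <- if (nrow(e))
    paste(e$from, ifelse(e$sign > 0, "pos", "neg"), e$to, sep = "\t")
  else character()
  .writeLines(lines, file)
})

#' @rdname network-export
setMethod("writeSIF", "DegradationNetwork", function(x, file) {
  e <- x@edges
  lines <- if (nrow(e)) paste(e$from, e$type, e$to, sep = "\t") else character()
  .writeLines(lines, file)
})

.igraphFrom <- function(edges, vertices) {
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' @rdname network-export
setMethod("writeGraphML", "CrossFeedingNetwork", function(x, file) {
  a <- x@activities
  e <- data.frame(from = a$species, to = a$compound,
                  activity = a$activity, confidence = a$confidence,
                  stringsAsFactors = FALSE)
  v <- data.frame(
    name = c(.speciesOf(x), x@compounds$compound),
    type = c(rep("species", length(.speciesOf(x))),
             tolower(x@compounds$klass)),
    stringsAsFactors = FALSE)
  igraph::write_graph(.igraphFrom(e, v), file, format = "graphml")
  invisible(file)
})

#' @rdname network-export
setMethod("writeGraphML", "InfluenceNetwork", function(x, file) {
  e <- x@edges
  v <- data.frame(name = x@nodes$species, segment = x@nodes$segment,
                  stringsAsFactors = FALSE)
  g <- .igraphFrom(e[, c("from", "to", "weight", "sign")], v)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
})

#' @rdname network-export
setMethod("writeGraphML", "DegradationNetwork", function(x, file) {
  v <- data.frame(name = x@nodes$name, type = x@nodes$type,
                  stringsAsFactors = FALSE)
  g <- .igraphFrom(x@edges[, c("from", "to", "type", "confidence")], v)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
})

#' Write a square matrix as TSV with header row and column
#'
#' @param m matrix with dimnames.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeMatrixTSV <- function(m, file) {
  d <- data.frame(species = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.writeTSV <- function(d, file) {
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
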
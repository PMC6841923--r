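#' Assemble a pipeline configuration
#'
#' @param activityFile,compoundFile,abundanceFile,enzymeFile,groupsFile
#'   input paths (`groupsFile`, `enzymeFile` optional); alternatively pass
#'   in-memory objects via `network` / `abundance` / `enzymes`.
#' @param network,abundance,enzymes optional in-memory inputs overriding
#'   the file paths.
#' @param alpha segmentation significance level.
#' @param minAbundance inclusion threshold, percent.
#' @param abundanceMode,normalization,confidenceWeighting influence-model
#'   options, see [InfluenceModel()].
#' @param topK species retained per segment for the influence matrix.
#' @param threshold influence-network magnitude threshold.
#' @param cutoff influencer cutoff (`"auto"` = mean betweenness).
#' @param centralityNormalization `"component"` or `"directed"`.
#' @param removalFraction,robustnessMode,robustnessSeeds robustness
#'   settings.
#' @param groupA,groupB optional species groups (or group labels from the
#'   groups file) for the similarity/co-occurrence correlation report.
#' @param seed master seed recorded in the provenance record.
#' @param outputDir directory for stage outputs.
#' @return a validated config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(activityFile = NULL, compoundFile = NULL,
                           abundanceFile = NULL, enzymeFile = NULL,
                           groupsFile = NULL,
                           network = NULL, abundance = NULL, enzymes = NULL,
                           alpha = 0.05, minAbundance = 0.02,
                           abundanceMode = "segment",
                           normalization = "import",
                           confidenceWeighting = FALSE,
                           topK = Inf, threshold = 0, cutoff = "auto",
                           centralityNormalization = "component",
                           removalFraction = 0.25,
                           robustnessMode = "species_and_metabolites",
                           robustnessSeeds = 1:5,
                           groupA = NULL, groupB = NULL,
                           seed = 1L, outputDir = "crossfeednet-out") {
  cfg <- list(activityFile = activityFile, compoundFile = compoundFile,
              abundanceFile = abundanceFile, enzymeFile = enzymeFile,
              groupsFile = groupsFile, network = network,
              abundance = abundance, enzymes = enzymes, alpha = alpha,
              minAbundance = minAbundance, abundanceMode = abundanceMode,
              normalization = normalization,
              confidenceWeighting = confidenceWeighting, topK = topK,
              threshold = threshold, cutoff = cutoff,
              centralityNormalization = centralityNormalization,
              removalFraction = removalFraction,
              robustnessMode = robustnessMode,
              robustnessSeeds = robustnessSeeds,
              groupA = groupA, groupB = groupB,
              seed = as.integer(seed), outputDir = outputDir)
  for (f in c("activityFile", "compoundFile", "abundanceFile", "enzymeFile",
              "groupsFile"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input path does not exist: ", cfg[[f]])
  if (is.null(cfg$network) && is.null(cfg$activityFile))
    stop("either a network object or an activity file is required")
  if (is.null(cfg$abundance) && is.null(cfg$abundanceFile))
    stop("either an abundance object or an abundance file is required")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipelineConfig()] arguments.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.stageLog <- function(stage, t0)
  message(sprintf("[%s] done in %.2fs", stage,
                  as.numeric(Sys.time()) - t0))

#' Run the full cross-feeding analysis pipeline
#'
#' Executes, in order: network loading and confidence scoring; transport
#' and metabolite-usage profiling; metabolic-similarity / co-occurrence
#' correlation (when species groups are configured); Kruskal--Wallis
#' segmentation; influence matrix; influence network; centrality report
#' with influencer identification and functional class fractions;
#' segment-wise byproduct profiles; robustness subsampling; lignocellulose
#' degradation network (when an enzyme table is configured). Every stage
#' writes its output under `outputDir` together with a provenance record
#' (config, seed, package and R versions).
#'
#' @param config a `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param verbose log stage timings.
#' @return (invisibly) a result bundle: `network`, `abundance`,
#'   `partition`, `influence` (matrix), `influenceNetwork`, `report`,
#'   `influencers`, `byproducts`, `robustness`, `degradation`,
#'   `correlation`, `usage`, `transport`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outputDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- if (verbose) .stageLog else function(...) invisible()

  t0 <- as.numeric(Sys.time())
  net <- if (!is.null(config$network)) config$network else
    loadNetwork(config$activityFile, config$compoundFile, config$groupsFile)
  ab <- if (!is.null(config$abundance)) config$abundance else
    loadAbundanceTable(config$abundanceFile, config$minAbundance)
  .writeTSV(as.data.frame(t(networkSummary(net))),
            file.path(out, "network_summary.tsv"))
  .writeTSV(net@activities, file.path(out, "confidence_table.tsv"))
  log("load", t0)

  t0 <- as.numeric(Sys.time())
  tp <- transportProfile(net)
  .writeTSV(tp$profile, file.path(out, "transport_profile.tsv"))
  usage <- metaboliteUsage(net)
  .writeTSV(usage, file.path(out, "metabolite_usage.tsv"))
  log("profile", t0)

  t0 <- as.numeric(Sys.time())
  sim <- metabolicSimilarity(net)
  cooc <- cooccurrenceScore(ab)
  writeMatrixTSV(sim, file.path(out, "similarity_matrix.tsv"))
  writeMatrixTSV(cooc, file.path(out, "cooccurrence_matrix.tsv"))
  corr <- NULL
  groupA <- config$groupA; groupB <- config$groupB
  grp <- speciesGroups(net)
  if (!is.null(groupA) && length(groupA) == 1L && length(grp) &&
      groupA %in% grp) groupA <- names(grp)[grp == groupA]
  if (!is.null(groupB) && length(groupB) == 1L && length(grp) &&
      groupB %in% grp) groupB <- names(grp)[grp == groupB]
  if (!is.null(groupA) && !is.null(groupB)) {
    corr <- groupCorrelation(sim, cooc, groupA, groupB, seed = config$seed)
    .writeTSV(data.frame(rho = corr$rho, p_value = corr$p_value,
                         n_pairs = corr$n_pairs, p_method = corr$p_method),
              file.path(out, "cooccurrence_report.tsv"))
  }
  log("cooccur", t0)

  t0 <- as.numeric(Sys.time())
  partition <- partitionSegments(ab, alpha = config$alpha,
                                 minAbundance = config$minAbundance)
  .writeTSV(data.frame(compartment = names(segments(partition)),
                       segment = unname(segments(partition))),
            file.path(out, "segment_partition.tsv"))
  .writeTSV(partitionTests(partition), file.path(out, "segment_tests.tsv"))
  log("segment", t0)

  t0 <- as.numeric(Sys.time())
  model <- InfluenceModel(abundanceMode = config$abundanceMode,
                          normalization = config$normalization,
                          confidenceWeighting = config$confidenceWeighting)
  mat <- influenceMatrix(net, ab, partition, model = model,
                         topK = config$topK)
  writeMatrixTSV(scores(mat), file.path(out, "influence_matrix.tsv"))
  g <- buildInfluenceNetwork(mat, threshold = config$threshold)
  writeSIF(g, file.path(out, "influence_network.sif"))
  writeGraphML(g, file.path(out, "influence_network.graphml"))
  log("influence", t0)

  t0 <- as.numeric(Sys.time())
  report <- centralityReport(g, net, cutoff = config$cutoff,
                             normalization = config$centralityNormalization)
  .writeTSV(report, file.path(out, "centrality_report.tsv"))
  influencers <- report$species[report$influencer]
  classes <- classifyInfluencers(influencers, net)
  .writeTSV(data.frame(class = names(classes$fractions_pct),
                       pct = unname(classes$fractions_pct)),
            file.path(out, "influencer_classes.tsv"))
  byp <- segmentByproductProfile(g, net)
  .writeTSV(byp, file.path(out, "segment_byproducts.tsv"))
  log("analyze", t0)

  t0 <- as.numeric(Sys.time())
  rob <- robustnessSweep(net, ab, partition, model = model,
                         topK = config$topK, threshold = config$threshold,
                         cutoff = config$cutoff,
                         removalFraction = config$removalFraction,
                         mode = config$robustnessMode,
                         seeds = config$robustnessSeeds)
  .writeTSV(rob, file.path(out, "robustness_summary.tsv"))
  jsonlite::write_json(rob, file.path(out, "robustness_summary.json"),
                       dataframe = "columns", digits = NA)
  log("robustness", t0)

  degNet <- NULL
  enzymes <- config$enzymes
  if (is.null(enzymes) && !is.null(config$enzymeFile))
    enzymes <- loadEnzymeTable(config$enzymeFile)
  if (!is.null(enzymes) && nrow(enzymes)) {
    t0 <- as.numeric(Sys.time())
    degs <- selectDegraders(report, net)
    if (nrow(degs)) {
      degNet <- suppressWarnings(
        buildDegradationNetwork(degs, enzymes, net))
      writeSIF(degNet, file.path(out, "degradation_network.sif"))
      writeGraphML(degNet, file.path(out, "degradation_network.graphml"))
      .writeTSV(degNet@nodes, file.path(out, "degradation_nodes.tsv"))
    }
    log("degradation", t0)
  }

  prov <- list(
    seed = config$seed,
    alpha = config$alpha, minAbundance = config$minAbundance,
    abundanceMode = config$abundanceMode,
    normalization = config$normalization,
    topK = if (is.finite(config$topK[1])) config$topK else "all",
    threshold = config$threshold, cutoff = config$cutoff,
    removalFraction = config$removalFraction,
    robustnessMode = config$robustnessMode,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("CrossFeedNet")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(network = net, abundance = ab, partition = partition,
                 influence = mat, influenceNetwork = g, report = report,
                 influencers = influencers, classes = classes,
                 byproducts = byp, robustness = rob, degradation = degNet,
                 correlation = corr, usage = usage, transport = tp))
}
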
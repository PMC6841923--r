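test_that("toy network construction and effective exports", {
  net <- toyNetwork()
  expect_s4_class(net, "CrossFeedingNetwork")
  expect_equal(speciesNames(net), c("A", "B"))
  expect_equal(sort(compoundNames(net)), c("acetate", "cellulose", "glucose"))
  eff <- effectiveExportMatrix(net)
  expect_true(eff["B", "glucose"])   # degradation-product rule
  expect_true(eff["A", "acetate"])
  expect_false(eff["B", "acetate"])
})

test_that("loadNetwork round-trips through files and merging is idempotent", {
  dir <- withr::local_tempdir()
  act <- data.frame(
    species = c("A", "A", "B", "A"),
    compound = c("glucose", "acetate", "cellulose", "Glucose "),
    activity = c("import", "export", "degrades", "EXPORT"),
    n_publications = c(2L, 1L, 4L, 2L), kegg_flag = c(1L, 0L, 1L, 1L))
  cmp <- data.frame(
    compound = c("glucose", "acetate", "cellulose"),
    class = c("metabolite", "metabolite", "macromolecule"),
    degradation_products = c("", "", "glucose;cellobiose"))
  write.table(act, file.path(dir, "act.tsv"), sep = "\t", row.names = FALSE)
  write.table(cmp, file.path(dir, "cmp.tsv"), sep = "\t", row.names = FALSE)
  net <- loadNetwork(file.path(dir, "act.tsv"), file.path(dir, "cmp.tsv"))
  # strain merge: A import + export glucose (name-normalized) collapse to BOTH
  a <- activities(net)
  expect_equal(a$activity[a$species == "A" & a$compound == "glucose"], "BOTH")
  # round trip is a fixed point
  writeSIF(net, file.path(dir, "net.sif"))
  a2 <- a[, c("species", "compound", "activity", "n_publications", "kegg_flag")]
  write.table(a2, file.path(dir, "act2.tsv"), sep = "\t", row.names = FALSE)
  net2 <- loadNetwork(file.path(dir, "act2.tsv"), file.path(dir, "cmp.tsv"))
  expect_equal(activities(net2), activities(net))
})

test_that("loader errors name the offending rows", {
  expect_error(
    makeCrossFeedingNetwork(data.frame(
      species = "A", compound = "x", activity = "consumes")),
    "unknown activity keyword in row\\(s\\) 1")
  expect_error(
    makeCrossFeedingNetwork(
      data.frame(species = "A", compound = "cellulose", activity = "degrades"),
      data.frame(compound = "cellulose", class = "MACROMOLECULE",
                 degradation_products = "")),
    "without degradation products")
  expect_error(
    makeCrossFeedingNetwork(data.frame(
      species = c("A", "A"), compound = c("x", "x"),
      activity = c("import", "import"),
      n_publications = c(1L, 2L), kegg_flag = c(0L, 0L))),
    "conflicting duplicate")
})

test_that("empty activity table yields an empty network", {
  net <- makeCrossFeedingNetwork(
    data.frame(species = character(), compound = character(),
               activity = character()))
  expect_equal(unname(networkSummary(net)["n_species"]), 0)
})

test_that("confidence score is bounded, monotone, and matches closed forms", {
  expect_equal(confidenceScore(7, 10, 0), 49)
  expect_equal(confidenceScore(10, 10, 1), 100)
  expect_equal(confidenceScore(0, 10, 0), 0)
  ns <- 0:10
  s0 <- confidenceScore(ns, 10, 0)
  s1 <- confidenceScore(ns, 10, 1)
  expect_true(all(diff(s0) >= 0) && all(diff(s1) >= 0))  # monotone in n
  expect_true(all(s1 >= s0))                             # monotone in K
  expect_true(all(s0 >= 0 & s1 <= 100))
  expect_error(confidenceScore(3, 0, 0), "nMax")
  expect_error(confidenceScore(11, 10, 0), "n <= nMax")
})

test_that("transport profile counts imports and effective exports", {
  net <- toyNetwork()
  tp <- transportProfile(net)
  p <- tp$profile
  expect_equal(p$n_imported[p$species == "A"], 1)
  expect_equal(p$n_exported[p$species == "A"], 1)
  expect_equal(p$n_imported[p$species == "B"], 0)
  expect_equal(p$n_exported[p$species == "B"], 1)
  # species degrading into two products exports both
  act <- data.frame(species = "D", compound = "cellulose",
                    activity = "degrades")
  cmp <- data.frame(compound = "cellulose", class = "MACROMOLECULE",
                    degradation_products = "glucose;cellobiose")
  tp2 <- transportProfile(makeCrossFeedingNetwork(act, cmp))
  expect_equal(tp2$profile$n_imported, 0)
  expect_equal(tp2$profile$n_exported, 2)
  # conservation: degradation inflates exports, never deflates
  com <- generateCommunity(smallCommunitySpec(seed = 3))
  tp3 <- transportProfile(com$network)
  nIO <- sum(activities(com$network)$activity %in%
               c("IMPORT", "EXPORT", "BOTH"))
  expect_gte(sum(tp3$profile$n_imported + tp3$profile$n_exported), nIO)
})

test_that("metabolite usage fractions count consumers and producers", {
  net <- triadNetwork()
  u <- metaboliteUsage(net)
  expect_equal(u$consumer_pct[u$compound == "glucose"], 100 * 2 / 3)
  expect_equal(u$producer_pct[u$compound == "glucose"], 100 * 1 / 3)
  expect_equal(u$consumer_pct[u$compound == "cellulose"], 0)
  # invariant under species permutation via restriction order
  u2 <- metaboliteUsage(net, restrictTo = c("f2", "deg", "f1"))
  expect_equal(u2[order(u2$compound), ], u[order(u$compound), ],
               ignore_attr = TRUE)
  expect_error(metaboliteUsage(net, restrictTo = character()), "empty")
})

test_that("abundance-transport correlation detects collinearity and noise", {
  net <- triadNetwork()
  tp <- transportProfile(net)$profile
  tot <- tp$n_imported + tp$n_exported
  ab <- flatAbundance(tp$species)
  m <- abundances(ab)
  m[] <- tot[match(rownames(m), tp$species)] * 2.5  # collinear
  expect_equal(abundanceTransportCorrelation(net, AbundanceTable(m)), 1)
  # independent draws at large n give R^2 near 0
  withr::local_seed(42)
  sp <- sprintf("s%03d", 1:500)
  act <- data.frame(
    species = rep(sp, times = sample(1:6, 500, replace = TRUE)))
  act$compound <- paste0("m", sample(50, nrow(act), replace = TRUE))
  act$activity <- sample(c("import", "export"), nrow(act), replace = TRUE)
  act <- act[!duplicated(act), ]
  bignet <- makeCrossFeedingNetwork(act)
  abm <- matrix(rlnorm(500 * 3), 500, 3,
                dimnames = list(sp, c("C", "M", "P1")))
  expect_lt(abundanceTransportCorrelation(bignet, AbundanceTable(abm)), 0.05)
  expect_error(abundanceTransportCorrelation(net, flatAbundance(c("A", "zz"))),
               "at least 3")
})

test_that("graph exports are schema-valid", {
  dir <- withr::local_tempdir()
  net <- triadNetwork()
  sif <- file.path(dir, "net.sif")
  writeSIF(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(activities(net)))
  expect_true(all(grepl("\t(imports|exports|imports-exports|degrades)\t",
                        lines)))
  gml <- file.path(dir, "net.graphml")
  writeGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3 + 4)
  expect_true("confidence" %in% igraph::edge_attr_names(g))
})
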
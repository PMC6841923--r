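test_that("Hotpep filtering is enforced and idempotent", {
  enz <- data.frame(
    species = c("d1", "d1", "d2", "d2"),
    enzyme = c("endoglucanase", "beta-glucosidase", "endo-1,4-beta-xylanase",
               "cellobiohydrolase"),
    ghfamily = c("GH5", "GH1", "GH10", "GH48"),
    substrate = c("cellulose", "cellulose", "hemicellulose", "cellulose"),
    source = c("CAZY", "DBCAN2_HOTPEP", "DBCAN2_HOTPEP", "CURATED"),
    frequency = c(NA, 2.0, 5.1, NA),
    hits = c(NA, 12, 30, NA))
  f1 <- loadEnzymeTable(enz)
  expect_equal(nrow(f1), 3)  # the frequency-2.0 Hotpep row fails the filter
  expect_false("beta-glucosidase" %in% f1$enzyme)
  expect_identical(loadEnzymeTable(f1), f1)  # idempotent
  expect_equal(nrow(loadEnzymeTable(enz, enforceFilters = FALSE)), 4)
  expect_error(loadEnzymeTable(transform(enz, source = "GUESS")),
               "unknown enzyme source")
})

test_that("degrader selection filters influencers with DEGRADES edges", {
  net <- triadNetwork()
  rep <- data.frame(species = c("deg", "f1", "f2"),
                    betweenness = c(0.5, 0.9, 0.1),
                    influencer = c(TRUE, TRUE, FALSE))
  d <- selectDegraders(rep, net)
  expect_equal(d$species, "deg")  # f1 is influential but not a degrader
  expect_equal(d$substrates, "cellulose")
  # no DEGRADES edges -> empty
  net2 <- makeCrossFeedingNetwork(data.frame(
    species = "x", compound = "m", activity = "import"))
  rep2 <- data.frame(species = "x", betweenness = 1, influencer = TRUE)
  expect_equal(nrow(selectDegraders(rep2, net2)), 0)
})

test_that("toy degradation chain joins all five node types", {
  act <- data.frame(
    species = c("d", "f", "f"),
    compound = c("cellulose", "glucose", "acetate"),
    activity = c("degrades", "import", "export"))
  cmp <- data.frame(compound = c("cellulose", "glucose", "acetate"),
                    class = c("MACROMOLECULE", "SMALL_METABOLITE",
                              "SMALL_METABOLITE"),
                    degradation_products = c("glucose", "", ""))
  net <- makeCrossFeedingNetwork(act, cmp)
  enz <- data.frame(species = "d", enzyme = "endoglucanase",
                    ghfamily = "GH5", substrate = "cellulose",
                    source = "CAZY", frequency = NA, hits = NA)
  dn <- buildDegradationNetwork("d", enz, net)
  expect_setequal(nodes(dn)$type,
                  c("degrader", "enzyme", "macromolecule",
                    "small_metabolite", "fermenter"))
  e <- edges(dn)
  expect_setequal(e$type, c("secretes", "hydrolyzes", "yields",
                            "consumes", "excretes"))
  # chain: d -> endoglucanase -> cellulose -> glucose -> f -> acetate
  expect_true(any(e$from == "d" & e$to == "endoglucanase"))
  expect_true(any(e$from == "cellulose" & e$to == "glucose"))
  expect_true(any(e$from == "glucose" & e$to == "f"))
  expect_true(any(e$from == "f" & e$to == "acetate"))
  # consumes/excretes edges carry the underlying activity confidence
  a <- activities(net)
  expect_equal(e$confidence[e$type == "consumes"],
               a$confidence[a$species == "f" & a$compound == "glucose"])
  # empty fermenter set truncates after yields
  dn2 <- buildDegradationNetwork("d", enz, net, fermenters = character())
  expect_false(any(edges(dn2)$type %in% c("consumes", "excretes")))
  # degrader missing from the enzyme table is kept, with a warning
  expect_warning(dn3 <- buildDegradationNetwork(
    c("d", "f"), enz, net, fermenters = character()), "without enzyme")
  expect_true("f" %in% nodes(dn3)$name)
})

test_that("degradation network is a faithful projection of the community", {
  com <- generateCommunity(smallCommunitySpec(seed = 13))
  part <- partitionSegments(com$abundance)
  pip <- CrossFeedNet:::.influencePipeline(com$network, com$abundance, part)
  degs <- selectDegraders(pip$report, com$network)
  if (!nrow(degs)) skip("no influential degrader in this community")
  dn <- suppressWarnings(
    buildDegradationNetwork(degs, com$enzymes, com$network))
  e <- edges(dn)
  a <- activities(com$network)
  imp <- a[a$activity %in% c("IMPORT", "BOTH"), ]
  exp <- a[a$activity %in% c("EXPORT", "BOTH"), ]
  # referential integrity: every consumes/excretes edge has a source activity
  cons <- e[e$type == "consumes", ]
  expect_true(all(paste(cons$to, cons$from) %in%
                    paste(imp$species, imp$compound)))
  exc <- e[e$type == "excretes", ]
  expect_true(all(paste(exc$from, exc$to) %in%
                    paste(exp$species, exp$compound)))
  dir <- withr::local_tempdir()
  writeGraphML(dn, file.path(dir, "deg.graphml"))
  ig <- igraph::read_graph(file.path(dir, "deg.graphml"), format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(nodes(dn)))
})
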
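test_that("influence score sign contract on minimal pairs", {
  mk <- function(acts) makeCrossFeedingNetwork(acts)
  ab <- c(p = 1, q = 1)
  feed <- mk(data.frame(species = c("p", "q"), compound = "m1",
                        activity = c("export", "import")))
  expect_equal(influenceScore("p", "q", feed, ab), 1)   # pure cross-feeding
  compete <- mk(data.frame(species = c("p", "q"), compound = "m1",
                           activity = c("import", "import")))
  expect_equal(influenceScore("p", "q", compete, ab), -1)  # pure competition
  disjoint <- mk(data.frame(species = c("p", "q"), compound = c("m1", "m2"),
                            activity = "import"))
  expect_equal(influenceScore("p", "q", disjoint, ab), 0)
  # abundance scaling: doubling n_p doubles I_pq
  expect_equal(influenceScore("p", "q", feed, c(p = 2, q = 1)), 2)
  expect_equal(influenceScore("p", "q", feed, c(p = 1, q = 2)), 0.5)
  # q importing nothing scores 0 with a warning
  exporter <- mk(data.frame(species = c("p", "q"), compound = c("m1", "m2"),
                            activity = c("export", "export")))
  expect_warning(s <- influenceScore("p", "q", exporter, ab), "imports nothing")
  expect_equal(s, 0)
  expect_error(influenceScore("p", "q", feed, c(p = 1)), "missing abundance")
  expect_error(influenceScore("p", "p", feed, ab), "distinct")
})

test_that("provider-ambiguity resolves to cross-feeding and monotonicity holds", {
  ab <- c(p = 1, q = 1)
  # p imports AND exports m -> provider, positive
  both <- makeCrossFeedingNetwork(data.frame(
    species = c("p", "q"), compound = "m1",
    activity = c("both", "import")))
  expect_equal(influenceScore("p", "q", both, ab), 1)
  # adding an export q imports never decreases I_pq
  base <- data.frame(species = c("p", "q", "q"),
                     compound = c("m1", "m1", "m2"),
                     activity = c("import", "import", "import"))
  s0 <- influenceScore("p", "q", makeCrossFeedingNetwork(base), ab)
  plus <- rbind(base, data.frame(species = "p", compound = "m2",
                                 activity = "export"))
  s1 <- influenceScore("p", "q", makeCrossFeedingNetwork(plus), ab)
  expect_gt(s1, s0)
  # adding a shared import never increases it
  minus <- rbind(base, data.frame(species = "p", compound = "m2",
                                  activity = "import"))
  s2 <- influenceScore("p", "q", makeCrossFeedingNetwork(minus), ab)
  expect_lt(s2, s0)
})

test_that("triad influence matrix has the hand-derived sign pattern", {
  net <- triadNetwork()
  ab <- flatAbundance(c("deg", "f1", "f2"))
  part <- partitionSegments(ab)
  mat <- influenceMatrix(net, ab, part)
  s <- scores(mat)
  expect_true(all(is.na(diag(s))))
  expect_gt(s["deg", "f1"], 0)   # degrader feeds both fermenters
  expect_gt(s["deg", "f2"], 0)
  expect_lt(s["f1", "f2"], 0)    # fermenters compete for glucose
  expect_lt(s["f2", "f1"], 0)
  expect_equal(s["f1", "deg"], 0)  # degrader imports nothing
  g <- buildInfluenceNetwork(mat, threshold = 0)
  expect_equal(sum(edges(g)$sign > 0), 2)
  expect_equal(sum(edges(g)$sign < 0), 2)
  # threshold above max |I| keeps all nodes, no edges
  g2 <- buildInfluenceNetwork(mat, threshold = max(abs(s), na.rm = TRUE) + 1)
  expect_equal(nrow(edges(g2)), 0)
  expect_equal(nrow(nodes(g2)), 3)
})

test_that("top-k segment selection caps the species per segment", {
  com <- generateCommunity(smallCommunitySpec(seed = 2, nSpecies = 80L,
                                              nMetabolites = 140L))
  part <- partitionSegments(com$abundance)
  segs <- sort(unique(unname(segments(part))))
  k <- stats::setNames(rep(10, length(segs)), segs)
  mat <- influenceMatrix(com$network, com$abundance, part, topK = k)
  expect_lte(nrow(scores(mat)), 10 * length(segs))
  tab <- table(segments(mat))
  expect_true(all(tab <= 10))
  # warning when topK exceeds availability
  expect_warning(
    influenceMatrix(triadNetwork(), flatAbundance(c("deg", "f1", "f2")),
                    partitionSegments(flatAbundance(c("deg", "f1", "f2"))),
                    topK = 99), "only")
})

test_that("planted relations are recovered sign-exactly", {
  com <- generateCommunity(smallCommunitySpec(seed = 4, nSpecies = 80L,
                                              nMetabolites = 140L))
  part <- partitionSegments(com$abundance)
  mat <- influenceMatrix(com$network, com$abundance, part, topK = Inf)
  s <- scores(mat)
  tm <- plantedSignMatrix(com$truth, speciesNames(com$network))
  common <- intersect(rownames(s), rownames(tm))
  s <- s[common, common]; tm <- tm[common, common]
  ok <- !is.na(tm)
  expect_gte(mean(sign(s[ok]) == tm[ok]), 0.99)
  # I_pq = 0 whenever p's metabolite sets are disjoint from q's imports
  imp <- importMatrix(com$network)
  eff <- effectiveExportMatrix(com$network)
  zero <- which(tm == 0, arr.ind = TRUE)
  pick <- zero[seq_len(min(50, nrow(zero))), , drop = FALSE]
  for (i in seq_len(nrow(pick))) {
    p <- common[pick[i, 1]]; q <- common[pick[i, 2]]
    touched <- (imp[p, ] | eff[p, ]) & imp[q, ]
    if (!any(touched)) expect_identical(unname(s[p, q]), 0)
  }
})

test_that("influence network exports round-trip through SIF and GraphML", {
  dir <- withr::local_tempdir()
  net <- triadNetwork()
  ab <- flatAbundance(c("deg", "f1", "f2"))
  g <- buildInfluenceNetwork(
    influenceMatrix(net, ab, partitionSegments(ab)), threshold = 0)
  writeSIF(g, file.path(dir, "g.sif"))
  lines <- readLines(file.path(dir, "g.sif"))
  expect_equal(length(lines), nrow(edges(g)))
  expect_true(all(grepl("\t(pos|neg)\t", lines)))
  writeGraphML(g, file.path(dir, "g.graphml"))
  ig <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(igraph::gorder(ig), 3)
  expect_setequal(igraph::vertex_attr(ig, "segment"), "S1")
})
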
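test_that("betweenness matches hand-derived path graphs", {
  # directed path a -> b -> c: b sits on the single (a, c) pair
  e <- data.frame(from = c("a", "b"), to = c("b", "c"))
  cb <- betweennessCentrality(e)
  expect_equal(unname(cb), c(0, 1, 0))
  # out-star: no path passes through the hub
  star <- data.frame(from = rep("h", 4), to = paste0("x", 1:4))
  expect_equal(unname(betweennessCentrality(star)["h"]), 0)
  # edgeless graph
  g0 <- new("InfluenceNetwork",
            nodes = data.frame(species = c("a", "b", "c"), segment = "S1"),
            edges = data.frame(from = character(), to = character(),
                               weight = numeric(), sign = numeric()),
            threshold = 0)
  expect_equal(unname(betweennessCentrality(g0)), c(0, 0, 0))
  # directed normalization halves the component-normalized value
  expect_equal(betweennessCentrality(e, normalization = "directed")["b"],
               cb["b"] / 2, ignore_attr = TRUE)
})

test_that("production betweenness equals the brute-force oracle exactly", {
  withr::local_seed(17)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    e <- randomDigraph(n, pEdge = runif(1, 0.15, 0.5))
    nodes <- letters[seq_len(n)]
    fast <- betweennessCentrality(e, nodeNames = nodes)
    slow <- bruteBetweenness(e, nodes)
    expect_equal(fast, slow, tolerance = 1e-12)
    # raw sums also agree with igraph's directed betweenness
    ig <- igraph::graph_from_data_frame(e, directed = TRUE,
                                        vertices = nodes)
    expect_equal(unname(betweennessCentrality(e, nodeNames = nodes,
                                              normalization = "none")),
                 unname(igraph::betweenness(ig, directed = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("influencer identification uses a strict mean cutoff", {
  cb <- c(a = 0.2, b = 0.2, c = 0.2)
  r <- identifyInfluencers(cb)
  expect_equal(r$influencers, character(0))  # all equal -> none above mean
  expect_equal(r$cutoff, 0.2)
  cb2 <- c(a = 0.5, b = 0.1, c = 0.0, d = 0.0)
  r2 <- identifyInfluencers(cb2)
  expect_equal(r2$influencers, "a")
  expect_equal(r2$fraction_pct, 25)
  # fraction is non-increasing in the cutoff
  cuts <- seq(0, 0.5, by = 0.05)
  fr <- vapply(cuts, function(ct)
    identifyInfluencers(cb2, cutoff = ct)$fraction_pct, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("planted hub degrader ranks first by betweenness", {
  hits <- 0
  for (s in 1:15) {
    com <- generateCommunity(smallCommunitySpec(seed = s))
    part <- partitionSegments(com$abundance)
    mat <- influenceMatrix(com$network, com$abundance, part, topK = Inf)
    g <- buildInfluenceNetwork(mat)
    cb <- betweennessCentrality(g)
    if (names(which.max(cb)) == com$truth$hub) hits <- hits + 1
  }
  expect_gte(hits, 14)
})

test_that("functional classification distinguishes degraders and fermenters", {
  act <- data.frame(
    species = c("d", "f", "b", "b", "o"),
    compound = c("cellulose", "acetate", "cellulose", "acetate", "m1"),
    activity = c("degrades", "export", "degrades", "export", "import"))
  cmp <- data.frame(compound = c("cellulose", "acetate", "m1"),
                    class = c("MACROMOLECULE", "SMALL_METABOLITE",
                              "SMALL_METABOLITE"),
                    degradation_products = c("glucose", "", ""))
  net <- makeCrossFeedingNetwork(act, cmp)
  cl <- classifyInfluencers(c("d", "f", "b", "o"), net)
  expect_equal(unname(cl$classes[c("d", "f", "b", "o")]),
               c("DEGRADER", "FERMENTER", "BOTH", "OTHER"))
  expect_equal(unname(cl$fractions_pct), c(25, 25, 25, 25))
  cl2 <- classifyInfluencers(c("d", "b"), net)
  expect_equal(unname(cl2$fractions_pct[c("DEGRADER", "BOTH")]), c(50, 50))
  expect_error(classifyInfluencers("nope", net), "not in network")
})

test_that("centrality report fields are consistent with the network", {
  com <- generateCommunity(smallCommunitySpec(seed = 8))
  part <- partitionSegments(com$abundance)
  pip <- CrossFeedNet:::.influencePipeline(com$network, com$abundance, part)
  rep <- pip$report
  e <- edges(pip$network)
  # out-degree equals retained outgoing edges
  for (s in rep$species[1:10])
    expect_equal(rep$out_degree[rep$species == s], sum(e$from == s))
  # positive/negative fractions count receiving nodes over (n - 1)
  n <- nrow(rep)
  i <- which.max(rep$out_degree)
  expect_equal(rep$positive_influence_pct[i],
               100 * sum(e$from == rep$species[i] & e$sign > 0) / (n - 1))
  # the printed normalization divides directed path sums by the undirected
  # pair count, so the directed-graph ceiling is 2
  expect_true(all(rep$betweenness >= 0 & rep$betweenness <= 2))
  expect_equal(rep$influencer, rep$betweenness > attr(rep, "cutoff"))
})

test_that("segment byproduct profiles count producers and consumers", {
  net <- triadNetwork()
  ab <- flatAbundance(c("deg", "f1", "f2"))
  g <- buildInfluenceNetwork(influenceMatrix(net, ab, partitionSegments(ab)))
  prof <- segmentByproductProfile(g, net)
  gl <- prof[prof$compound == "glucose", ]
  expect_equal(gl$producer_pct, 100 / 3)   # only the degrader yields glucose
  expect_equal(gl$consumer_pct, 200 / 3)   # both fermenters consume it
  # a segment where everyone exports acetate reaches 100%
  act <- data.frame(species = c("x", "y", "z"), compound = "acetate",
                    activity = "export")
  net2 <- makeCrossFeedingNetwork(act)
  ab2 <- flatAbundance(c("x", "y", "z"))
  g2 <- buildInfluenceNetwork(influenceMatrix(net2, ab2,
                                              partitionSegments(ab2)))
  prof2 <- segmentByproductProfile(g2, net2)
  expect_equal(prof2$producer_pct[prof2$compound == "acetate"], 100)
  expect_true(all(prof2$producer_rank[prof2$compound == "acetate"] == 1))
})
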
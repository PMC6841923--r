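test_that("metabolic similarity is Jaccard on import sets", {
  act <- data.frame(
    species = c("p", "p", "q", "q", "r", "r", "s"),
    compound = c("glucose", "xylose", "glucose", "maltose",
                 "glucose", "xylose", "acetate"),
    activity = c(rep("import", 6), "export"))
  net <- makeCrossFeedingNetwork(act)
  sim <- metabolicSimilarity(net)
  expect_equal(sim["p", "q"], 1 / 3)
  expect_equal(sim["p", "r"], 1)       # identical import sets
  expect_equal(sim["q", "r"], 1 / 3)
  expect_equal(sim["p", "s"], 0)       # s imports nothing
  expect_equal(sim["s", "s"], 0)       # empty-set convention
  expect_equal(sim, t(sim))
  expect_true(all(sim >= 0 & sim <= 1))
})

test_that("co-occurrence is Spearman over compartments", {
  m <- rbind(s1 = 1:6, s2 = c(2, 1, 4, 3, 6, 5), s3 = 6:1,
             s4 = rep(2, 6))
  colnames(m) <- c("C", "M", "P1", "P3", "P4", "P5")
  cc <- cooccurrenceScore(AbundanceTable(m))
  expect_equal(cc["s1", "s2"], 0.8285714, tolerance = 1e-6)
  expect_equal(cc["s1", "s3"], -1)      # reversed ranks
  expect_equal(cc["s1", "s1"], 1)
  expect_equal(attr(cc, "excluded"), "s4")  # zero variance flagged
  expect_true(all(is.na(cc["s4", ])))
  # independent oracle on the derived example
  expect_equal(cc["s1", "s2"],
               cor(1:6, c(2, 1, 4, 3, 6, 5), method = "spearman"))
  expect_error(cooccurrenceScore(flatAbundance("a", c("C", "M"))), ">= 3")
})

test_that("group correlation is symmetric and matches a perfect ranking", {
  withr::local_seed(1)
  n <- 12
  sp <- paste0("s", seq_len(n))
  sim <- matrix(runif(n * n), n, n, dimnames = list(sp, sp))
  sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
  cooc <- sim  # identical values -> rho 1
  A <- sp[1:6]; B <- sp[7:12]
  r <- groupCorrelation(sim, cooc, A, B)
  expect_equal(r$rho, 1)
  expect_equal(r$n_pairs, 36)
  r2 <- groupCorrelation(sim, cooc, B, A)
  expect_equal(r2$rho, r$rho)
  expect_equal(r2$p_value, r$p_value)
  # large-sample t approximation agrees with cor.test
  cooc2 <- matrix(runif(n * n), n, n, dimnames = list(sp, sp))
  cooc2[lower.tri(cooc2)] <- t(cooc2)[lower.tri(cooc2)]
  r3 <- groupCorrelation(sim, cooc2, A, B)
  x <- sim[cbind(rep(A, times = 6), rep(B, each = 6))]
  y <- cooc2[cbind(rep(A, times = 6), rep(B, each = 6))]
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r3$rho, unname(ct$estimate))
  expect_equal(r3$p_method, "t")
  # small pair counts use the seeded permutation test, reproducibly
  r4 <- groupCorrelation(sim, cooc2, sp[1:3], sp[7:9], seed = 5)
  r5 <- groupCorrelation(sim, cooc2, sp[1:3], sp[7:9], seed = 5)
  expect_equal(r4$p_method, "permutation")
  expect_identical(r4$p_value, r5$p_value)
  expect_error(groupCorrelation(sim, cooc, sp[1], sp[2:3]), "at least 5")
})

test_that("planted cross-feeding couples similarity and co-occurrence", {
  # guild B imports exactly what guild A exports; abundances positively
  # coupled within pairs -> cross-group rho positive in most seeds
  hits <- 0
  for (s in 1:10) {
    withr::local_seed(s)
    nPair <- 8
    A <- paste0("a", 1:nPair); B <- paste0("b", 1:nPair)
    act <- do.call(rbind, lapply(seq_len(nPair), function(i) {
      mets <- paste0("m", i, "_", 1:2)
      rbind(
        data.frame(species = A[i], compound = mets, activity = "export"),
        data.frame(species = A[i], compound = paste0("base", i),
                   activity = "import"),
        data.frame(species = B[i], compound = mets, activity = "import"))
    }))
    net <- makeCrossFeedingNetwork(act)
    base <- matrix(rlnorm(nPair * 6, sdlog = 1), nPair, 6)
    abm <- rbind(base * rlnorm(nPair * 6, sdlog = 0.2),
                 base * rlnorm(nPair * 6, sdlog = 0.2))
    dimnames(abm) <- list(c(A, B), c("C", "M", "P1", "P3", "P4", "P5"))
    r <- groupCorrelation(metabolicSimilarity(net, mode = "import_export"),
                          cooccurrenceScore(AbundanceTable(abm)), A, B)
    if (r$rho > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
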
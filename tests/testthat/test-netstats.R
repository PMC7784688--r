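mkIm <- function(cts, nrep = 3L) InfectionMatrix(cts, nrep)

test_that("infection score is the mean per-replicate clearing frequency", {
  n <- 35
  ids <- sprintf("s%02d", 1:n)
  cts <- matrix(3L, n, n, dimnames = list(ids, ids))
  im <- mkIm(cts)
  expect_equal(infectionScore(im, "s01"), 1)
  cts[] <- 0L
  expect_equal(infectionScore(mkIm(cts), "s01"), 0)
  cts["s01", "s07"] <- 3L
  expect_equal(infectionScore(mkIm(cts), "s01"), 1 / 35)
  expect_error(infectionScore(im, "nope"), "unknown producer")
})

test_that("infection calls and reproducibility follow the replicate counts", {
  ids <- c("a", "b")
  cts <- matrix(c(3L, 1L, 2L, 0L), 2, 2, dimnames = list(ids, ids))
  im <- mkIm(cts)
  expect_equal(sum(infectedPairs(im)), 3L)
  expect_equal(sum(infectedPairs(im, rule = "all")), 1L)

  cts4 <- matrix(c(3L, 3L, 1L, 2L), 2, 2, dimnames = list(ids, ids))
  rep4 <- replicateReproducibility(mkIm(cts4))
  expect_equal(rep4$overall, 0.5)
  expect_equal(rep4$nInfected, 4L)
  expect_equal(replicateReproducibility(mkIm(matrix(3L, 2, 2,
    dimnames = list(ids, ids))))$overall, 1)
  # no infections: flagged NA, not zero
  none <- replicateReproducibility(mkIm(matrix(0L, 2, 2,
    dimnames = list(ids, ids))))
  expect_true(is.na(none$overall))
  # stratified by capsule type
  clt <- c(a = "KL1", b = "KL2")
  strat <- replicateReproducibility(mkIm(cts4), clt)
  expect_equal(strat$sameClt, 0.5)   # diagonal pairs: counts 3 and 2
  expect_equal(strat$crossClt, 0.5)  # off-diagonal: counts 3 and 1
})

test_that("CLT contingency counts ordered pairs with and without self", {
  ids <- c("a1", "a2", "b1", "b2")
  clt <- setNames(c("KL1", "KL1", "KL2", "KL2"), ids)
  cts <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  tab <- cltContingency(mkIm(cts), clt, includeSelf = TRUE)
  expect_equal(unname(tab), rbind(c(0L, 8L), c(0L, 8L)))
  tabNoSelf <- cltContingency(mkIm(cts), clt, includeSelf = FALSE)
  expect_equal(sum(tabNoSelf), 16L - 4L)
  expect_equal(sum(tab), 16L)
  # single-CLT panel: cross row is all zero
  one <- setNames(rep("KL1", 4), ids)
  expect_equal(unname(cltContingency(mkIm(cts), one)[2, ]), c(0L, 0L))
  expect_error(cltContingency(mkIm(cts), clt[-1]), "missing label")
})

test_that("exact 2x2 test matches hand enumeration and conventions", {
  r <- fisherExact2x2(rbind(c(1, 1), c(1, 1)))
  expect_equal(oddsRatio(r), 1)
  expect_equal(pValue(r), 1)
  r <- fisherExact2x2(rbind(c(35, 70), c(40, 1080)))
  expect_equal(oddsRatio(r), 13.5)
  expect_lt(pValue(r), 1e-4)
  r <- fisherExact2x2(rbind(c(5, 0), c(0, 5)))
  expect_equal(pValue(r), 2 / 252)
  expect_equal(oddsRatio(r), Inf)
  r <- fisherExact2x2(rbind(c(0, 5), c(0, 5)))   # degenerate column
  expect_equal(pValue(r), 1)
  expect_true(is.na(oddsRatio(r)))
  expect_error(fisherExact2x2(rbind(c(-1, 1), c(1, 1))), "non-negative")
})

test_that("exact test agrees with stats::fisher.test on random tables", {
  set.seed(55)
  for (i in 1:50) {
    tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2, 2)
    if (sum(tab) == 0) next
    ours <- pValue(fisherExact2x2(tab))
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(ours, ref, tolerance = 1e-7, info = paste(tab, collapse = ","))
  }
})

test_that("LPS contingency flags degenerate single-serotype panels", {
  ids <- c("a", "b")
  cts <- matrix(c(0L, 3L, 0L, 0L), 2, 2, dimnames = list(ids, ids))
  res <- lpsContingency(mkIm(cts), setNames(c("O1", "O1"), ids))
  expect_equal(unname(contingencyTable(res)[2, ]), c(0L, 0L))
  expect_equal(pValue(res), 1)  # degenerate margin
})

test_that("prophage similarity exposure uses target-producer wGRR", {
  ids <- c("A", "B", "C")
  cts <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  cts["A", "B"] <- 2L
  im <- mkIm(cts)
  w <- matrix(0, 3, 3, dimnames = list(c("p1", "p2", "p3"),
                                       c("p1", "p2", "p3")))
  diag(w) <- 1
  w["p1", "p2"] <- w["p2", "p1"] <- 0.9   # B's p2 similar to A's p1
  byStrain <- list(A = "p1", B = "p2", C = "p3")
  res <- prophageSimilarityAssociation(im, w, byStrain)
  tab <- contingencyTable(res)
  expect_equal(tab["similar_prophage", "infected"], 1L)
  expect_equal(sum(tab), 6L)
  # prophage-free target is never exposed
  byStrain$B <- character(0)
  res <- prophageSimilarityAssociation(im, w, byStrain)
  expect_equal(sum(contingencyTable(res)["similar_prophage", ]), 0L)
})

test_that("repressor pair fraction counts dissimilar phages with like repressors", {
  ids <- paste0("p", 1:5)
  w <- matrix(0.1, 5, 5, dimnames = list(ids, ids)); diag(w) <- 1
  rs <- matrix(NA_real_, 5, 5, dimnames = list(ids, ids))
  expect_equal(repressorPairFraction(w, rs), 0)      # no repressors annotated
  rs["p1", "p2"] <- rs["p2", "p1"] <- 0.95
  rs["p3", "p4"] <- rs["p4", "p3"] <- 0.85
  rs["p1", "p5"] <- rs["p5", "p1"] <- 0.5
  expect_equal(repressorPairFraction(w, rs), 2 / 10)
  # identical phages fail the wGRR ceiling
  w[] <- 1
  expect_equal(repressorPairFraction(w, rs), 0)
})

test_that("spearman rho matches hand-ranked examples", {
  x <- c(1, 2, 3, 4)
  expect_equal(spearmanRho(x, x)$rho, 1)
  expect_equal(spearmanRho(x, rev(x))$rho, -1)
  expect_equal(spearmanRho(x, c(1, 3, 2, 4))$rho, 0.8)
  expect_true(is.na(spearmanRho(c(1, 1, 1), c(1, 2, 3))$rho))
  set.seed(8)
  xx <- rnorm(30); yy <- xx + rnorm(30, sd = 0.3)
  res <- spearmanRho(xx, yy, nPermutations = 2000, seed = 4)
  expect_lt(res$p, 0.01)
  res2 <- spearmanRho(xx, yy, nPermutations = 2000, seed = 4)
  expect_equal(res$p, res2$p)   # seeded permutation test reproduces
})

test_that("GC comparison reports paired signed-rank results", {
  expect_error(gcComparison(c(0.5, 0.5), c(0.5, 0.5)), "insufficient")
  same <- rep(0.5, 6)
  res <- gcComparison(same, same)
  expect_equal(res$p, 1)
  expect_equal(res$median_difference_points, 0)
  # n = 6, all negative differences: exact two-sided p = 2/2^6
  host <- rep(0.55, 6)
  ph <- host - c(0.02, 0.03, 0.04, 0.05, 0.06, 0.07)
  res <- gcComparison(ph, host)
  expect_equal(res$p, 2 / 64)
  expect_equal(res$median_difference_points, -4.5)
})

test_that("synthetic prophages generated 5 GC points low are recovered", {
  set.seed(77)
  hostGc <- runif(30, 0.5, 0.6)
  prophGc <- vapply(hostGc, function(g)
    gcContent(randomDnaStr(8000, gc = g - 0.05)), numeric(1))
  res <- gcComparison(prophGc, hostGc)
  expect_lt(res$p, 0.001)
  expect_lt(abs(res$median_difference_points + 5), 1)
})
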
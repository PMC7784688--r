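mkHit <- function(q, s, pid = 80, ev = 1e-10, bs = 100, qc = 0.9, sc = 0.9) {
  data.frame(query_id = q, subject_id = s, pct_identity = pid, length = 100,
             evalue = ev, bitscore = bs, query_coverage = qc,
             subject_coverage = sc, stringsAsFactors = FALSE)
}

test_that("filterHits applies strict e-value and inclusive identity/coverage", {
  hits <- rbind(
    mkHit("a1", "b1", pid = 34.9),                  # below identity
    mkHit("a2", "b2", pid = 80, ev = 1e-3),         # evalue not < 1e-4
    mkHit("a3", "b3", pid = 35, ev = 1e-5, qc = 0.5, sc = 0.5),  # boundary keep
    mkHit("a4", "b4", pid = 80, qc = 0.49))         # coverage fail
  kept <- filterHits(hits)
  expect_identical(kept$query_id, "a3")
  # query-only coverage mode re-admits the subject-coverage failure
  hits2 <- mkHit("a5", "b5", qc = 0.9, sc = 0.1)
  expect_equal(nrow(filterHits(hits2, coverageMode = "both")), 0L)
  expect_equal(nrow(filterHits(hits2, coverageMode = "query")), 1L)
})

test_that("bestHits ranks by bitscore, evalue, identity, then subject id", {
  prot <- list(A = c("a1"), B = c("b1", "b2"))
  h <- rbind(mkHit("a1", "b1", bs = 50), mkHit("a1", "b2", bs = 60))
  expect_identical(bestHits(h, prot)$subject_id, "b2")
  h <- rbind(mkHit("a1", "b1", bs = 60, ev = 1e-10),
             mkHit("a1", "b2", bs = 60, ev = 1e-20))
  expect_identical(bestHits(h, prot)$subject_id, "b2")
  h <- rbind(mkHit("a1", "b1", bs = 60, ev = 1e-10, pid = 70),
             mkHit("a1", "b2", bs = 60, ev = 1e-10, pid = 90))
  expect_identical(bestHits(h, prot)$subject_id, "b2")
  h <- rbind(mkHit("a1", "b2"), mkHit("a1", "b1"))
  expect_identical(bestHits(h, prot)$subject_id, "b1")
  expect_error(bestHits(mkHit("zz", "b1"), prot), "not assigned")
})

test_that("bidirectional best hits require reciprocity and average identities", {
  prot <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  h <- rbind(mkHit("a1", "b1", pid = 40), mkHit("b1", "a1", pid = 42))
  best <- bestHits(h, prot)
  pairs <- bidirectionalBestHits(best, "A", "B")
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$identity, 41)
  # broken reciprocity: b1's best is a2
  h <- rbind(mkHit("a1", "b1", bs = 100),
             mkHit("b1", "a2", bs = 90), mkHit("b1", "a1", bs = 80))
  pairs <- bidirectionalBestHits(bestHits(h, prot), "A", "B")
  expect_equal(nrow(pairs), 0L)
})

test_that("wGRR reproduces the worked examples and bounds", {
  p3 <- data.frame(protein_a = paste0("a", 1:3), protein_b = paste0("b", 1:3),
                   identity = 100)
  expect_equal(wgrr(p3, 100, 150)$wgrr, 0.03)
  p6 <- data.frame(protein_a = paste0("a", 1:6), protein_b = paste0("b", 1:6),
                   identity = 50)
  expect_equal(wgrr(p6, 100, 100)$wgrr, 0.03)
  p0 <- p3[0, ]
  expect_equal(wgrr(p0, 10, 10)$wgrr, 0)
  # self comparison: all n proteins perfectly paired
  pn <- data.frame(protein_a = paste0("a", 1:10), protein_b = paste0("b", 1:10),
                   identity = 100)
  expect_equal(wgrr(pn, 10, 10)$wgrr, 1)
  expect_error(wgrr(pn, 5, 10), "exceed")
})

test_that("wgrrMatrix handles disjoint and duplicated proteomes", {
  prot <- list(A = paste0("a", 1:5), B = paste0("b", 1:5))
  none <- mkHit("a1", "b1")[0, ]
  res <- wgrrMatrix(prot, none)
  expect_equal(res$wgrr["A", "B"], 0)
  expect_equal(diag(res$wgrr), c(A = 1, B = 1))
  # duplicated proteome: every protein reciprocally 100% identical
  dup <- do.call(rbind, lapply(1:5, function(i)
    rbind(mkHit(paste0("a", i), paste0("b", i), pid = 100, qc = 1, sc = 1),
          mkHit(paste0("b", i), paste0("a", i), pid = 100, qc = 1, sc = 1))))
  res <- wgrrMatrix(prot, dup)
  expect_equal(res$wgrr["A", "B"], 1)
  expect_equal(res$wgrr, t(res$wgrr))
})

test_that("BBH sets equal the exhaustive best-hit search on random panels", {
  set.seed(101)
  for (rep in 1:25) {
    panel <- randomHitsPanel(nProteomes = 5, nProteins = 8)
    best <- bestHits(filterHits(panel$hits), panel$proteins)
    ids <- names(panel$proteins)
    for (k in 1:3) {
      ab <- sample(ids, 2)
      got <- bidirectionalBestHits(best, ab[1], ab[2])
      want <- bruteBbh(filterHits(panel$hits), panel$proteins, ab[1], ab[2])
      got <- got[order(got$protein_a), , drop = FALSE]
      want <- want[order(want$protein_a), , drop = FALSE]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("wGRR is symmetric and bounded on random panels", {
  set.seed(202)
  for (rep in 1:10) {
    panel <- randomHitsPanel()
    res <- wgrrMatrix(panel$proteins, panel$hits)
    expect_equal(res$wgrr, t(res$wgrr))
    expect_true(all(res$wgrr >= 0 & res$wgrr <= 1))
  }
})

test_that("planted-homolog proteome pairs recover n_hom * q / m", {
  for (cfg in list(list(q = 1.0, nHom = 3, seed = 5),
                   list(q = 0.5, nHom = 6, seed = 6),
                   list(q = 0.7, nHom = 20, seed = 7))) {
    pp <- generateProteomePair(100, 120, cfg$nHom, cfg$q, seed = cfg$seed)
    res <- wgrrMatrix(list(A = names(pp$proteomeA), B = names(pp$proteomeB)),
                      exactHitsFromTruth(pp$truth))
    expect_lt(abs(res$wgrr["A", "B"] - cfg$nHom * cfg$q / 100), 0.05)
    expect_equal(res$n_bbh["A", "B"], cfg$nHom)
  }
})

test_that("similarityNetwork uses a strict threshold", {
  w <- matrix(c(1, 0.5, 0.51, 0.5, 1, 0.2, 0.51, 0.2, 1), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  edges <- similarityNetwork(w, 0.5)
  expect_equal(nrow(edges), 1L)
  expect_identical(edges$prophage_a, "p1")
  expect_identical(edges$prophage_b, "p3")
  expect_equal(nrow(similarityNetwork(w[0, 0, drop = FALSE], 0.5)), 0L)
})
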
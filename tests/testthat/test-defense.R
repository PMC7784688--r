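plantSpacer <- function(seq, spacer, pos, strand = "+") {
  ins <- if (strand == "+") spacer else bruteRevComp(spacer)
  substr(seq, pos, pos + nchar(ins) - 1) <- ins
  seq
}

test_that("CRISPR arrays with fewer than three spacers are excluded", {
  tab <- data.frame(array_id = c("a1", "a1", "a2", "a2", "a2"),
                    strain_id = "s1",
                    spacer_seq = strrep("ACGT", 8),
                    stringsAsFactors = FALSE)
  kept <- filterCrisprArrays(tab)
  expect_identical(unique(kept$array_id), "a2")
  expect_equal(nrow(filterCrisprArrays(tab[0, ])), 0L)
})

test_that("spacer matching honours the identity and coverage thresholds", {
  set.seed(91)
  bg <- randomDnaStr(600)
  sp <- substr(randomDnaStr(100), 1, 32)

  exact <- plantSpacer(bg, sp, 200)
  m <- matchSpacer(sp, exact)
  hit <- m[m$position == 200, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$coverage, 1.0)
  expect_identical(hit$strand, "+")

  # 4 mismatches on a 32-mer: 28/32 = 0.875 < 0.9, interior positions so
  # truncation cannot rescue the window
  mut <- strsplit(sp, "")[[1]]
  for (p in c(8, 14, 20, 26))
    mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  fourMm <- plantSpacer(bg, paste(mut, collapse = ""), 200)
  expect_equal(nrow(matchSpacer(sp, fourMm)), 0L)

  # reverse-strand plant
  rev <- plantSpacer(bg, sp, 350, strand = "-")
  m <- matchSpacer(sp, rev)
  expect_true(any(m$position == 350 & m$strand == "-"))

  # subject shorter than the minimum window
  expect_equal(nrow(matchSpacer(sp, substr(bg, 1, 20))), 0L)
  expect_error(matchSpacer("ACGTACGT", bg), "shorter than 10")
})

test_that("a 30-nt spacer with 3 interior mismatches matches at identity 0.9", {
  set.seed(92)
  bg <- randomDnaStr(400)
  sp <- substr(randomDnaStr(50), 1, 30)
  mut <- strsplit(sp, "")[[1]]
  for (p in c(10, 17, 24))  # > 3 from both ends: present in every window
    mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  seq <- plantSpacer(bg, paste(mut, collapse = ""), 150)
  m <- matchSpacer(sp, seq)
  hit <- m[m$position == 150, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$identity, 0.9)
  expect_equal(hit$n_mismatches, 3L)
  expect_equal(hit$matched_length, 30L)
})

test_that("spacer matcher agrees with the exhaustive window oracle", {
  set.seed(93)
  for (i in 1:60) {
    n <- sample(60:120, 1)
    L <- sample(c(20, 25, 32), 1)
    bg <- randomDnaStr(n)
    sp <- substr(randomDnaStr(40), 1, L)
    mm <- sample(0:4, 1)
    if (runif(1) < 0.8) {
      mut <- strsplit(sp, "")[[1]]
      if (mm > 0) for (p in sample(seq_len(L), mm))
        mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
      bg <- plantSpacer(bg, paste(mut, collapse = ""),
                        sample(n - L + 1, 1),
                        strand = sample(c("+", "-"), 1))
    }
    got <- matchSpacer(sp, bg)
    cand <- bruteSpacerCandidates(sp, bg)
    expect_equal(nrow(got) > 0, nrow(cand) > 0, info = paste("case", i))
    if (nrow(got)) {
      # every report satisfies the thresholds and exists in the oracle set
      expect_true(all(got$identity >= 0.9))
      expect_true(all(got$coverage >= 0.9))
      key <- function(d) paste(d$position, d$strand, d$matched_length,
                               d$n_mismatches)
      expect_true(all(key(got) %in% key(cand)))
      # the single best oracle candidate is among the reports
      o <- cand[order(cand$n_mismatches, -cand$matched_length,
                      cand$position), ][1, ]
      expect_true(any(got$position == o$position & got$strand == o$strand &
                      got$matched_length == o$matched_length))
    }
  }
})

test_that("motif scanning handles palindromes, degenerate codes and strands", {
  # palindrome: a single forward report, no duplicate from the complement
  s <- findMotifSites("GAATTC", "AAGAATTCAA")
  expect_equal(s$position, 3L)
  expect_identical(s$strand, "+")
  # degenerate position
  s <- findMotifSites("GANTC", "TTGACTCTT")
  expect_equal(s$position, 3L)
  # non-palindrome planted on both strands
  seq <- paste0("TTT", "GACGC", "AAAA", bruteRevComp("GACGC"), "TTT")
  s <- findMotifSites("GACGC", seq)
  expect_equal(nrow(s), 2L)
  expect_setequal(s$strand, c("+", "-"))
  expect_error(findMotifSites("GAX", "ACGT"), "non-IUPAC|shorter")
  expect_error(findMotifSites("ACG", "ACGT"), "shorter than 4")
})

test_that("motif scanner equals the exhaustive window scan", {
  set.seed(94)
  motifs <- c("GAATTC", "GANTC", "GCCGGC", "CCWGG", "GRCGYC", "CANNNNTGG")
  for (i in 1:35) {
    m <- sample(motifs, 1)
    seq <- randomDnaStr(sample(200:800, 1), gc = runif(1, 0.3, 0.7))
    if (runif(1) < 0.7) {
      site <- paste(vapply(strsplit(m, "")[[1]], function(ch)
        sample(IUPAC_TABLE[[ch]], 1), character(1)), collapse = "")
      if (runif(1) < 0.5) site <- bruteRevComp(site)
      pos <- sample(nchar(seq) - nchar(site) + 1, 1)
      substr(seq, pos, pos + nchar(site) - 1) <- site
    }
    got <- findMotifSites(m, seq)
    want <- bruteMotifSites(m, seq)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste(m, "case", i))
  }
})

test_that("palindromic motif sites map onto the reverse-complemented sequence", {
  set.seed(95)
  m <- "GGCGCC"
  for (i in 1:10) {
    seq <- randomDnaStr(300, gc = 0.6)
    fwd <- findMotifSites(m, seq)
    rev <- findMotifSites(m, bruteRevComp(seq))
    mapped <- sort(nchar(seq) - rev$position - nchar(m) + 2)
    expect_equal(sort(fwd$position), mapped)
  }
})

test_that("R-M protein equivalence applies the per-type identity thresholds", {
  expect_equal(rmIdentityThreshold("REase", "II"), 0.50)
  expect_equal(rmIdentityThreshold("REase", "IV"), 0.50)
  expect_equal(rmIdentityThreshold("MTase", "IIG"), 0.55)
  expect_equal(rmIdentityThreshold("MTase", "II"), 0.60)
  expect_equal(rmIdentityThreshold("MTase", "I"), 0.80)
  expect_equal(rmIdentityThreshold("REase", "III"), 0.80)
  expect_error(rmIdentityThreshold("REase", "V"), "no equivalence threshold")
  expect_error(rmIdentityThreshold("other", "II"), "no equivalence threshold")

  set.seed(96)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  base <- paste(sample(aa, 200, TRUE), collapse = "")
  expect_true(rmProteinEquivalent(base, base, "REase", "II"))
  expect_true(rmProteinEquivalent(base, base, "MTase", "I"))

  # substitute an exact fraction of positions; gap penalties keep the global
  # alignment positionwise, so identity is (L - k)/L exactly
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), k)) ch[p] <- setdiff(aa, ch[p])[1]
    paste(ch, collapse = "")
  }
  at70 <- mutate(base, 60)   # identity 0.70
  expect_equal(proteinIdentity(base, at70), 0.70)
  expect_false(rmProteinEquivalent(base, at70, "MTase", "I"))  # needs 0.80
  expect_true(rmProteinEquivalent(base, at70, "MTase", "II"))  # needs 0.60
  at52 <- mutate(base, 96)   # identity 0.52
  expect_equal(proteinIdentity(base, at52), 0.52)
  expect_true(rmProteinEquivalent(base, at52, "REase", "II"))
  expect_false(rmProteinEquivalent(base, at52, "REase", "I"))
})

test_that("R-M targeting requires the system to be absent from the producer", {
  set.seed(97)
  genome <- randomDnaStr(2000)
  # ensure exactly one EcoRI-like site in the producer's prophage
  genome <- gsub("GAATTC", "GAATCC", genome)
  substr(genome, 1000, 1005) <- "GAATTC"
  seqs <- c(phA = genome, phB = randomDnaStr(2000))
  prophages <- data.frame(prophage_id = c("phA", "phB"),
                          strain_id = c("A", "B"),
                          completeness = "intact", stringsAsFactors = FALSE)
  mt <- paste(sample(c("A", "C", "D", "E"), 250, TRUE), collapse = "")
  re <- paste(sample(c("F", "G", "H", "I"), 250, TRUE), collapse = "")
  rmB <- data.frame(system_id = "sysB", strain_id = "B", rm_type = "II",
                    role = c("MTase", "REase"),
                    protein_fasta_id = c("pM", "pR"), motif = "GAATTC",
                    stringsAsFactors = FALSE)
  prots <- c(pM = mt, pR = re)

  calls <- rmTargeting(rmB, prots, prophages, seqs)
  ab <- calls[calls$producer == "A" & calls$target == "B", ]
  expect_true(ab$targeted)        # B's system, absent from A, one site
  expect_equal(ab$evidence, 1L)
  # two-site mode: a single site is no longer sufficient
  calls2 <- rmTargeting(rmB, prots, prophages, seqs, twoSiteMode = TRUE)
  expect_false(calls2[calls2$producer == "A" & calls2$target == "B", "targeted"])

  # A carries an equivalent system: excluded, not targeted
  rmBoth <- rbind(rmB, within(rmB, {
    system_id <- "sysA"; strain_id <- "A"
    protein_fasta_id <- c("pM2", "pR2")
  }))
  prots2 <- c(prots, pM2 = mt, pR2 = re)
  calls3 <- rmTargeting(rmBoth, prots2, prophages, seqs)
  expect_false(calls3[calls3$producer == "A" & calls3$target == "B", "targeted"])

  # systems without motifs are skipped with a message
  rmNoMotif <- rmB
  rmNoMotif$motif <- NA_character_
  expect_message(rmTargeting(rmNoMotif, prots, prophages, seqs),
                 "without recognition motif")
})

test_that("two-site positives are a subset of one-site positives", {
  for (seed in 1:4) {
    ds <- generateDefenseScenario(nStrains = 4, seed = seed)
    one <- rmTargeting(ds$rmTable, ds$proteinSeqs, ds$prophageTable,
                       ds$prophageSeqs, twoSiteMode = FALSE)
    two <- rmTargeting(ds$rmTable, ds$proteinSeqs, ds$prophageTable,
                       ds$prophageSeqs, twoSiteMode = TRUE)
    key <- function(d) paste(d$producer, d$target)
    expect_true(all(key(two[two$targeted, ]) %in% key(one[one$targeted, ])))
  }
})

test_that("CRISPR targeting needs a matching spacer above the thresholds", {
  set.seed(98)
  genome <- randomDnaStr(1500)
  seqs <- c(phA = genome)
  prophages <- data.frame(prophage_id = "phA", strain_id = "A",
                          completeness = "intact", stringsAsFactors = FALSE)
  proto <- substr(genome, 500, 531)
  pads <- replicate(2, randomDnaStr(32))
  spacers <- data.frame(array_id = "arrB", strain_id = "B",
                        spacer_seq = c(proto, pads), stringsAsFactors = FALSE)
  calls <- crisprTargeting(spacers, prophages, seqs, strains = c("A", "B"))
  expect_true(calls[calls$producer == "A" & calls$target == "B", "targeted"])
  expect_false(calls[calls$producer == "B" & calls$target == "A", "targeted"])

  # degrade the spacer to ~84% identity: below the 90% threshold
  ch <- strsplit(proto, "")[[1]]
  for (p in c(5, 10, 15, 20, 25)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  spacers$spacer_seq[1] <- paste(ch, collapse = "")
  calls <- crisprTargeting(spacers, prophages, seqs, strains = c("A", "B"))
  expect_false(calls[calls$producer == "A" & calls$target == "B", "targeted"])

  # no spacers at all
  calls <- crisprTargeting(spacers[0, ], prophages, seqs,
                           strains = c("A", "B"))
  expect_false(any(calls$targeted))
})

test_that("defense association cross-tabulates targeting against infection", {
  cts <- matrix(0L, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cts["A", "B"] <- 3L
  im <- InfectionMatrix(cts, 3)
  calls <- expand.grid(producer = c("A", "B", "C"), target = c("A", "B", "C"),
                       stringsAsFactors = FALSE)
  calls <- calls[calls$producer != calls$target, ]
  calls$mechanism <- "rm"
  calls$targeted <- calls$producer == "A" & calls$target == "B"
  res <- defenseAssociation(im, calls, prophageStrains = c("A", "B", "C"))
  expect_equal(contingencyTable(res),
               matrix(c(1L, 0L, 0L, 5L), 2, 2,
                      dimnames = dimnames(contingencyTable(res))))
  expect_error(
    defenseAssociation(im, within(calls, producer[1] <- "Z")),
    "absent from the infection matrix")
})
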
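# Independent brute-force oracles used to validate the package's
# implementations on small instances. These deliberately share no code with
# the implementations they check.

# hypergeometric two-sided p by explicit choose() enumeration
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  if (N == 0) return(NA_real_)
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  pObs <- prob(a)
  tot <- 0
  for (x in lo:hi) {
    px <- prob(x)
    if (px <= pObs * (1 + 1e-7)) tot <- tot + px
  }
  min(1, tot)
}

# LCS length by enumeration of all subsequences of the shorter string
bruteLcsLen <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
  n <- length(ca); best <- 0L
  isSubseq <- function(sel, ref) {
    j <- 1L
    for (ch in sel) {
      while (j <= length(ref) && ref[j] != ch) j <- j + 1L
      if (j > length(ref)) return(FALSE)
      j <- j + 1L
    }
    TRUE
  }
  for (mask in 0:(2^n - 1L)) {
    sel <- ca[bitwAnd(bitwShiftL(1L, 0:(n - 1L)), mask) != 0L]
    if (length(sel) > best && isSubseq(sel, cb)) best <- length(sel)
  }
  best
}

IUPAC_TABLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

bruteRevComp <- function(m) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(m, "")[[1]]]), collapse = "")
}

bruteMotifWindowMatch <- function(motif, window) {
  mc <- strsplit(motif, "")[[1]]; wc <- strsplit(window, "")[[1]]
  all(mapply(function(m, w) w %in% IUPAC_TABLE[[m]], mc, wc))
}

# exhaustive window scan for an IUPAC motif; palindromes forward-only
bruteMotifSites <- function(motif, seq) {
  m <- nchar(motif); n <- nchar(seq)
  res <- data.frame(position = integer(), strand = character(),
                    stringsAsFactors = FALSE)
  for (p in seq_len(max(0, n - m + 1))) {
    if (bruteMotifWindowMatch(motif, substr(seq, p, p + m - 1)))
      res <- rbind(res, data.frame(position = p, strand = "+"))
  }
  rc <- bruteRevComp(motif)
  if (rc != motif) {
    for (p in seq_len(max(0, n - m + 1))) {
      if (bruteMotifWindowMatch(rc, substr(seq, p, p + m - 1)))
        res <- rbind(res, data.frame(position = p, strand = "-"))
    }
  }
  res[order(res$position, res$strand), , drop = FALSE]
}

# all windows of all allowed sub-spacers meeting identity/coverage, uncollapsed
bruteSpacerCandidates <- function(spacer, seq, minId = 0.9, minCov = 0.9) {
  L <- nchar(spacer); n <- nchar(seq)
  minLen <- ceiling(minCov * L - 1e-9)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") spacer else bruteRevComp(spacer)
    for (Lp in minLen:min(L, n)) {
      for (s0 in 1:(nchar(q) - Lp + 1)) {
        sub <- substr(q, s0, s0 + Lp - 1)
        for (p in 1:(n - Lp + 1)) {
          win <- substr(seq, p, p + Lp - 1)
          mm <- sum(strsplit(sub, "")[[1]] != strsplit(win, "")[[1]])
          if ((Lp - mm) / Lp >= minId)
            out[[length(out) + 1]] <- data.frame(
              position = p, strand = strand, matched_length = Lp,
              n_mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else
    data.frame(position = integer(), strand = character(),
               matched_length = integer(), n_mismatches = integer())
}

# exhaustive best-hit / BBH search on a hits table
bruteBestHit <- function(hits, prophageOf, query, targetProphage) {
  cand <- hits[hits$query_id == query &
               prophageOf[hits$subject_id] == targetProphage, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  best <- cand[1, ]
  betterThan <- function(x, y) {
    if (x$bitscore != y$bitscore) return(x$bitscore > y$bitscore)
    if (x$evalue != y$evalue) return(x$evalue < y$evalue)
    if (x$pct_identity != y$pct_identity) return(x$pct_identity > y$pct_identity)
    x$subject_id < y$subject_id
  }
  for (i in seq_len(nrow(cand)))
    if (betterThan(cand[i, ], best)) best <- cand[i, ]
  best
}

bruteBbh <- function(hits, proteinsByProphage, A, B) {
  prophageOf <- setNames(rep(names(proteinsByProphage),
                             lengths(proteinsByProphage)),
                         unlist(proteinsByProphage))
  pairs <- list()
  for (x in proteinsByProphage[[A]]) {
    bx <- bruteBestHit(hits, prophageOf, x, B)
    if (is.null(bx)) next
    y <- bx$subject_id
    by <- bruteBestHit(hits, prophageOf, y, A)
    if (!is.null(by) && by$subject_id == x)
      pairs[[length(pairs) + 1]] <- data.frame(
        protein_a = x, protein_b = y,
        identity = (bx$pct_identity + by$pct_identity) / 2,
        stringsAsFactors = FALSE)
  }
  if (length(pairs)) do.call(rbind, pairs) else
    data.frame(protein_a = character(), protein_b = character(),
               identity = numeric(), stringsAsFactors = FALSE)
}

randomDnaStr <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random hits panel for BBH oracle tests; small integer bitscores force ties
randomHitsPanel <- function(nProteomes = 5, nProteins = 8, density = 0.15) {
  ids <- paste0("ph", seq_len(nProteomes))
  proteins <- lapply(ids, function(p) paste0(p, "_g", seq_len(nProteins)))
  names(proteins) <- ids
  all <- unlist(proteins)
  prophageOf <- setNames(rep(ids, each = nProteins), all)
  combos <- expand.grid(q = all, s = all, stringsAsFactors = FALSE)
  combos <- combos[prophageOf[combos$q] != prophageOf[combos$s], ]
  take <- runif(nrow(combos)) < density
  hits <- data.frame(
    query_id = combos$q[take], subject_id = combos$s[take],
    pct_identity = round(runif(sum(take), 35, 100), 1),
    length = sample(50:300, sum(take), replace = TRUE),
    evalue = 10^-sample(5:30, sum(take), replace = TRUE),
    bitscore = sample(c(50, 60, 70), sum(take), replace = TRUE),
    query_coverage = 1, subject_coverage = 1,
    stringsAsFactors = FALSE)
  list(proteins = proteins, hits = hits)
}
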
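#' @importFrom stats rbinom
NULL

# independent per-component substreams from one root seed, so adding a
# generator never perturbs another's output
.STREAM_OFFSETS <- c(proteome = 1L, hits = 2L, panel = 3L, defense = 4L,
                     trajectory = 5L, pipeline = 6L)

.substreamSeed <- function(seed, stream) {
  off <- .STREAM_OFFSETS[[stream]]
  as.integer((as.numeric(seed) + off * 1000003) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

.randomProtein <- function(n) {
  vapply(n, function(L)
    paste(sample(AA_LETTERS, L, replace = TRUE), collapse = ""),
    character(1L))
}

.randomDna <- function(L, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
}

#' Generate a proteome pair with planted homologs
#'
#' Background proteins are i.i.d. uniform over the 20 residues. Each of the
#' `nHom` planted homolog pairs is a copy of an A protein with exactly
#' `round((1 - identityTarget) * L)` positions substituted to a different
#' residue, so the realized identity is `1 - k/L` (equal to the target up to
#' the rounding to whole substitutions).
#'
#' @param nA,nB proteome sizes.
#' @param nHom number of planted homolog pairs (`<= min(nA, nB)`).
#' @param identityTarget target amino-acid identity in `(0, 1]`.
#' @param lengthRange inclusive range of protein lengths (default 100-300).
#' @param seed root seed.
#' @return list with `proteomeA`, `proteomeB`
#'   ([Biostrings::AAStringSet]s named `A_p<i>` / `B_p<i>`) and `truth`, a
#'   data.frame `protein_a, protein_b, identity` (fraction), `length`.
#' @export
generateProteomePair <- function(nA, nB, nHom, identityTarget,
                                 lengthRange = c(100L, 300L), seed = 1L) {
  if (nHom > min(nA, nB))
    stop("nHom exceeds the smaller proteome size")
  if (identityTarget <= 0 || identityTarget > 1)
    stop("identityTarget must be in (0, 1]")
  .withSeed(.substreamSeed(seed, "proteome"), {
    lenA <- sample(lengthRange[1L]:lengthRange[2L], nA, replace = TRUE)
    lenB <- sample(lengthRange[1L]:lengthRange[2L], nB, replace = TRUE)
    pa <- .randomProtein(lenA)
    pb <- .randomProtein(lenB)
    truth <- data.frame(protein_a = character(), protein_b = character(),
                        identity = numeric(), length = integer(),
                        stringsAsFactors = FALSE)
    for (i in seq_len(nHom)) {
      L <- lenA[i]
      chars <- strsplit(pa[i], "")[[1L]]
      k <- round((1 - identityTarget) * L)
      if (k > 0L) {
        pos <- sample(L, k)
        for (p in pos)
          chars[p] <- sample(setdiff(AA_LETTERS, chars[p]), 1L)
      }
      pb[i] <- paste(chars, collapse = "")
      truth <- rbind(truth, data.frame(
        protein_a = paste0("A_p", i), protein_b = paste0("B_p", i),
        identity = 1 - k / L, length = L, stringsAsFactors = FALSE))
    }
    list(proteomeA = AAStringSet(setNames(pa, paste0("A_p", seq_len(nA)))),
         proteomeB = AAStringSet(setNames(pb, paste0("B_p", seq_len(nB)))),
         truth = truth)
  })
}

#' Lossless hits table from a planted-homolog truth table
#'
#' Emits one hit per planted pair per direction with the realized identity,
#' full coverage, a uniform tiny e-value and a bitscore proportional to
#' identity times length — bypassing external aligners so downstream BBH/wGRR
#' computations can be checked against planted truth exactly.
#'
#' @param truth truth data.frame from [generateProteomePair()].
#' @return hits data.frame in the [readHitsTable()] schema.
#' @export
exactHitsFromTruth <- function(truth) {
  n <- nrow(truth)
  if (n == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), length = numeric(),
                      evalue = numeric(), bitscore = numeric(),
                      query_coverage = numeric(), subject_coverage = numeric(),
                      stringsAsFactors = FALSE))
  one <- data.frame(query_id = truth$protein_a, subject_id = truth$protein_b,
                    pct_identity = 100 * truth$identity,
                    length = truth$length, evalue = 1e-50,
                    bitscore = 2 * truth$identity * truth$length,
                    query_coverage = 1, subject_coverage = 1,
                    stringsAsFactors = FALSE)
  other <- one
  other$query_id <- one$subject_id
  other$subject_id <- one$query_id
  rbind(one, other)
}

.DEFAULT_CLT_SIZES <- c(6L, 5L, 3L, 3L, 2L, 2L, 2L, 2L, rep(1L, 10L))

#' Generate a synthetic all-against-all infection panel
#'
#' Emulates the serotype-modular infection regime: for each ordered
#' (producer, target) pair and each replicate, infection is Bernoulli with
#' probability `pSame` when the two strains share a capsule locus type and
#' `pDiff` otherwise, independently across replicates. The default CLT group
#' sizes (6, 5, 3, 3, four pairs, ten singletons over 35 strains) give 105
#' ordered same-CLT combinations (self-pairs included) out of 1225, the
#' regime of the study panel; the default probabilities mirror its same-CLT
#' (33%) and cross-CLT (3.6%) infection frequencies.
#'
#' @param nStrains panel size (default 35).
#' @param cltSizes integer CLT group sizes summing to `nStrains`; ignored
#'   when `cltAssignment` is given.
#' @param cltAssignment optional named vector mapping strain id to CLT.
#' @param pSame,pDiff per-replicate infection probabilities (defaults 0.33
#'   and 0.036).
#' @param nReplicates replicates (default 3).
#' @param lpsSizes optional LPS O-locus group sizes (default: 4 groups of
#'   roughly equal size, assigned independently of CLT).
#' @param seed root seed.
#' @return list with `matrix` (an [InfectionMatrix-class]) and `metadata`
#'   (data.frame `strain_id, clt, lps`).
#' @export
generateInfectionPanel <- function(nStrains = 35L,
                                   cltSizes = NULL,
                                   cltAssignment = NULL,
                                   pSame = 0.33, pDiff = 0.036,
                                   nReplicates = 3L, lpsSizes = NULL,
                                   seed = 1L) {
  if (any(c(pSame, pDiff) < 0) || any(c(pSame, pDiff) > 1))
    stop("infection probabilities must lie in [0, 1]")
  if (is.null(cltAssignment)) {
    if (is.null(cltSizes)) {
      cltSizes <- if (nStrains == 35L) .DEFAULT_CLT_SIZES
                  else c(rep(2L, nStrains %/% 3L),
                         rep(1L, nStrains - 2L * (nStrains %/% 3L)))
    }
    if (sum(cltSizes) != nStrains)
      stop("cltSizes must sum to nStrains")
    strains <- sprintf("s%02d", seq_len(nStrains))
    clt <- setNames(rep(sprintf("KL%02d", seq_along(cltSizes)), cltSizes),
                    strains)
  } else {
    strains <- names(cltAssignment)
    clt <- cltAssignment
    nStrains <- length(strains)
  }
  .withSeed(.substreamSeed(seed, "panel"), {
    if (is.null(lpsSizes)) {
      nl <- max(1L, min(4L, nStrains))
      lps <- setNames(sprintf("O%d", sample(nl, nStrains, replace = TRUE)),
                      strains)
    } else {
      if (sum(lpsSizes) != nStrains) stop("lpsSizes must sum to nStrains")
      lps <- setNames(sample(rep(sprintf("O%d", seq_along(lpsSizes)),
                                 lpsSizes)), strains)
    }
    same <- outer(clt[strains], clt[strains], "==")
    p <- ifelse(same, pSame, pDiff)
    cts <- matrix(rbinom(nStrains * nStrains, nReplicates, p),
                  nStrains, nStrains, dimnames = list(strains, strains))
    list(matrix = InfectionMatrix(cts, nReplicates),
         metadata = data.frame(strain_id = strains, clt = unname(clt[strains]),
                               lps = unname(lps[strains]),
                               stringsAsFactors = FALSE))
  })
}

.concretizeMotif <- function(motif) {
  chars <- strsplit(motif, "")[[1L]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_EXPANSION[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L)), collapse = "")
}

#' Generate a defense-targeting scenario with planted motifs and spacers
#'
#' Builds one intact prophage genome per strain (random background of the
#' requested GC content), assigns type II R-M systems carrying the supplied
#' recognition motifs round-robin to strains, plants one concretized
#' occurrence of each motif (random strand) in a prophage of a different
#' strain, and plants protospacers: for each requested mismatch count, a
#' window of a prophage is copied into a CRISPR spacer of another strain
#' with that many substitutions (arrays are padded with random spacers to
#' three). The truth record lists every planted site and spacer, and
#' (post-scan) all chance background motif occurrences.
#'
#' @param nStrains number of strains (>= 2).
#' @param motifSet IUPAC recognition motifs to assign and plant.
#' @param mismatchCounts integer vector: one planted protospacer per entry,
#'   carrying that many substitutions.
#' @param spacerLength planted spacer length (default 32).
#' @param genomeLength prophage genome length (default 5000).
#' @param gc background GC content (default 0.5).
#' @param seed root seed.
#' @return list with `prophageSeqs` (named [Biostrings::DNAStringSet]),
#'   `prophageTable`, `rmTable`, `proteinSeqs`, `crisprTable`, and `truth`
#'   (lists `motif_sites` and `spacers`).
#' @export
generateDefenseScenario <- function(nStrains = 4L,
                                    motifSet = c("GAATTC", "GANTC", "GCCGGC"),
                                    mismatchCounts = c(0L, 1L, 3L),
                                    spacerLength = 32L,
                                    genomeLength = 5000L, gc = 0.5,
                                    seed = 1L) {
  if (nStrains < 2L) stop("need at least 2 strains")
  if (any(nchar(motifSet) > genomeLength))
    stop("motif longer than the genome")
  motifSet <- unname(vapply(motifSet, .checkIupac, character(1L)))
  .withSeed(.substreamSeed(seed, "defense"), {
    strains <- sprintf("s%02d", seq_len(nStrains))
    phIds <- paste0(strains, "_ph1")
    genomes <- setNames(vapply(seq_len(nStrains),
                               function(i) .randomDna(genomeLength, gc),
                               character(1L)), phIds)
    prophageTable <- data.frame(prophage_id = phIds, strain_id = strains,
                                start = 1L, end = genomeLength,
                                completeness = "intact",
                                stringsAsFactors = FALSE)
    # R-M systems: motif k belongs to strain (k mod n); planted in the next
    # strain's prophage so targeting pairs exist by construction
    rmRows <- list(); protSeqs <- character(); siteRows <- list()
    for (k in seq_along(motifSet)) {
      owner <- ((k - 1L) %% nStrains) + 1L
      victim <- (owner %% nStrains) + 1L
      sysId <- sprintf("RM%02d", k)
      mt <- .randomProtein(300L); re <- .randomProtein(300L)
      protSeqs[paste0(sysId, "_M")] <- mt
      protSeqs[paste0(sysId, "_R")] <- re
      rmRows[[length(rmRows) + 1L]] <- data.frame(
        system_id = sysId, strain_id = strains[owner], rm_type = "II",
        role = c("MTase", "REase"),
        protein_fasta_id = paste0(sysId, c("_M", "_R")),
        motif = motifSet[k], stringsAsFactors = FALSE)
      site <- .concretizeMotif(motifSet[k])
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") site else revCompIupac(site)
      pos <- sample(genomeLength - nchar(site) + 1L, 1L)
      g <- genomes[[phIds[victim]]]
      substr(g, pos, pos + nchar(site) - 1L) <- ins
      genomes[[phIds[victim]]] <- g
      siteRows[[length(siteRows) + 1L]] <- data.frame(
        motif = motifSet[k], prophage_id = phIds[victim], position = pos,
        strand = strand, planted = TRUE, stringsAsFactors = FALSE)
    }
    # protospacers: window of the producer's prophage stored (mutated) in
    # another strain's array
    spacerRows <- list(); truthSpacers <- list()
    for (k in seq_along(mismatchCounts)) {
      src <- ((k - 1L) %% nStrains) + 1L
      holder <- (src %% nStrains) + 1L
      pos <- sample(genomeLength - spacerLength + 1L, 1L)
      proto <- substr(genomes[[phIds[src]]], pos, pos + spacerLength - 1L)
      chars <- strsplit(proto, "")[[1L]]
      mm <- mismatchCounts[k]
      if (mm > 0L) {
        # substitutions go in the window core so every coverage-allowed
        # truncation retains them and the planted mismatch count is exact
        edge <- floor(0.1 * spacerLength)
        core <- (edge + 1L):(spacerLength - edge)
        for (p in sample(core, mm))
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
      }
      spacer <- paste(chars, collapse = "")
      arrId <- sprintf("CR%02d", holder)
      pads <- vapply(1:2, function(j) .randomDna(spacerLength), character(1L))
      spacerRows[[length(spacerRows) + 1L]] <- data.frame(
        array_id = arrId, strain_id = strains[holder],
        spacer_seq = c(spacer, pads), stringsAsFactors = FALSE)
      truthSpacers[[length(truthSpacers) + 1L]] <- data.frame(
        spacer_seq = spacer, source_prophage = phIds[src], position = pos,
        n_mismatches = mm, holder_strain = strains[holder],
        stringsAsFactors = FALSE)
    }
    rmTable <- do.call(rbind, rmRows)
    crisprTable <- do.call(rbind, spacerRows)
    planted <- do.call(rbind, siteRows)
    # post-scan: chance background occurrences belong in the truth as well
    allSites <- do.call(rbind, lapply(unique(planted$motif), function(m) {
      do.call(rbind, lapply(phIds, function(ph) {
        hits <- findMotifSites(m, genomes[[ph]])
        if (nrow(hits) == 0L) return(NULL)
        data.frame(motif = m, prophage_id = ph, position = hits$position,
                   strand = hits$strand, stringsAsFactors = FALSE)
      }))
    }))
    allSites$planted <- mapply(function(m, ph, pos) {
      any(planted$motif == m & planted$prophage_id == ph &
          planted$position == pos)
    }, allSites$motif, allSites$prophage_id, allSites$position)
    list(prophageSeqs = DNAStringSet(genomes),
         prophageTable = prophageTable,
         rmTable = rmTable,
         proteinSeqs = AAStringSet(protSeqs),
         crisprTable = crisprTable,
         truth = list(motif_sites = allSites,
                      spacers = do.call(rbind, truthSpacers)))
  })
}

.TREATMENT_S <- c(LB = 0.10, LB_citrate = 0.02, MMC = 0.30,
                  MMC_citrate = 0.05)

#' Simulate capsule-loss trajectories
#'
#' Selection-against-capsule with unidirectional loss mutation: per
#' generation the capsulated frequency updates as
#' `f' = f(1-mu) / (f(1-mu) + (1 - f(1-mu)) (1+s))`, and the daily
#' observation is the fraction of `samplingN` sampled clones that are
#' capsulated (binomial sampling noise). The process is a fixture emulating
#' phage predation selecting non-capsulated escape mutants, not a
#' mechanistic model.
#'
#' @param s selection coefficient favouring non-capsulated cells (>= 0).
#' @param mu capsule-loss mutation rate per generation (default `1e-3`).
#' @param generationsPerDay generations per daily passage (default 7, the
#'   1:100 dilution regime).
#' @param days experiment length in days (default 10).
#' @param nPopulations independent populations (default 6).
#' @param samplingN clones phenotyped per day (default 100).
#' @param strainId,treatment labels for the output table.
#' @param seed root seed.
#' @return data.frame `population_id, strain_id, treatment, day,
#'   capsulated_fraction` with days 0..days.
#' @export
generateTrajectories <- function(s, mu = 1e-3, generationsPerDay = 7L,
                                 days = 10L, nPopulations = 6L,
                                 samplingN = 100L, strainId = "sim",
                                 treatment = "LB", seed = 1L) {
  if (s < 0 || mu < 0 || mu > 1) stop("invalid rate")
  .withSeed(.substreamSeed(seed, "trajectory"), {
    out <- list()
    for (pop in seq_len(nPopulations)) {
      f <- 1
      obs <- rbinom(1L, samplingN, f) / samplingN
      rows <- data.frame(day = 0L, capsulated_fraction = obs)
      for (d in seq_len(days)) {
        for (g in seq_len(generationsPerDay)) {
          fm <- f * (1 - mu)
          f <- fm / (fm + (1 - fm) * (1 + s))
        }
        rows <- rbind(rows, data.frame(
          day = d, capsulated_fraction = rbinom(1L, samplingN, f) / samplingN))
      }
      out[[pop]] <- data.frame(
        population_id = sprintf("%s_%s_pop%d", strainId, treatment, pop),
        strain_id = strainId, treatment = treatment,
        day = rows$day, capsulated_fraction = rows$capsulated_fraction,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Simulate a four-treatment evolution experiment
#'
#' Runs [generateTrajectories()] for the four environments of the evolution
#' design (plain LB, LB + citrate blocking phage adsorption, MMC induction,
#' MMC + citrate), with default selection coefficients ordered as phage
#' predation intensity implies: MMC > LB > MMC_citrate > LB_citrate.
#'
#' @param sByTreatment named vector of selection coefficients per treatment.
#' @param strainId strain label.
#' @param seed root seed (one offset per treatment keeps them independent).
#' @param ... further arguments to [generateTrajectories()].
#' @return combined trajectory data.frame.
#' @export
generateEvolutionExperiment <- function(sByTreatment = .TREATMENT_S,
                                        strainId = "sim", seed = 1L, ...) {
  do.call(rbind, lapply(seq_along(sByTreatment), function(i) {
    generateTrajectories(s = sByTreatment[[i]], strainId = strainId,
                         treatment = names(sByTreatment)[i],
                         seed = seed + 101L * i, ...)
  }))
}
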
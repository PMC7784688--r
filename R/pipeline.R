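#' @importFrom yaml read_yaml
#' @importFrom jsonlite write_json
NULL

.CONFIG_DEFAULTS <- list(
  seed = 1L,
  outdir = ".",
  wgrr_network_threshold = 0.5,
  max_evalue = 1e-4,
  min_identity_pct = 35,
  min_coverage = 0.5,
  coverage_mode = "both",
  spacer_min_identity = 0.9,
  spacer_min_coverage = 0.9,
  two_site_mode = FALSE,
  include_self = TRUE,
  auc_window = 5,
  n_replicates = 3L,
  inputs = list())

.INPUT_KEYS <- c("proteomes", "hits", "prophage_table", "prophage_fasta",
                 "rm_table", "rm_proteins", "crispr_table",
                 "infection_matrix", "strain_metadata", "trajectories")

#' Default pipeline configuration
#'
#' All thresholds default to the study's stated values: wGRR network edges
#' above 0.5, hit filters (e-value < 1e-4, identity >= 35%, coverage >= 50%
#' both sides), spacer matching at 90% identity and coverage, one-site R-M
#' targeting, self-pairs counted in serotype contingency tables, a 5-day
#' AUC window and 3 replicates.
#'
#' @return named list of configuration values.
#' @export
defaultPipelineConfig <- function() .CONFIG_DEFAULTS

#' Read and validate a YAML pipeline configuration
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [defaultPipelineConfig()]. Thresholds are range-checked.
#'
#' @param path path to a YAML file.
#' @return merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(user$inputs)) {
    badIn <- setdiff(names(user$inputs), .INPUT_KEYS)
    if (length(badIn))
      stop("unknown input key(s): ", paste(badIn, collapse = ", "))
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, user)
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param config configuration list to validate.
#' @export
validatePipelineConfig <- function(config) {
  inRange <- function(key, lo, hi) {
    v <- config[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < lo || v > hi)
      stop(sprintf("config '%s' must be a number in [%g, %g]", key, lo, hi))
  }
  inRange("wgrr_network_threshold", 0, 1)
  inRange("min_coverage", 0, 1)
  inRange("min_identity_pct", 0, 100)
  inRange("spacer_min_identity", 0, 1)
  inRange("spacer_min_coverage", 0, 1)
  inRange("auc_window", 1, 1000)
  if (!config$coverage_mode %in% c("both", "query"))
    stop("config 'coverage_mode' must be 'both' or 'query'")
  if (!is.logical(config$two_site_mode) || !is.logical(config$include_self))
    stop("two_site_mode and include_self must be logical")
  invisible(config)
}

.readProteomes <- function(spec) {
  paths <- if (length(spec) == 1L && dir.exists(spec[[1L]])) {
    files <- list.files(spec[[1L]], pattern = "\\.(faa|fasta|fa)$",
                        full.names = TRUE)
    setNames(files, sub("\\.[^.]*$", "", basename(files)))
  } else unlist(spec)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("proteome inputs must be named by prophage identifier")
  lapply(paths, function(p) names(readFasta(p, "protein")))
}

#' Run the wGRR stage of the pipeline
#'
#' Reads per-prophage proteome FASTAs and a homology hits table, computes
#' the all-against-all wGRR matrix and the threshold similarity network,
#' and writes `wgrr.tsv` (long format: prophage_a, prophage_b, n_bbh, wgrr)
#' and `edges.tsv` to the output directory.
#'
#' @param config configuration list (see [readPipelineConfig()]); needs
#'   `inputs$proteomes` (named FASTA paths or a directory) and
#'   `inputs$hits`.
#' @return list with `wgrr`, `n_bbh`, `edges` and the output paths,
#'   invisibly.
#' @export
runWgrr <- function(config) {
  proteomes <- .readProteomes(config$inputs$proteomes)
  hits <- readHitsTable(config$inputs$hits)
  res <- wgrrMatrix(proteomes, hits, maxEvalue = config$max_evalue,
                    minIdentityPct = config$min_identity_pct,
                    minCoverage = config$min_coverage,
                    coverageMode = config$coverage_mode)
  edges <- similarityNetwork(res$wgrr, config$wgrr_network_threshold)
  ids <- rownames(res$wgrr)
  ut <- which(upper.tri(res$wgrr), arr.ind = TRUE)
  long <- data.frame(prophage_a = ids[ut[, 1L]], prophage_b = ids[ut[, 2L]],
                     n_bbh = res$n_bbh[ut], wgrr = res$wgrr[ut])
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  wgrrPath <- file.path(config$outdir, "wgrr.tsv")
  edgePath <- file.path(config$outdir, "edges.tsv")
  write.table(long, wgrrPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(edges, edgePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(wgrr = res$wgrr, n_bbh = res$n_bbh, edges = edges,
                 files = c(wgrr = wgrrPath, edges = edgePath)))
}

#' Run the defense-targeting stage of the pipeline
#'
#' Computes R-M and CRISPR targeting calls across the panel and, when an
#' infection matrix is supplied, the per-mechanism association with
#' infection outcomes. Writes `targeting.tsv` and `defense_association.json`.
#'
#' @param config configuration list; needs `inputs$rm_table`,
#'   `inputs$rm_proteins`, `inputs$crispr_table`, `inputs$prophage_table`,
#'   `inputs$prophage_fasta` and optionally `inputs$infection_matrix`.
#' @return list with `calls` and per-mechanism [ContingencyResult-class]s,
#'   invisibly.
#' @export
runDefense <- function(config) {
  rmTable <- readRmTable(config$inputs$rm_table)
  rmProteins <- readFasta(config$inputs$rm_proteins, "protein")
  crisprTable <- readCrisprTable(config$inputs$crispr_table)
  prophageTable <- readProphageTable(config$inputs$prophage_table)
  prophageSeqs <- readFasta(config$inputs$prophage_fasta, "dna")
  strains <- sort(unique(c(prophageTable$strain_id, rmTable$strain_id,
                           crisprTable$strain_id)))
  rmCalls <- rmTargeting(rmTable, rmProteins, prophageTable, prophageSeqs,
                         strains = strains,
                         twoSiteMode = config$two_site_mode)
  crCalls <- crisprTargeting(crisprTable, prophageTable, prophageSeqs,
                             strains = strains,
                             minIdentity = config$spacer_min_identity,
                             minCoverage = config$spacer_min_coverage)
  calls <- rbind(rmCalls, crCalls)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(calls, file.path(config$outdir, "targeting.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  out <- list(calls = calls)
  if (!is.null(config$inputs$infection_matrix)) {
    im <- readInfectionMatrix(config$inputs$infection_matrix,
                              config$n_replicates)
    phStrains <- unique(prophageTable$strain_id[
      prophageTable$completeness == "intact"])
    assoc <- list(
      rm = defenseAssociation(im, rmCalls, phStrains),
      crispr = defenseAssociation(im, crCalls, phStrains))
    js <- lapply(assoc, function(a) list(
      table = contingencyTable(a), odds_ratio = oddsRatio(a),
      p_two_sided = pValue(a)))
    write_json(js, file.path(config$outdir, "defense_association.json"),
               auto_unbox = TRUE, digits = NA, force = TRUE)
    out$association <- assoc
  }
  invisible(out)
}

#' Run the infection-matrix statistics stage of the pipeline
#'
#' Computes per-producer infection scores, replicate reproducibility, and
#' the CLT and LPS serotype contingency tests; writes `netstats.json` and
#' `infection_scores.tsv`.
#'
#' @param config configuration list; needs `inputs$infection_matrix` and
#'   `inputs$strain_metadata` (TSV with strain_id, clt, lps).
#' @return list of results, invisibly.
#' @export
runNetstats <- function(config) {
  im <- readInfectionMatrix(config$inputs$infection_matrix,
                            config$n_replicates)
  meta <- read.delim(config$inputs$strain_metadata, stringsAsFactors = FALSE)
  if (!all(c("strain_id", "clt") %in% names(meta)))
    stop("strain metadata must provide strain_id and clt columns")
  clt <- setNames(meta$clt, meta$strain_id)
  scores <- data.frame(
    strain_id = producers(im),
    infection_score = vapply(producers(im), function(s) infectionScore(im, s),
                             numeric(1L)))
  repro <- replicateReproducibility(im, clt)
  cltRes <- cltModularityTest(im, clt, includeSelf = config$include_self)
  out <- list(infection_scores = scores, reproducibility = repro,
              clt = cltRes)
  if ("lps" %in% names(meta)) {
    out$lps <- lpsContingency(im, setNames(meta$lps, meta$strain_id),
                              includeSelf = config$include_self)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(scores, file.path(config$outdir, "infection_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  asJson <- function(a) list(table = contingencyTable(a),
                             odds_ratio = oddsRatio(a),
                             p_two_sided = pValue(a))
  js <- list(n_infected = repro$nInfected,
             reproducibility = repro[c("overall", "sameClt", "crossClt")],
             clt = asJson(cltRes))
  if (!is.null(out$lps)) js$lps <- asJson(out$lps)
  write_json(js, file.path(config$outdir, "netstats.json"),
             auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out)
}

#' Run the capsule-loss stage of the pipeline
#'
#' Computes per-population AUCs over the configured window, group summaries,
#' and pairwise treatment comparisons within each strain; writes `auc.tsv`
#' and `treatment_comparisons.json`.
#'
#' @param config configuration list; needs `inputs$trajectories`.
#' @return list with `auc`, `summary`, `comparisons`, invisibly.
#' @export
runEvolve <- function(config) {
  traj <- readTrajectories(config$inputs$trajectories)
  aucs <- capsuleAucTable(traj, window = config$auc_window)
  summ <- lossRateSummary(aucs)
  comps <- list()
  for (strain in unique(aucs$strain_id)) {
    su <- aucs[aucs$strain_id == strain, , drop = FALSE]
    trts <- unique(su$treatment)
    if (length(trts) < 2L) next
    for (i in seq_len(length(trts) - 1L)) for (j in seq((i + 1L), length(trts))) {
      a <- su$auc[su$treatment == trts[i]]
      b <- su$auc[su$treatment == trts[j]]
      if (length(a) < 3L || length(b) < 3L) next
      cmp <- compareTreatmentAucs(a, b)
      comps[[paste(strain, trts[i], trts[j], sep = ":")]] <- list(
        strain = strain, treatment_a = trts[i], treatment_b = trts[j],
        U = cmp$statistic, p_two_sided = cmp$p)
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write.table(aucs, file.path(config$outdir, "auc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_json(unname(comps),
             file.path(config$outdir, "treatment_comparisons.json"),
             auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(auc = aucs, summary = summ, comparisons = comps))
}

#' Generate a complete synthetic input set on disk
#'
#' One command produces a panel exercising every other pipeline stage:
#' per-prophage proteome FASTAs with a lossless hits table, an infection
#' matrix with strain metadata, a defense scenario (prophage genomes, R-M
#' and CRISPR tables) and a four-treatment trajectory table, each with its
#' truth record serialized alongside as JSON. Identical seed and
#' configuration reproduce identical files.
#'
#' @param config configuration list; `outdir` and `seed` are used.
#' @param nStrains panel size for the infection matrix (default 35).
#' @return named vector of written file paths, invisibly.
#' @export
runSimulate <- function(config, nStrains = 35L) {
  outdir <- config$outdir
  seed <- config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  # wGRR fixture
  pp <- generateProteomePair(100L, 120L, nHom = 10L, identityTarget = 0.8,
                             seed = seed)
  protDir <- file.path(outdir, "proteomes")
  dir.create(protDir, showWarnings = FALSE)
  writeFasta(pp$proteomeA, file.path(protDir, "phageA.faa"))
  writeFasta(pp$proteomeB, file.path(protDir, "phageB.faa"))
  paths["proteomes"] <- protDir
  paths["hits"] <- file.path(outdir, "hits.tsv")
  writeHitsTable(exactHitsFromTruth(pp$truth), paths[["hits"]])
  write_json(pp$truth, file.path(outdir, "truth_proteomes.json"),
             auto_unbox = TRUE, digits = NA)
  # infection panel
  panel <- generateInfectionPanel(nStrains = nStrains, seed = seed)
  paths["infection_matrix"] <- file.path(outdir, "infection_matrix.csv")
  writeInfectionMatrix(panel$matrix, paths[["infection_matrix"]])
  paths["strain_metadata"] <- file.path(outdir, "strain_metadata.tsv")
  write.table(panel$metadata, paths[["strain_metadata"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  # defense scenario
  ds <- generateDefenseScenario(seed = seed)
  paths["prophage_fasta"] <- file.path(outdir, "prophages.fasta")
  writeFasta(ds$prophageSeqs, paths[["prophage_fasta"]])
  paths["prophage_table"] <- file.path(outdir, "prophage_table.tsv")
  write.table(ds$prophageTable, paths[["prophage_table"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths["rm_table"] <- file.path(outdir, "rm_systems.tsv")
  write.table(ds$rmTable, paths[["rm_table"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["rm_proteins"] <- file.path(outdir, "rm_proteins.faa")
  writeFasta(ds$proteinSeqs, paths[["rm_proteins"]])
  paths["crispr_table"] <- file.path(outdir, "crispr_spacers.tsv")
  write.table(ds$crisprTable, paths[["crispr_table"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_json(ds$truth, file.path(outdir, "truth_defense.json"),
             auto_unbox = TRUE, digits = NA)
  # trajectories
  traj <- generateEvolutionExperiment(strainId = "simA", seed = seed,
                                      nPopulations = 6L)
  paths["trajectories"] <- file.path(outdir, "trajectories.csv")
  write.csv(traj, paths[["trajectories"]], quote = FALSE, row.names = FALSE)
  invisible(paths)
}
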
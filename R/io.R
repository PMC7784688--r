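#' @importFrom utils read.delim read.csv write.csv write.table
NULL

#' Read a FASTA file with alphabet validation
#'
#' Identifiers are the first whitespace-delimited token of each header and
#' must be unique within the file; sequences are uppercased on read. DNA
#' records may use `A,C,G,T,N`; protein records the 20 standard residues
#' plus `X`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet], in
#'   file order, named by identifier.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "acgt"), f)
#' readFasta(f, "dna")
#' @export
readFasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBStringSet(path)
  if (length(raw) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "[ \t]+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicated FASTA identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  allowed <- if (alphabet == "dna") c("A", "C", "G", "T", "N")
             else c(AA_LETTERS, "X")
  for (i in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[i]], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      stop(sprintf("record '%s' contains illegal %s character(s): %s",
                   ids[i], alphabet, paste(bad, collapse = ", ")))
  }
  names(seqs) <- ids
  if (alphabet == "dna") DNAStringSet(seqs) else AAStringSet(seqs)
}

#' Write sequences to FASTA
#'
#' @param x a named XStringSet or named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- BStringSet(x)
  if (is.null(names(x))) stop("sequences must be named")
  writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a BLAST-tabular homology hits table
#'
#' Expects tab-separated columns `qseqid, sseqid, pident, length, evalue,
#' bitscore, qcovs, scovs` (a header line is recognised and skipped).
#' Coverage columns may be fractions in `[0,1]` or percentages; percentages
#' are detected by any value exceeding 1 and rescaled. Self-hits
#' (query == subject) are dropped.
#'
#' @param path path to the TSV.
#' @return data.frame with columns `query_id, subject_id, pct_identity,
#'   length, evalue, bitscore, query_coverage, subject_coverage`.
#' @export
readHitsTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hasHeader <- length(lines) > 0L && grepl("^qseqid\\b", lines[[1L]])
  dataLines <- if (hasHeader) lines[-1L] else lines
  offset <- if (hasHeader) 1L else 0L
  cols <- c("query_id", "subject_id", "pct_identity", "length",
            "evalue", "bitscore", "query_coverage", "subject_coverage")
  if (length(dataLines) == 0L) {
    out <- as.data.frame(setNames(
      c(list(character(), character()), replicate(6, numeric(), FALSE)), cols))
    return(out)
  }
  parts <- strsplit(dataLines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 8L))
    stop(sprintf("malformed hits row at line %d: expected 8 fields, got %d",
                 which(nf != 8L)[1L] + offset, nf[nf != 8L][1L]))
  m <- matrix(unlist(parts), ncol = 8L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:8, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 6L)
  badRow <- which(apply(num, 1L, function(r) any(is.na(r))))
  if (length(badRow))
    stop(sprintf("malformed numeric field at line %d", badRow[1L] + offset))
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     pct_identity = num[, 1L], length = num[, 2L],
                     evalue = num[, 3L], bitscore = num[, 4L],
                     query_coverage = num[, 5L], subject_coverage = num[, 6L],
                     stringsAsFactors = FALSE)
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100))
    stop("pct_identity out of [0, 100]")
  if (any(hits$evalue < 0) || any(hits$bitscore < 0))
    stop("negative evalue or bitscore")
  # coverage dialect auto-detection: any value > 1 means percentages
  covs <- c(hits$query_coverage, hits$subject_coverage)
  if (length(covs) && max(covs) > 1) {
    hits$query_coverage <- hits$query_coverage / 100
    hits$subject_coverage <- hits$subject_coverage / 100
  }
  if (any(hits$query_coverage < 0 | hits$query_coverage > 1) ||
      any(hits$subject_coverage < 0 | hits$subject_coverage > 1))
    stop("coverage out of range after dialect detection")
  hits[hits$query_id != hits$subject_id, , drop = FALSE]
}

#' Write a hits table in the package's BLAST-tabular dialect
#'
#' @param hits data.frame as returned by [readHitsTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHitsTable <- function(hits, path) {
  out <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                    pident = hits$pct_identity, length = hits$length,
                    evalue = hits$evalue, bitscore = hits$bitscore,
                    qcovs = hits$query_coverage, scovs = hits$subject_coverage)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prophage coordinate/metadata table
#'
#' Accepts either a TSV with columns `prophage_id, strain_id, start, end,
#' completeness` or a GFF3 file with feature type `prophage` and attributes
#' `ID`, `strain` and `phaster_class`. Coordinates are 1-based inclusive.
#' Completeness must be one of `intact`, `questionable`, `incomplete`.
#'
#' @param path path to the table.
#' @return data.frame with columns `prophage_id, strain_id, start, end,
#'   completeness`.
#' @export
readProphageTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^##gff-version", first)) {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    tab <- tab[tab[[3L]] == "prophage", , drop = FALSE]
    attr1 <- function(attrs, key) {
      m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
      vapply(m, function(x) if (length(x) == 2L) x[[2L]] else NA_character_,
             character(1L))
    }
    out <- data.frame(prophage_id = attr1(tab[[9L]], "ID"),
                      strain_id = attr1(tab[[9L]], "strain"),
                      start = as.integer(tab[[4L]]),
                      end = as.integer(tab[[5L]]),
                      completeness = attr1(tab[[9L]], "phaster_class"),
                      stringsAsFactors = FALSE)
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("prophage_id", "strain_id", "start", "end", "completeness")
    miss <- setdiff(need, names(out))
    if (length(miss))
      stop("prophage table missing column(s): ", paste(miss, collapse = ", "))
    out <- out[, need]
  }
  if (any(is.na(out$prophage_id)) || anyDuplicated(out$prophage_id))
    stop("prophage_id must be present and unique")
  bad <- !out$completeness %in% c("intact", "questionable", "incomplete")
  if (any(bad))
    stop("invalid completeness value(s): ",
         paste(unique(out$completeness[bad]), collapse = ", "))
  if (any(out$start > out$end)) stop("prophage with start > end")
  out
}

#' Read an infection matrix CSV
#'
#' First column holds producer identifiers, the header row target
#' identifiers, cells the number of replicates showing clearing.
#'
#' @param path path to the CSV.
#' @param nReplicates replicate count the cells are bounded by.
#' @return An [InfectionMatrix-class].
#' @export
readInfectionMatrix <- function(path, nReplicates = 3L) {
  tab <- read.csv(path, row.names = 1L, check.names = FALSE)
  InfectionMatrix(as.matrix(tab), nReplicates = nReplicates)
}

#' Write an infection matrix CSV
#'
#' @param x an [InfectionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeInfectionMatrix <- function(x, path) {
  write.csv(as.data.frame(counts(x)), path, quote = FALSE)
  invisible(path)
}

#' Read a restriction-modification system table
#'
#' TSV with columns `system_id, strain_id, rm_type, role, protein_fasta_id,
#' motif` (empty motif for systems whose recognition site is unknown).
#'
#' @param path path to the TSV.
#' @return data.frame; `motif` is `NA` where absent.
#' @export
readRmTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("system_id", "strain_id", "rm_type", "role", "protein_fasta_id",
            "motif")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("R-M table missing column(s): ", paste(miss, collapse = ", "))
  bad <- !tab$rm_type %in% c("I", "II", "IIG", "III", "IV")
  if (any(bad))
    stop("invalid rm_type value(s): ",
         paste(unique(tab$rm_type[bad]), collapse = ", "))
  ok <- !is.na(tab$motif)
  tab$motif[ok] <- vapply(tab$motif[ok], .checkIupac, character(1L))
  tab[, need]
}

#' Read a CRISPR array table
#'
#' TSV with columns `array_id, strain_id, spacer_seq`, one row per spacer.
#'
#' @param path path to the TSV.
#' @return data.frame of spacers.
#' @export
readCrisprTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("array_id", "strain_id", "spacer_seq")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("CRISPR table missing column(s): ", paste(miss, collapse = ", "))
  tab$spacer_seq <- toupper(tab$spacer_seq)
  bad <- !grepl("^[ACGTN]+$", tab$spacer_seq)
  if (any(bad))
    stop("invalid spacer sequence(s) in array(s): ",
         paste(unique(tab$array_id[bad]), collapse = ", "))
  tab[, need]
}

#' Read capsule-loss trajectories
#'
#' CSV with columns `population_id, strain_id, treatment, day,
#' capsulated_fraction`; one row per population per day.
#'
#' @param path path to the CSV.
#' @return data.frame of daily capsulated fractions.
#' @export
readTrajectories <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population_id", "strain_id", "treatment", "day",
            "capsulated_fraction")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trajectory table missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$capsulated_fraction < 0 | tab$capsulated_fraction > 1))
    stop("capsulated_fraction out of [0, 1]")
  if (any(tab$day < 0)) stop("negative day")
  tab[, need]
}
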
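# File I/O: FASTA input, IUPRED long-format disorder tracks, TSV results,
# per-protein JSON detail.

#' Read protein sequences from FASTA
#'
#' Wrapped sequence lines are concatenated, record order is preserved,
#' sequences are upper-cased, and the accession is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession` and `sequence`, one row per
#'   record (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(tibble::tibble(accession = character(0), sequence = character(0)))
  }
  acc <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(sprintf("empty sequence for record(s): %s", paste(acc[empty], collapse = ", ")),
      call. = FALSE
    )
  }
  dup <- unique(acc[duplicated(acc)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate accession(s): %s", paste(dup, collapse = ", ")),
      call. = FALSE
    )
  }
  tibble::tibble(accession = acc, sequence = unname(seqs))
}

#' Read a per-residue disorder track in IUPRED long format
#'
#' The format is: comment lines starting with `#`, then whitespace-separated
#' rows of (1-based position, residue letter, score). Positions must be
#' consecutive from 1, scores must lie in \[0, 1\], and the number of rows
#' must equal `expected_length`.
#'
#' @param path Path to the track file.
#' @param expected_length Length of the matching protein sequence.
#' @return Numeric vector of disorder scores in file order.
#' @export
read_disorder_track <- function(path, expected_length) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) != expected_length) {
    stop(sprintf(
      "%s: %d data rows but expected %d", path, length(lines), expected_length
    ), call. = FALSE)
  }
  fields <- strsplit(lines, "\\s+")
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop(sprintf("%s: malformed row %d", path, which(bad)[1L]), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 1L)))
  scores <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (any(is.na(pos)) || !identical(pos, seq_len(expected_length))) {
    stop(sprintf("%s: positions are not consecutive from 1", path), call. = FALSE)
  }
  if (any(is.na(scores)) || any(scores < 0) || any(scores > 1)) {
    stop(sprintf("%s: scores must lie in [0, 1]", path), call. = FALSE)
  }
  scores
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write per-protein results as TSV
#'
#' Writes the canonical result table: header `accession`, `n_idrs`,
#' `n_disordered_residues`, `abtscore`, `abtdensity`, `group`; floating
#' values with 6 significant digits; rows in input order. Reruns on the
#' same input produce byte-identical files.
#'
#' @param results Result tibble (from [score_proteome()], optionally
#'   [stratify()]ed). May have zero rows.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  grp <- if ("group" %in% names(results)) results$group else rep(NA_integer_, nrow(results))
  header <- paste(
    c("accession", "n_idrs", "n_disordered_residues", "abtscore", "abtdensity", "group"),
    collapse = "\t"
  )
  rows <- character(0)
  if (nrow(results) > 0L) {
    rows <- paste(
      results$accession,
      as.integer(results$n_idrs),
      as.integer(results$n_disordered_residues),
      fmt_num(results$abtscore),
      fmt_num(results$abtdensity),
      ifelse(is.na(grp), "NA", as.character(as.integer(grp))),
      sep = "\t"
    )
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a results TSV back into a tibble
#'
#' @param path Path written by [write_results_tsv()].
#' @return A tibble with the canonical result columns; `group` is integer
#'   with `NA` for unranked proteins.
#' @export
read_results_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      accession = readr::col_character(),
      n_idrs = readr::col_integer(),
      n_disordered_residues = readr::col_integer(),
      abtscore = readr::col_double(),
      abtdensity = readr::col_double(),
      group = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' Write per-protein JSON detail files
#'
#' One JSON file per protein (named `<accession>.json`) with the IDR
#' coordinates (1-based inclusive), per-IDR kappa, filtered area sum,
#' multiplier and score, for auditing the aggregate numbers in the TSV.
#'
#' @param results Result tibble from [score_proteome()] (with its `idrs`
#'   list column).
#' @param dir Output directory; created if needed.
#' @return The file paths, invisibly.
#' @export
write_idr_details_json <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!"idrs" %in% names(results)) {
    stop("`results` lacks the `idrs` detail column", call. = FALSE)
  }
  paths <- character(nrow(results))
  for (i in seq_len(nrow(results))) {
    paths[i] <- file.path(dir, paste0(results$accession[i], ".json"))
    jsonlite::write_json(
      list(
        accession = results$accession[i],
        n_disordered_residues = results$n_disordered_residues[i],
        abtscore = results$abtscore[i],
        abtdensity = results$abtdensity[i],
        idrs = results$idrs[[i]]
      ),
      paths[i],
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
    )
  }
  invisible(paths)
}
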
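# Proteome-scale batch scoring, percentile stratification and exports.

#' Batch-score a proteome
#'
#' Reads a FASTA file and, for each record, the matching disorder track
#' `<accession><track_suffix>` from `disorder_dir`; scores every protein
#' with [score_protein()]. Records without a track file are skipped with a
#' warning and recorded in the `skipped` attribute. Proteins without a
#' retained IDR are kept in the output with `abtdensity = NA`.
#'
#' @param fasta Path to the proteome FASTA.
#' @param disorder_dir Directory of per-protein disorder track files.
#' @param params An [abt_params()] object.
#' @param track_suffix File suffix of the track files (default
#'   `".iupred"`).
#' @return A tibble with one row per scored protein: `accession`,
#'   `n_idrs`, `n_disordered_residues`, `abtscore`, `abtdensity` and a
#'   list column `idrs` of per-IDR detail tables. The skip report is
#'   attached as attribute `"skipped"` (tibble of `accession`, `reason`).
#' @export
score_proteome <- function(fasta, disorder_dir, params = abt_params(),
                           track_suffix = ".iupred") {
  recs <- read_fasta(fasta)
  skipped_acc <- character(0)
  skipped_reason <- character(0)
  rows <- vector("list", nrow(recs))
  details <- vector("list", nrow(recs))
  kept <- logical(nrow(recs))
  for (i in seq_len(nrow(recs))) {
    acc <- recs$accession[i]
    track_path <- file.path(disorder_dir, paste0(acc, track_suffix))
    if (!file.exists(track_path)) {
      warning(sprintf("no disorder track for %s; skipping", acc), call. = FALSE)
      skipped_acc <- c(skipped_acc, acc)
      skipped_reason <- c(skipped_reason, "missing disorder track")
      next
    }
    track <- read_disorder_track(track_path, nchar(recs$sequence[i]))
    prot <- score_protein(recs$sequence[i], track, accession = acc, params = params)
    rows[[i]] <- glance(prot)
    details[[i]] <- prot$idrs
    kept[i] <- TRUE
  }
  if (!any(kept)) stop("no scorable proteins", call. = FALSE)
  out <- dplyr::bind_rows(rows[kept])
  out$idrs <- details[kept]
  attr(out, "skipped") <- tibble::tibble(
    accession = skipped_acc, reason = skipped_reason
  )
  out
}

#' Stratify scored proteins into percentile groups by ABTdensity
#'
#' Proteins with a defined ABTdensity are ranked in descending order
#' (ties broken stably by input order) and cut at the given percentile
#' fractions of the ranked total: with the default cuts, Group 1 is the top
#' 5%, Group 2 reaches down to 15%, Group 3 to 30%, and Group 4 is the
#' remainder. Group sizes use floor arithmetic on the cumulative cut
#' points. Proteins without an IDR receive no group (`NA`).
#'
#' @param results Result tibble with `abtdensity` (e.g. from
#'   [score_proteome()]).
#' @param cuts Strictly increasing fractions in (0, 1); `length(cuts) + 1`
#'   groups are formed.
#' @return `results` with an integer `group` column; the number of groups
#'   is attached as attribute `"n_groups"`.
#' @export
stratify <- function(results, cuts = c(0.05, 0.15, 0.30)) {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 1L || any(diff(cuts) <= 0) || any(cuts <= 0) || any(cuts >= 1)) {
    stop("`cuts` must be strictly increasing fractions in (0, 1)", call. = FALSE)
  }
  dens <- results$abtdensity
  ranked <- which(!is.na(dens))
  if (length(ranked) == 0L) {
    stop("no protein has a defined ABTdensity; nothing to stratify", call. = FALSE)
  }
  n <- length(ranked)
  ord <- ranked[order(-dens[ranked])] # stable: ties keep input order
  bounds <- floor(cuts * n + 1e-9)
  group <- rep(NA_integer_, nrow(results))
  rank_of <- seq_len(n)
  grp_ranked <- rowSums(outer(rank_of, bounds, `>`)) + 1L
  group[ord] <- as.integer(grp_ranked)
  out <- results
  out$group <- group
  attr(out, "skipped") <- attr(results, "skipped")
  attr(out, "n_groups") <- length(cuts) + 1L
  out
}

#' Summarize stratified groups
#'
#' The machine twin of a group summary table: per group, the protein count,
#' the ABTscore and ABTdensity ranges, and the mean ABTdensity.
#'
#' @param results Stratified result tibble (from [stratify()]).
#' @return A tibble with one row per group.
#' @export
summarize_groups <- function(results) {
  if (!"group" %in% names(results)) {
    stop("`results` has no `group` column; run stratify() first", call. = FALSE)
  }
  results |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      abtscore_min = min(.data$abtscore),
      abtscore_max = max(.data$abtscore),
      abtdensity_min = min(.data$abtdensity),
      abtdensity_max = max(.data$abtdensity),
      abtdensity_mean = mean(.data$abtdensity),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
}

#' Score distribution of a protein subset
#'
#' Given an external accession list (e.g. nucleolar or stress-granule
#' proteins), reports the size of its intersection with the scored set and
#' the median ABTscore and ABTdensity over that intersection (medians of
#' ABTdensity ignore proteins without an IDR). Unknown accessions are
#' counted, not an error; an empty intersection is.
#'
#' @param results Result tibble.
#' @param accessions Character vector of accessions.
#' @return A one-row tibble: `n`, `n_missing`, `median_abtscore`,
#'   `median_abtdensity`.
#' @export
subset_summary <- function(results, accessions) {
  accessions <- unique(accessions)
  if (length(accessions) == 0L) stop("`accessions` is empty", call. = FALSE)
  hit <- results$accession %in% accessions
  if (!any(hit)) stop("no listed accession is present in `results`", call. = FALSE)
  sub <- results[hit, , drop = FALSE]
  tibble::tibble(
    n = nrow(sub),
    n_missing = sum(!accessions %in% results$accession),
    median_abtscore = stats::median(sub$abtscore),
    median_abtdensity = stats::median(sub$abtdensity, na.rm = TRUE)
  )
}

#' Export per-group accession lists
#'
#' Writes one plain-text file per group (`group1_accessions.txt`, ...), one
#' accession per line in ranked order, for pasting into external enrichment
#' or network web tools. Empty groups still produce an (empty) file, and
#' reruns are byte-identical.
#'
#' @param results Stratified result tibble (from [stratify()]).
#' @param outdir Output directory; created if needed.
#' @return The file paths, invisibly.
#' @export
export_group_accessions <- function(results, outdir) {
  if (!"group" %in% names(results)) {
    stop("`results` has no `group` column; run stratify() first", call. = FALSE)
  }
  n_groups <- attr(results, "n_groups")
  if (is.null(n_groups)) n_groups <- max(4L, max(results$group, na.rm = TRUE))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  ranked <- results[!is.na(results$group), , drop = FALSE]
  ranked <- ranked[order(-ranked$abtdensity), , drop = FALSE]
  paths <- character(n_groups)
  for (g in seq_len(n_groups)) {
    paths[g] <- file.path(outdir, sprintf("group%d_accessions.txt", g))
    con <- file(paths[g], open = "wb")
    writeLines(ranked$accession[ranked$group == g], con, sep = "\n")
    close(con)
  }
  invisible(paths)
}
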
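# Per-IDR and per-protein scoring: filtered tract areas weighted by kappa.

#' Score one IDR subsequence
#'
#' Computes the NCPR profile (window 5), sums the areas of charged tracts
#' with area strictly greater than `min_area`, multiplies that sum by
#' `(0.6 + kappa)^2`, and reports the pieces. An undefined kappa (no
#' charged residues, or charges of one sign only) is treated as 0, giving
#' the minimum multiplier 0.36; when that happens with a nonzero area sum a
#' warning is emitted.
#'
#' @param idr_seq Amino-acid sequence of the IDR (one string; for merged
#'   IDRs this includes the low-disorder gap residues).
#' @param ncpr_window NCPR window width (odd, default 5).
#' @param min_area Strict tract-area threshold (default 1).
#' @param kappa_max_ops Budget passed to [charge_kappa()].
#' @return A one-row tibble: `length`, `f_plus`, `f_minus`, `kappa` (`NA`
#'   when undefined), `filtered_area_sum`, `multiplier`, `score`.
#' @examples
#' score_idr("DDDDDKKKKK") # area 7.6, kappa 1, score 19.456
#' @export
score_idr <- function(idr_seq, ncpr_window = 5L, min_area = 1,
                      kappa_max_ops = 2e8) {
  prof <- ncpr_profile(idr_seq, ncpr_window)
  fas <- sum_filtered_areas(prof, min_area)
  k <- charge_kappa(idr_seq, max_ops = kappa_max_ops)
  fr <- charge_fractions(idr_seq)
  if (is.na(k) && fas > 0) {
    warning(
      "kappa undefined for an IDR with nonzero tract area; using multiplier 0.36",
      call. = FALSE
    )
  }
  mult <- (0.6 + ifelse(is.na(k), 0, k))^2
  tibble::tibble(
    length = nchar(idr_seq),
    f_plus = unname(fr["f_plus"]),
    f_minus = unname(fr["f_minus"]),
    kappa = k,
    filtered_area_sum = fas,
    multiplier = mult,
    score = fas * mult
  )
}

#' Score a protein from its sequence and disorder track
#'
#' Segments the disorder track into retained IDRs, scores each IDR
#' subsequence (gap residues of merged IDRs included), and aggregates:
#' the ABTscore is the sum of per-IDR scores and the ABTdensity is the
#' ABTscore divided by the total number of retained disordered residues
#' (or, with `density_denominator = "per_region"`, the mean per-IDR
#' score/length ratio). A protein with no retained IDR gets ABTscore 0 and
#' an `NA` ABTdensity, and is excluded from percentile ranking downstream.
#'
#' @param sequence Amino-acid sequence (one string).
#' @param disorder Numeric vector of per-residue disorder propensities in
#'   \[0, 1\], same length as the sequence.
#' @param accession Protein identifier.
#' @param params An [abt_params()] object.
#' @return An object of class `"abt_protein"`: a list with `accession`,
#'   `sequence`, `disorder`, `params`, a per-IDR tibble `idrs` (`start`,
#'   `end` 1-based inclusive plus the [score_idr()] columns), `abtscore`,
#'   `n_disordered_residues` and `abtdensity`. Use [tidy()] for the per-IDR
#'   table and [glance()] for a one-row summary.
#' @examples
#' p <- score_protein(strrep("DK", 25), rep(0.9, 50))
#' glance(p)
#' @export
score_protein <- function(sequence, disorder, accession = "protein",
                          params = abt_params()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("sequence must be non-empty", call. = FALSE)
  if (length(disorder) != n) {
    stop(sprintf(
      "disorder track length (%d) does not match sequence length (%d) for %s",
      length(disorder), n, accession
    ), call. = FALSE)
  }
  segs <- segment_idrs(disorder, params)
  if (nrow(segs) == 0L) {
    idrs <- tibble::tibble(
      start = integer(0), end = integer(0), length = integer(0),
      f_plus = numeric(0), f_minus = numeric(0), kappa = numeric(0),
      filtered_area_sum = numeric(0), multiplier = numeric(0),
      score = numeric(0)
    )
  } else {
    scored <- purrr::map2(segs$start, segs$end, function(s, e) {
      score_idr(substr(sequence, s, e),
        ncpr_window = params$ncpr_window,
        min_area = params$min_area,
        kappa_max_ops = params$kappa_max_ops
      )
    })
    idrs <- dplyr::bind_cols(segs, dplyr::bind_rows(scored))
  }
  n_dis <- sum(idrs$length)
  abtscore <- sum(idrs$score)
  abtdensity <- if (n_dis == 0L) {
    NA_real_
  } else if (params$density_denominator == "total") {
    abtscore / n_dis
  } else {
    mean(idrs$score / idrs$length)
  }
  structure(
    list(
      accession = accession,
      sequence = sequence,
      disorder = as.numeric(disorder),
      params = params,
      idrs = idrs,
      abtscore = abtscore,
      n_disordered_residues = as.integer(n_dis),
      abtdensity = abtdensity
    ),
    class = "abt_protein"
  )
}

#' @export
print.abt_protein <- function(x, ...) {
  cat(sprintf(
    "<abt_protein> %s: %d residues, %d IDR(s), %d disordered residues\n",
    x$accession, nchar(x$sequence), nrow(x$idrs), x$n_disordered_residues
  ))
  cat(sprintf(
    "  ABTscore %.6g, ABTdensity %s\n", x$abtscore,
    if (is.na(x$abtdensity)) "undefined (no IDR)" else sprintf("%.6g", x$abtdensity)
  ))
  if (nrow(x$idrs) > 0L) print(x$idrs)
  invisible(x)
}

#' Per-IDR detail of a scored protein
#'
#' @param x An `abt_protein` object.
#' @param ... Unused.
#' @return A tibble with one row per retained IDR.
#' @export
tidy.abt_protein <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(accession = rep(x$accession, nrow(x$idrs))), x$idrs)
}

#' One-row summary of a scored protein
#'
#' @param x An `abt_protein` object.
#' @param ... Unused.
#' @return A one-row tibble: `accession`, `n_idrs`,
#'   `n_disordered_residues`, `abtscore`, `abtdensity`.
#' @export
glance.abt_protein <- function(x, ...) {
  tibble::tibble(
    accession = x$accession,
    n_idrs = nrow(x$idrs),
    n_disordered_residues = x$n_disordered_residues,
    abtscore = x$abtscore,
    abtdensity = x$abtdensity
  )
}
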
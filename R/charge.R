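# NCPR profiles and charged-tract detection within an IDR subsequence.

# split a single string into a character vector of residues, or pass a
# vector of single letters through
as_residues <- function(seq) {
  if (length(seq) == 1L) {
    strsplit(seq, "", fixed = TRUE)[[1]] # "" becomes character(0)
  } else {
    as.character(seq)
  }
}

#' Formal charge of amino-acid residues
#'
#' Lysine and arginine carry +1, aspartate and glutamate -1; every other
#' letter (including histidine and ambiguity codes such as X, B, Z, U, O)
#' is neutral.
#'
#' @param aa A character vector of single letters, or one string (split into
#'   residues).
#' @return Integer vector of charges in \{-1, 0, +1\}.
#' @examples
#' residue_charge(c("D", "R", "H"))
#' residue_charge("DDKKG")
#' @export
residue_charge <- function(aa) {
  res <- toupper(as_residues(aa))
  ch <- integer(length(res))
  ch[res %in% c("K", "R")] <- 1L
  ch[res %in% c("D", "E")] <- -1L
  ch
}

#' Windowed net-charge-per-residue profile
#'
#' The NCPR at each residue is the mean formal charge over a centered window
#' (default 5 residues) that shrinks at the ends of the sequence. The
#' profile is computed on the IDR subsequence alone; residues outside the
#' IDR are never read.
#'
#' @param seq Amino-acid sequence (one string) of the IDR.
#' @param window Odd positive integer window width.
#' @return Numeric vector in \[-1, 1\], one value per residue.
#' @examples
#' ncpr_profile("DDDDDKKKKK")
#' @export
ncpr_profile <- function(seq, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  ch <- residue_charge(seq)
  if (length(ch) == 0L) stop("sequence must be non-empty", call. = FALSE)
  rolling_mean(as.numeric(ch), window)
}

#' Detect sign-constant charged tracts in an NCPR profile
#'
#' A tract is a maximal run of consecutive positions whose NCPR values are
#' all strictly positive or all strictly negative; a zero value or a sign
#' change terminates the tract. The tract area is the number of residues
#' times the mean absolute NCPR, i.e. the absolute sum of NCPR values over
#' the tract.
#'
#' @param profile Numeric NCPR vector (from [ncpr_profile()]).
#' @return A tibble with columns `start`, `end` (1-based inclusive into the
#'   IDR), `sign` (+1 or -1) and `area`, sorted and disjoint.
#' @examples
#' find_tracts(ncpr_profile("DDDDDKKKKK"))
#' @export
find_tracts <- function(profile) {
  s <- sign(profile)
  if (length(s) == 0L || !any(s != 0)) {
    return(tibble::tibble(
      start = integer(0), end = integer(0),
      sign = integer(0), area = numeric(0)
    ))
  }
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  starts <- as.integer(starts[keep])
  ends <- as.integer(ends[keep])
  cs <- cumsum(c(0, profile))
  tibble::tibble(
    start = starts,
    end = ends,
    sign = as.integer(r$values[keep]),
    area = abs(cs[ends + 1L] - cs[starts])
  )
}

#' Sum of charged-tract areas passing the area filter
#'
#' Sums the areas of tracts (of either sign) whose area is strictly greater
#' than `min_area`. Because NCPR values are small rationals, tract areas
#' frequently land exactly on the threshold (e.g. a lone +0.2 x 5 tract has
#' area exactly 1); the comparison therefore uses a 1e-9 tolerance, so a
#' tract must exceed `min_area` by more than 1e-9 to contribute, making the
#' strict filter robust to float summation order.
#'
#' @param profile Numeric NCPR vector.
#' @param min_area Strict lower bound on contributing tract areas
#'   (default 1).
#' @return Non-negative scalar.
#' @examples
#' sum_filtered_areas(ncpr_profile("DDDDDKKKKK")) # 7.6
#' @export
sum_filtered_areas <- function(profile, min_area = 1) {
  tr <- find_tracts(profile)
  sum(tr$area[tr$area > min_area + 1e-9])
}

#' Fractions of positively and negatively charged residues
#'
#' @param seq Amino-acid sequence (one string).
#' @return Named numeric vector `c(f_plus = , f_minus = )`.
#' @examples
#' charge_fractions("DDKK")
#' @export
charge_fractions <- function(seq) {
  ch <- residue_charge(seq)
  if (length(ch) == 0L) stop("sequence must be non-empty", call. = FALSE)
  c(f_plus = mean(ch == 1L), f_minus = mean(ch == -1L))
}
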
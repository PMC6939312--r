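# Das-Pappu kappa: blob-wise charge asymmetry deviation (delta), its
# maximum over arrangements of the same composition (delta_max), and their
# ratio averaged over blob sizes 5 and 6.

# delta from a vector of per-residue charges
delta_from_charges <- function(ch, blob) {
  n <- length(ch)
  nw <- n - blob + 1L
  csP <- cumsum(c(0L, ch == 1L))
  csM <- cumsum(c(0L, ch == -1L))
  i <- seq_len(nw)
  wp <- (csP[i + blob] - csP[i]) / blob
  wm <- (csM[i + blob] - csM[i]) / blob
  den <- wp + wm
  sig <- ifelse(den == 0, 0, (wp - wm)^2 / den)
  fp <- csP[n + 1L] / n
  fm <- csM[n + 1L] / n
  gden <- fp + fm
  sg <- if (gden == 0) 0 else (fp - fm)^2 / gden
  mean((sig - sg)^2)
}

#' Blob-wise charge asymmetry deviation (delta)
#'
#' For every fully contained window of `blob` residues, the local charge
#' asymmetry is sigma = (f+ - f-)^2 / (f+ + f-) (zero for windows without
#' charged residues); delta is the mean squared deviation of the window
#' sigmas from the whole-sequence sigma.
#'
#' @param seq Amino-acid sequence (one string).
#' @param blob Window size in residues; the sequence must be at least this
#'   long.
#' @return Non-negative scalar.
#' @examples
#' charge_delta("EEEKKK", 5)
#' charge_delta("EEEEEE", 5) # 0: every window matches the global sigma
#' @export
charge_delta <- function(seq, blob = 5L) {
  blob <- as.integer(blob)
  ch <- residue_charge(seq)
  if (length(ch) < blob) {
    stop("sequence shorter than the blob size", call. = FALSE)
  }
  delta_from_charges(ch, blob)
}

# candidate charge vectors for the constructive fallback: the two charge
# species and the neutrals as contiguous blocks in every 3-gap placement,
# plus arrangements with one species split across the two ends
dmax_candidates <- function(p, m, z) {
  cands <- list()
  add <- function(v) cands[[length(cands) + 1L]] <<- v
  blocks <- function(a, b, c2) c(rep(0L, a), rep(1L, p), rep(0L, b), rep(-1L, m), rep(0L, c2))
  for (a in 0:z) {
    for (b in 0:(z - a)) add(blocks(a, b, z - a - b))
  }
  counts <- c(`1` = p, `-1` = m, `0` = z)
  species <- c(1L, -1L, 0L)
  for (s in species) {
    others <- setdiff(species, s)
    cs <- counts[as.character(s)]
    if (cs == 0L) next
    for (ord in list(others, rev(others))) {
      mid <- c(
        rep(ord[1L], counts[as.character(ord[1L])]),
        rep(ord[2L], counts[as.character(ord[2L])])
      )
      for (x in 0:cs) add(c(rep(s, x), mid, rep(s, cs - x)))
    }
  }
  cands
}

#' Maximum delta over arrangements of a composition (delta_max)
#'
#' The normalizer of kappa: the largest [charge_delta()] attainable by any
#' permutation of the sequence's residue composition. Computed exactly by a
#' dynamic program over sliding-window states whenever the state space fits
#' the operation budget; beyond the budget, the maximum over a constructive
#' family of block arrangements (contiguous charge/neutral blocks in every
#' placement, plus one species split across the two ends) is used instead.
#'
#' @param seq Amino-acid sequence (one string); only its composition
#'   matters.
#' @param blob Window size in residues.
#' @param max_ops Operation budget for the exact dynamic program.
#' @return Non-negative scalar, `>= charge_delta(seq, blob)` (exactly so in
#'   the exact regime).
#' @examples
#' charge_delta_max("EEEKKK", 5)
#' @export
charge_delta_max <- function(seq, blob = 5L, max_ops = 2e8) {
  blob <- as.integer(blob)
  ch <- residue_charge(seq)
  n <- length(ch)
  if (n < blob) stop("sequence shorter than the blob size", call. = FALSE)
  p <- sum(ch == 1L)
  m <- sum(ch == -1L)
  z <- n - p - m
  if (p + m == 0L) return(0)
  ops <- as.numeric(n) * 3^(blob - 1) * (p + 1) * (m + 1) * 3
  if (ops <= max_ops) {
    return(dmax_exact_cpp(p, m, z, blob))
  }
  max(vapply(dmax_candidates(p, m, z), delta_from_charges,
    numeric(1),
    blob = blob
  ))
}

#' Kappa charge-segregation parameter
#'
#' Quantifies how segregated the acidic and basic residues of a sequence
#' are: near 0 for well-mixed charges (e.g. "DKDKDKDK"), 1 for a fully
#' segregated diblock (e.g. "DDDDKKKK"). Computed as the mean of
#' delta/delta_max over blob sizes 5 and 6; a blob longer than the sequence
#' is skipped, and a blob whose delta_max is 0 (no charged residues, or all
#' charges of one sign) contributes no term. When no term is available the
#' value is undefined and `NA` is returned.
#'
#' @param seq Amino-acid sequence (one string).
#' @param blobs Integer vector of blob sizes (default 5 and 6).
#' @param max_ops Operation budget passed to [charge_delta_max()].
#' @return Scalar in \[0, 1\], or `NA` when undefined.
#' @examples
#' charge_kappa("EEEEEKKKKK") # 1: already maximally segregated
#' charge_kappa("EKEKEKEKEK") # close to 0
#' charge_kappa("GGGGGGGGGG") # NA: no charged residues
#' @export
charge_kappa <- function(seq, blobs = c(5L, 6L), max_ops = 2e8) {
  ch <- residue_charge(seq)
  if (length(ch) == 0L) stop("sequence must be non-empty", call. = FALSE)
  terms <- numeric(0)
  for (g in as.integer(blobs)) {
    if (length(ch) < g) next
    dm <- charge_delta_max(seq, g, max_ops = max_ops)
    if (dm > 0) {
      terms <- c(terms, delta_from_charges(ch, g) / dm)
    }
  }
  if (length(terms) == 0L) return(NA_real_)
  mean(terms)
}
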
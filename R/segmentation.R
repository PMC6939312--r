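# IDR segmentation: smooth -> threshold -> merge -> length filter.
# All coordinates are 1-based inclusive residue positions.

# centered rolling mean whose window shrinks at the ends of the track
rolling_mean <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a disorder track with a centered rolling mean
#'
#' The window is centered on each residue and shrinks at the ends of the
#' track, so the output has the same length as the input and single-residue
#' tracks are returned unchanged.
#'
#' @param scores Numeric vector of per-residue disorder propensities.
#' @param window Odd positive integer window width (default 7).
#' @return Numeric vector, same length as `scores`.
#' @examples
#' smooth_track(rep(0.6, 10))
#' smooth_track(c(0, 0, 0, 1, 0, 0, 0))[4] # 1/7
#' @export
smooth_track <- function(scores, window = 7L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("`window` must be an odd positive integer", call. = FALSE)
  }
  if (length(scores) == 0L) return(numeric(0))
  rolling_mean(as.numeric(scores), window)
}

#' Maximal runs above a disorder cutoff
#'
#' Returns the maximal runs of positions whose value is strictly greater
#' than `cutoff`, as 1-based inclusive segments. Values exactly at the
#' cutoff do not qualify.
#'
#' @param smoothed Numeric vector (typically a smoothed disorder track).
#' @param cutoff Threshold; strictly-greater comparison.
#' @return A tibble with integer columns `start` and `end`, sorted and
#'   disjoint.
#' @examples
#' threshold_runs(rep(0.5, 40), 0.45)
#' threshold_runs(rep(0.45, 40), 0.45) # empty: strict inequality
#' @export
threshold_runs <- function(smoothed, cutoff = 0.45) {
  above <- smoothed > cutoff
  if (length(above) == 0L || !any(above)) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = as.integer(starts[keep]), end = as.integer(ends[keep]))
}

#' Merge segments separated by short gaps
#'
#' Consecutive segments separated by at most `max_gap` residues are unioned
#' into one segment whose span includes the gap residues. With the default
#' gap of 7, two disorder runs 7 residues apart become one IDR while a gap
#' of 8 structured residues keeps them apart.
#'
#' @param segments Tibble/data frame with `start` and `end` (1-based
#'   inclusive), sorted and disjoint.
#' @param max_gap Non-negative integer; gaps of at most this many residues
#'   are absorbed.
#' @return A tibble of merged segments, sorted and disjoint, any two
#'   separated by more than `max_gap` residues.
#' @examples
#' segs <- tibble::tibble(start = c(1L, 38L), end = c(30L, 60L))
#' merge_segments(segs, 7) # gap of 7 residues: merged into [1, 60]
#' @export
merge_segments <- function(segments, max_gap = 7L) {
  max_gap <- as.integer(max_gap)
  if (max_gap < 0L) stop("`max_gap` must be non-negative", call. = FALSE)
  starts <- as.integer(segments$start)
  ends <- as.integer(segments$end)
  n <- length(starts)
  if (any(ends < starts)) stop("segments must satisfy start <= end", call. = FALSE)
  if (n > 1L && any(starts[-1L] <= ends[-n])) {
    stop("segments must be sorted and disjoint", call. = FALSE)
  }
  if (n <= 1L) {
    return(tibble::tibble(start = starts, end = ends))
  }
  out_start <- starts[1L]
  out_end <- ends[1L]
  res_start <- integer(0)
  res_end <- integer(0)
  for (i in 2L:n) {
    gap <- starts[i] - out_end - 1L
    if (gap <= max_gap) {
      out_end <- ends[i]
    } else {
      res_start <- c(res_start, out_start)
      res_end <- c(res_end, out_end)
      out_start <- starts[i]
      out_end <- ends[i]
    }
  }
  tibble::tibble(start = c(res_start, out_start), end = c(res_end, out_end))
}

#' Drop segments shorter than a minimum length
#'
#' Retains exactly the segments of length at least `min_length`; a segment
#' of exactly `min_length` residues is kept.
#'
#' @param segments Tibble with `start` and `end` (1-based inclusive).
#' @param min_length Positive integer minimum residue count.
#' @return Filtered tibble.
#' @export
filter_segments <- function(segments, min_length = 30L) {
  min_length <- as.integer(min_length)
  if (min_length < 1L) stop("`min_length` must be positive", call. = FALSE)
  keep <- (segments$end - segments$start + 1L) >= min_length
  segments[keep, , drop = FALSE]
}

#' Segment a disorder track into retained IDRs
#'
#' Applies the full segmentation pipeline in order: centered rolling-mean
#' smoothing, strict thresholding, gap merging (gap residues are absorbed
#' into the merged IDR), and the minimum-length filter.
#'
#' @param track Numeric vector of per-residue disorder propensities in
#'   \[0, 1\].
#' @param params An [abt_params()] object.
#' @return A tibble of IDR segments (`start`, `end`, 1-based inclusive),
#'   sorted, disjoint, each at least `params$min_length` residues long.
#' @examples
#' segment_idrs(rep(0.9, 50))
#' @export
segment_idrs <- function(track, params = abt_params()) {
  track <- as.numeric(track)
  if (any(is.na(track)) || any(track < 0) || any(track > 1)) {
    stop("disorder track values must lie in [0, 1]", call. = FALSE)
  }
  smoothed <- smooth_track(track, params$smooth_window)
  runs <- threshold_runs(smoothed, params$cutoff)
  merged <- merge_segments(runs, params$merge_gap)
  filter_segments(merged, params$min_length)
}
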
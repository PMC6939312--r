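#' Scoring and segmentation parameters
#'
#' Bundles every tunable of the pipeline with the published defaults: disorder
#' smoothing window of 7 residues, disorder cutoff 0.45 (strict), IDRs within
#' 7 residues of each other merged, IDRs shorter than 30 residues dropped,
#' NCPR window of 5 residues, and tract areas retained only when strictly
#' greater than 1.
#'
#' @param smooth_window Odd positive integer; width of the centered rolling
#'   mean applied to the disorder track (residues).
#' @param cutoff Disorder propensity threshold; positions with smoothed
#'   disorder strictly greater than this belong to an IDR run.
#' @param merge_gap Maximum number of ordered residues between two disorder
#'   runs for them to be merged into one IDR (gap residues are kept in the
#'   merged IDR).
#' @param min_length Minimum IDR length in residues; shorter IDRs are
#'   discarded after merging.
#' @param ncpr_window Odd positive integer; width of the centered NCPR
#'   window, computed within each IDR only.
#' @param min_area Only charged tracts with area strictly greater than this
#'   contribute to the score.
#' @param density_denominator `"total"` divides the ABTscore by the total
#'   number of retained disordered residues in the protein (one density per
#'   protein); `"per_region"` averages the per-IDR score/length ratios
#'   instead. Both stay within \[0, 2.56\].
#' @param kappa_max_ops Operation budget above which the exact
#'   dynamic-programming kappa normalization falls back to a constructive
#'   block-arrangement search; see [charge_delta_max()].
#'
#' @return A list of class `"abt_params"`.
#' @examples
#' abt_params()
#' abt_params(min_length = 40)
#' @export
abt_params <- function(smooth_window = 7L,
                       cutoff = 0.45,
                       merge_gap = 7L,
                       min_length = 30L,
                       ncpr_window = 5L,
                       min_area = 1,
                       density_denominator = c("total", "per_region"),
                       kappa_max_ops = 2e8) {
  smooth_window <- as.integer(smooth_window)
  merge_gap <- as.integer(merge_gap)
  min_length <- as.integer(min_length)
  ncpr_window <- as.integer(ncpr_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("`smooth_window` must be an odd positive integer", call. = FALSE)
  }
  if (ncpr_window < 1L || ncpr_window %% 2L == 0L) {
    stop("`ncpr_window` must be an odd positive integer", call. = FALSE)
  }
  if (merge_gap < 0L) stop("`merge_gap` must be non-negative", call. = FALSE)
  if (min_length < 1L) stop("`min_length` must be positive", call. = FALSE)
  structure(
    list(
      smooth_window = smooth_window,
      cutoff = cutoff,
      merge_gap = merge_gap,
      min_length = min_length,
      ncpr_window = ncpr_window,
      min_area = min_area,
      density_denominator = match.arg(density_denominator),
      kappa_max_ops = kappa_max_ops
    ),
    class = "abt_params"
  )
}

#' @export
print.abt_params <- function(x, ...) {
  cat("ABT scoring parameters\n")
  cat(sprintf("  disorder smoothing window : %d residues\n", x$smooth_window))
  cat(sprintf("  disorder cutoff (strict)  : %g\n", x$cutoff))
  cat(sprintf("  IDR merge gap             : <= %d residues\n", x$merge_gap))
  cat(sprintf("  minimum IDR length        : %d residues\n", x$min_length))
  cat(sprintf("  NCPR window               : %d residues\n", x$ncpr_window))
  cat(sprintf("  tract area filter         : area > %g\n", x$min_area))
  cat(sprintf("  density denominator       : %s\n", x$density_denominator))
  invisible(x)
}
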
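# ggplot2 displays: per-protein NCPR profile with highlighted tracts, and
# proteome-level ABTdensity distributions.

#' Plot a scored protein's NCPR profile and charged tracts
#'
#' Draws the windowed NCPR profile within each retained IDR along the
#' protein, shades the IDR spans, and highlights sign-constant charged
#' tracts; tracts whose area passes the filter (area > `min_area`) are
#' drawn opaque, the rest faint.
#'
#' @param object An `abt_protein` from [score_protein()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abt_protein <- function(object, ...) {
  p <- object$params
  idrs <- object$idrs
  prof_tbl <- purrr::map2_dfr(idrs$start, idrs$end, function(s, e) {
    sub <- substr(object$sequence, s, e)
    tibble::tibble(position = s:e, ncpr = ncpr_profile(sub, p$ncpr_window))
  })
  tract_tbl <- purrr::map2_dfr(idrs$start, idrs$end, function(s, e) {
    sub <- substr(object$sequence, s, e)
    tr <- find_tracts(ncpr_profile(sub, p$ncpr_window))
    tr$start <- tr$start + s - 1L
    tr$end <- tr$end + s - 1L
    tr
  })
  g <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = idrs,
      ggplot2::aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5, ymin = -1, ymax = 1),
      fill = "grey85", alpha = 0.5
    )
  if (nrow(tract_tbl) > 0L) {
    g <- g + ggplot2::geom_rect(
      data = tract_tbl,
      ggplot2::aes(
        xmin = .data$start - 0.5, xmax = .data$end + 0.5,
        ymin = 0, ymax = .data$sign * pmin(1, .data$area / pmax(.data$end - .data$start + 1, 1)),
        fill = factor(.data$sign),
        alpha = .data$area > p$min_area
      )
    ) +
      ggplot2::scale_fill_manual(
        values = c(`-1` = "#c0392b", `1` = "#2980b9"),
        labels = c(`-1` = "acidic", `1` = "basic"), name = "tract"
      ) +
      ggplot2::scale_alpha_manual(
        values = c(`TRUE` = 0.8, `FALSE` = 0.25),
        labels = c(`TRUE` = sprintf("area > %g", p$min_area), `FALSE` = "filtered out"),
        name = NULL
      )
  }
  g +
    ggplot2::geom_line(data = prof_tbl, ggplot2::aes(x = .data$position, y = .data$ncpr)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::coord_cartesian(xlim = c(1, nchar(object$sequence)), ylim = c(-1, 1)) +
    ggplot2::labs(
      x = "residue", y = "NCPR",
      title = sprintf(
        "%s  (ABTscore %.4g, ABTdensity %s)", object$accession, object$abtscore,
        if (is.na(object$abtdensity)) "NA" else sprintf("%.4g", object$abtdensity)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot the ABTdensity distribution of a scored set
#'
#' Histogram of per-protein ABTdensity values; if the results are
#' stratified, bars are filled by group.
#'
#' @param results Result tibble from [score_proteome()] (optionally
#'   [stratify()]ed).
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_abtdensity <- function(results, bins = 40) {
  dat <- dplyr::filter(results, !is.na(.data$abtdensity))
  g <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$abtdensity))
  if ("group" %in% names(dat)) {
    g <- g + ggplot2::geom_histogram(
      ggplot2::aes(fill = factor(.data$group)),
      bins = bins
    ) +
      ggplot2::labs(fill = "group")
  } else {
    g <- g + ggplot2::geom_histogram(bins = bins)
  }
  g + ggplot2::labs(x = "ABTdensity", y = "proteins") + ggplot2::theme_minimal()
}
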
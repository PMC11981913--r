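# ggplot2 views of the main result types: decomposition graphs, spine
# tables, proximity strata and motif enrichment.

#' Plot a decomposition graph (2D projection)
#'
#' Projects the skeleton onto a coordinate plane, one path per branch,
#' coloured by compartment; the soma is drawn at its detected radius.
#'
#' @param object a `neuro_decomp`.
#' @param plane two coordinate names out of `x`,`y`,`z` (default `c("x","z")`).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot neuro_decomp
#' @export
autoplot.neuro_decomp <- function(object, plane = c("x", "z"), ...) {
  ax <- match(plane, c("x", "y", "z"))
  dat <- dplyr::bind_rows(lapply(active_branch_ids(object), function(id) {
    b <- object$branches[[id]]
    tibble::tibble(branch_id = id,
                   h = b$points[, ax[1]] / 1000,
                   v = b$points[, ax[2]] / 1000,
                   compartment = b$compartment %||% NA_character_)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(h, v, group = branch_id,
                                    colour = compartment)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::annotate("point", x = object$root$center[ax[1]] / 1000,
                      y = object$root$center[ax[2]] / 1000,
                      size = 3, shape = 21, fill = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(plane[1], " (um)"),
                  y = paste0(plane[2], " (um)"),
                  colour = "compartment") +
    ggplot2::theme_minimal()
}

#' Spine morphology overview plot
#'
#' Histogram of spine skeletal lengths with the detection benchmark
#' threshold marked, faceted by head/neck outcome when available.
#'
#' @param spines tibble from [detect_spines()] / [segment_head_neck()].
#' @param threshold_nm reference length threshold (default 700).
#' @return a ggplot.
#' @export
plot_spine_lengths <- function(spines, threshold_nm = 700) {
  p <- ggplot2::ggplot(spines,
                       ggplot2::aes(skeletal_length_nm)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = threshold_nm, linetype = 2) +
    ggplot2::labs(x = "spine skeletal length (nm)", y = "count") +
    ggplot2::theme_minimal()
  if ("has_neck" %in% names(spines))
    p <- p + ggplot2::facet_wrap(~has_neck,
                                 labeller = ggplot2::labeller(
                                   has_neck = c(`TRUE` = "head + neck",
                                                `FALSE` = "no neck")))
  p
}

#' Conversion-rate curves over a radius sweep
#'
#' @param strata tibble from [stratify_conversion()] with a `radius_nm`
#'   column and optional class columns.
#' @param colour optional name of the column mapped to colour.
#' @return a ggplot.
#' @export
plot_conversion <- function(strata, colour = NULL) {
  aes <- if (!is.null(colour))
    ggplot2::aes(radius_nm / 1000, rate,
                 colour = .data[[colour]], group = .data[[colour]])
  else ggplot2::aes(radius_nm / 1000, rate, group = 1)
  ggplot2::ggplot(strata, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "proximity radius (um)", y = "conversion rate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Motif enrichment plot
#'
#' Observed triad counts against the null mean with +/- 1 s.d. ribbons,
#' ordered by edge count.
#'
#' @param enr tibble from [enrichment()].
#' @return a ggplot.
#' @export
plot_enrichment <- function(enr) {
  enr$class <- factor(enr$class, levels = enr$class[order(enr$n_edges)])
  ggplot2::ggplot(enr, ggplot2::aes(class)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = null_mean, ymin = pmax(null_mean - null_sd, 0),
      ymax = null_mean + null_sd), colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = observed), colour = "firebrick",
                        size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "triad class (by edge count)",
                  y = "count (observed red, null grey)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
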
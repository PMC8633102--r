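epistasis_class_colours <- c(
  none = "grey85",
  magnitude = "#27408b",
  sign = "#d4a017",
  reciprocal_sign = "#2e8b57"
)

#' Plot a parameter-space scan
#'
#' Heat map of a [scan_identical_mutations()] or [scan_mutation_pair()]
#' result: either the signed epistasis magnitude (diverging red/blue scale,
#' white at zero) or the epistasis class per cell.
#'
#' @param object A `scan_grid` tibble.
#' @param fill `"epsilon"` (default) or `"eclass"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.scan_grid <- function(object, fill = c("epsilon", "eclass"), ...) {
  fill <- match.arg(fill)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y))
  if (fill == "epsilon") {
    lim <- max(abs(object$epsilon))
    p <- p +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$epsilon)) +
      ggplot2::scale_fill_gradient2(
        low = "#27408b", mid = "white", high = "#b22222",
        limits = c(-lim, lim), name = "epsilon\n(kcal/mol)")
  } else {
    p <- p +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$eclass)) +
      ggplot2::scale_fill_manual(values = epistasis_class_colours,
                                 name = "class")
  }
  p +
    ggplot2::labs(x = attr(object, "x_name"), y = attr(object, "y_name")) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
plot.scan_grid <- function(x, ...) print(autoplot(x, ...))

#' Plot an epistasis titration curve
#'
#' Epistasis against effector chemical potential, with points coloured by
#' epistatic class and the classification cutoff marked.
#'
#' @param object A [titrate_epistasis()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.titration_curve <- function(object, ...) {
  cutoff <- attr(object, "cutoff")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mu, y = .data$epsilon)) +
    ggplot2::geom_hline(yintercept = c(-cutoff, 0, cutoff),
                        linetype = c("dashed", "solid", "dashed"),
                        colour = "grey60") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$eclass), size = 1.6) +
    ggplot2::scale_colour_manual(values = epistasis_class_colours,
                                 name = "class") +
    ggplot2::labs(
      x = sprintf("mu_%s (kcal/mol)", attr(object, "ligand")),
      y = "epsilon (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' @export
plot.titration_curve <- function(x, ...) print(autoplot(x, ...))

#' Plot a DMS summary
#'
#' Either the fractional contribution of each epistatic class as a function
#' of the magnitude cutoff (stacked area), or the histogram of signed peak
#' epistasis.
#'
#' @param object A [summarize_dms()] result.
#' @param type `"classes"` (default) or `"histogram"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dms_summary <- function(object, type = c("classes", "histogram"),
                                 ...) {
  type <- match.arg(type)
  if (type == "classes") {
    sw <- object$sweep
    sw$eclass <- factor(sw$eclass, levels = rev(epistasis_classes()))
    ggplot2::ggplot(sw, ggplot2::aes(x = .data$cutoff, y = .data$fraction,
                                     fill = .data$eclass)) +
      ggplot2::geom_area() +
      ggplot2::scale_fill_manual(values = epistasis_class_colours,
                                 name = "class") +
      ggplot2::labs(x = "epistasis cutoff (kcal/mol)",
                    y = "fraction of pairs") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$histogram,
                    ggplot2::aes(x = .data$mid, y = .data$count)) +
      ggplot2::geom_col(width = object$histogram$upper -
                          object$histogram$lower,
                        fill = "grey40") +
      ggplot2::labs(x = "peak epsilon (kcal/mol)", y = "pairs") +
      ggplot2::theme_minimal()
  }
}

#' @export
plot.dms_summary <- function(x, ...) print(autoplot(x, ...))
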
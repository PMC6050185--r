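#' Plot a spatially embedded genealogy
#'
#' Maps the sampled individuals and the ancestor birth locations on the
#' landscape, with segments joining each node to its parent (minimal-image
#' wrapping is not drawn; segments crossing the boundary appear long).
#'
#' @param object An `slfv_genealogy` from a 2D simulation.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot slfv_genealogy
#' @export
autoplot.slfv_genealogy <- function(object, ...) {
  nodes <- object$nodes
  if (!"y" %in% names(nodes)) {
    stop("spatial genealogy plots need a 2D landscape", call. = FALSE)
  }
  seg <- dplyr::filter(nodes, !is.na(.data$parent))
  seg$xend <- nodes$x[seg$parent]
  seg$yend <- nodes$y[seg$parent]
  nodes$role <- ifelse(is_leaf(nodes), "sample", "ancestor")
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(xend = .data$xend, yend = .data$yend),
      linewidth = 0.3, colour = "grey60"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$role,
                                     size = .data$role)) +
    ggplot2::scale_size_manual(values = c(sample = 2.5, ancestor = 1.2)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "SLFV genealogy on the torus",
                  x = "x", y = "y", colour = NULL, size = NULL) +
    ggplot2::theme_minimal()
}

#' Plot ABC posterior samples
#'
#' Histograms of the accepted parameter draws with the posterior median
#' (solid) and HPDI bounds (dashed).
#'
#' @param object An `slfv_posterior`.
#' @param mass HPDI mass.
#' @param ... Unused.
#' @return A ggplot faceted by parameter.
#' @method autoplot slfv_posterior
#' @export
autoplot.slfv_posterior <- function(object, mass = 0.95, ...) {
  draws <- tidy(object)
  marks <- glance(object, mass = mass)
  marks <- tidyr::pivot_longer(
    marks[, c("parameter", "median", "hpdi_lower", "hpdi_upper")],
    -"parameter", names_to = "what", values_to = "value"
  )
  marks$lty <- ifelse(marks$what == "median", "median", "HPDI")
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$value, linetype = .data$lty)
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "accepted draws",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation estimates against truth
#'
#' @param object An `slfv_cv` from [loo_cv_r2()].
#' @param ... Unused.
#' @return A ggplot faceted by parameter with the 1:1 line.
#' @method autoplot slfv_cv
#' @export
autoplot.slfv_cv <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "true value", y = "ABC posterior median") +
    ggplot2::theme_minimal()
}

#' Isolation-by-distance scatter plot
#'
#' Pairwise genetic distance (mean per-site differences across loci) against
#' minimal-image torus distance, with the least-squares line whose slope and
#' intercept enter the summary vector.
#'
#' @param ds An `slfv_dataset` (or list of alignments).
#' @param sheet Sample sheet (defaults to the dataset's).
#' @param landscape The [landscape()].
#' @return A ggplot.
#' @export
plot_ibd <- function(ds, sheet = NULL, landscape) {
  if (inherits(ds, "slfv_dataset")) {
    if (is.null(sheet)) sheet <- ds$sheet
    ds <- ds$alignments
  }
  sheet <- validate_sample_sheet(sheet, landscape)
  pairs <- pairwise_index(nrow(sheet))
  gd <- rowMeans(matrix(
    vapply(ds, pairwise_genetic_distance, numeric(nrow(pairs)),
           pairs = pairs),
    nrow = nrow(pairs)
  ))
  loc <- sample_locations(sheet, landscape)
  td <- torus_distance(loc[pairs$i, , drop = FALSE],
                       loc[pairs$j, , drop = FALSE], landscape)
  df <- tibble::tibble(geographic = td, genetic = gd)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$geographic, y = .data$genetic)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "torus distance", y = "pairwise genetic distance",
                  title = "Isolation by distance") +
    ggplot2::theme_minimal()
}
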
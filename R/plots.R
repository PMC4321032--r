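# ggplot2 visualisations for each result type

#' @export
autoplot.genetic_map <- function(object, ...) {
  tbl <- object$map
  ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$group), y = .data$pos_cM)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$group), linewidth = 3,
                       colour = "grey85") +
    ggplot2::geom_point(shape = 95, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "linkage group", y = "position (cM)",
                  title = "Genetic map") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scan_result <- function(object, threshold = NULL, ...) {
  tbl <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(tbl, ggplot2::aes(.data$pos_cM, .data$lod,
                                         colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  p
}

#' @export
autoplot.effect_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$class, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "genotype class", y = "phenotype mean") +
    ggplot2::theme_minimal()
}

#' Oxford grid of synteny link counts
#'
#' @param stats result of [synteny_stats()].
#' @return A ggplot object: linkage group x target chromosome tile plot.
#' @export
plot_oxford <- function(stats) {
  ggplot2::ggplot(stats$oxford,
                  ggplot2::aes(.data$chrom, factor(.data$group),
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target chromosome", y = "linkage group",
                  fill = "links") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scaffold-to-group colinearity plot
#'
#' Mirrors the anchoring figure style: for scaffolds with at least
#' `min_markers` mapped markers, marker bp positions against map cM
#' positions, one panel per scaffold.
#'
#' @param map a `genetic_map` or map tibble.
#' @param marker_scaffolds tibble `(marker, scaffold, scaffold_bp)`.
#' @param group linkage group to display.
#' @param min_markers minimum mapped markers per displayed scaffold
#'   (default 4).
#' @return A ggplot object.
#' @export
plot_anchoring <- function(map, marker_scaffolds, group, min_markers = 4) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  d <- tbl %>%
    dplyr::filter(.data$group == !!group) %>%
    dplyr::inner_join(marker_scaffolds, by = "marker") %>%
    dplyr::group_by(.data$scaffold) %>%
    dplyr::filter(dplyr::n() >= min_markers) %>%
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$pos_cM, .data$scaffold_bp / 1e6,
                                  colour = .data$scaffold)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "linkage group position (cM)",
                  y = "scaffold position (Mb)") +
    ggplot2::theme_minimal()
}
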
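#' Anchor genome scaffolds to linkage groups
#'
#' Groups the mapped markers by the scaffold carrying them and assigns each
#' scaffold the modal linkage group of its markers (a tie makes the
#' scaffold `ambiguous` and counts as non-colocalized). Colinearity between
#' a scaffold's bp coordinates and its group's cM coordinates is measured
#' with the tie-adjusted Kendall rank correlation; its sign gives the
#' scaffold orientation.
#'
#' The headline colocalization percentage uses scaffolds with at least two
#' mapped markers as the denominator (singletons are trivially colocalized
#' and would inflate it); the singleton-inclusive variant is also reported.
#'
#' @param map a `genetic_map` or tibble `(group, marker, pos_cM)`.
#' @param marker_scaffolds tibble `(marker, scaffold, scaffold_bp)` (1-based
#'   bp of the tag on the scaffold).
#' @return An object of class `scaffold_anchors`: list with `anchors`
#'   (tibble scaffold, group, n_markers, colocalized, tau, orientation) and
#'   `summary` (one-row tibble).
#' @examples
#' m <- tibble::tibble(group = 1, marker = c("m1", "m2", "m3"),
#'                     pos_cM = c(0, 5, 10))
#' sc <- tibble::tibble(marker = c("m1", "m2", "m3"), scaffold = "s1",
#'                      scaffold_bp = c(100, 5e5, 9e5))
#' anchor_scaffolds(m, sc)$summary
#' @export
anchor_scaffolds <- function(map, marker_scaffolds) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  joined <- dplyr::inner_join(tbl, marker_scaffolds, by = "marker")
  unplaced <- setdiff(tbl$marker, marker_scaffolds$marker)
  if (length(unplaced))
    warn(sprintf("%d mapped markers have no scaffold position", length(unplaced)))

  anchors <- joined %>%
    dplyr::group_split(.data$scaffold) %>%
    purrr::map_dfr(function(s) {
      counts <- sort(table(s$group), decreasing = TRUE)
      tie <- length(counts) > 1 && counts[1] == counts[2]
      modal <- if (tie) NA_integer_ else as.integer(names(counts)[1])
      on_modal <- if (tie) s[0, ] else s[s$group == modal, ]
      col <- colinearity(on_modal$scaffold_bp, on_modal$pos_cM)
      tibble::tibble(
        scaffold = s$scaffold[1],
        group = modal,
        n_markers = nrow(s),
        colocalized = !tie && length(unique(s$group)) == 1,
        tau = col$tau,
        orientation = col$orientation
      )
    })

  multi <- anchors[anchors$n_markers >= 2, ]
  summary <- tibble::tibble(
    n_scaffolds = nrow(anchors),
    n_markers_placed = sum(anchors$n_markers),
    mean_markers_per_scaffold = mean(anchors$n_markers),
    scaffolds_per_group = nrow(anchors) /
      length(unique(anchors$group[!is.na(anchors$group)])),
    colocalization_pct = 100 * sum(multi$colocalized) / max(nrow(multi), 1),
    colocalization_pct_incl_singletons =
      100 * sum(anchors$colocalized) / nrow(anchors)
  )
  structure(list(anchors = anchors, summary = summary),
            class = "scaffold_anchors")
}

#' Colinearity between scaffold bp order and map cM order
#'
#' Tie-adjusted Kendall rank correlation between the two coordinate
#' systems; `tau > 0` is `forward` orientation, `tau < 0` `reverse`, and
#' `tau = 0` (or fewer than two distinct positions) `ambiguous`.
#'
#' @param bp,cM coordinate vectors of the scaffold's markers on the
#'   scaffold and on its linkage group.
#' @return A list `(tau, orientation)`; `tau` is `NA` when undefined.
#' @examples
#' colinearity(c(1, 2, 3), c(30, 20, 10)) # tau = -1, reverse
#' @export
colinearity <- function(bp, cM) {
  if (length(bp) < 2 || length(unique(bp)) < 2 || length(unique(cM)) < 2)
    return(list(tau = NA_real_, orientation = "ambiguous"))
  tau <- stats::cor(bp, cM, method = "kendall")
  orientation <- if (is.na(tau) || tau == 0) "ambiguous"
    else if (tau > 0) "forward" else "reverse"
  list(tau = tau, orientation = orientation)
}

#' Compare two linkage maps
#'
#' Percent ratios (new over old, rounded to integer percent) for the
#' standard map-comparison metrics: marker number, map length, marker
#' density, anchored scaffold count and syntenic link count.
#'
#' @param metrics_new,metrics_old named lists or one-row data frames with
#'   any of `n_groups`, `n_markers`, `length_cM`, `density_per_cM`,
#'   `n_scaffolds`, `n_links`.
#' @return A tibble `(metric, new, old, ratio_pct)`; a zero denominator
#'   gives `NA` with a flag column.
#' @examples
#' compare_maps(list(n_markers = 2235), list(n_markers = 400))
#' @export
compare_maps <- function(metrics_new, metrics_old) {
  fields <- union(names(metrics_new), names(metrics_old))
  fields <- intersect(c("n_groups", "n_markers", "length_cM",
                        "density_per_cM", "n_scaffolds", "n_links"), fields)
  new <- vapply(fields, function(f) as.numeric(metrics_new[[f]] %||% NA), 0)
  old <- vapply(fields, function(f) as.numeric(metrics_old[[f]] %||% NA), 0)
  tibble::tibble(
    metric = fields, new = unname(new), old = unname(old),
    ratio_pct = unname(ifelse(!is.na(old) & old != 0,
                              round(100 * new / old), NA_real_)),
    undefined = unname(is.na(old) | old == 0 | is.na(new))
  )
}

#' @export
print.scaffold_anchors <- function(x, ...) {
  s <- x$summary
  cat("<scaffold_anchors> ", s$n_scaffolds, " scaffolds, ",
      round(s$mean_markers_per_scaffold, 2), " markers/scaffold, ",
      "colocalization ", round(s$colocalization_pct, 1), "%\n", sep = "")
  invisible(x)
}
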
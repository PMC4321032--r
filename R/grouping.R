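#' Assign markers to linkage groups by single-linkage clustering
#'
#' Two markers belong to the same linkage group iff they are connected by a
#' path of pairs whose independence LOD meets the threshold. Groups are
#' numbered by decreasing size, ties broken by the lexicographically
#' smallest member marker.
#'
#' @param pairs pairwise tibble from [pairwise_linkage()].
#' @param lod_threshold minimum independence LOD for an edge.
#' @param markers optional character vector of all markers (so markers with
#'   no usable pair still appear, as singleton groups).
#' @return A tibble `(marker, group)`.
#' @examples
#' # see group_markers examples in the vignette; requires a pairs table
#' @export
group_markers <- function(pairs, lod_threshold, markers = NULL) {
  if (lod_threshold <= 0) abort("`lod_threshold` must be positive")
  markers <- markers %||% sort(unique(c(pairs$marker1, pairs$marker2)))
  keep <- !is.na(pairs$ind_lod) & pairs$ind_lod >= lod_threshold
  g <- igraph::graph_from_data_frame(
    pairs[keep, c("marker1", "marker2")],
    directed = FALSE,
    vertices = data.frame(name = markers)
  )
  comp <- igraph::components(g)$membership
  partition_tibble(comp)
}

partition_tibble <- function(membership) {
  d <- tibble::tibble(marker = names(membership), comp = unname(membership))
  ord <- d %>%
    dplyr::group_by(.data$comp) %>%
    dplyr::summarise(size = dplyr::n(), lead = min(.data$marker)) %>%
    dplyr::arrange(dplyr::desc(.data$size), .data$lead) %>%
    dplyr::mutate(group = dplyr::row_number())
  d %>%
    dplyr::left_join(ord[, c("comp", "group")], by = "comp") %>%
    dplyr::select("marker", "group") %>%
    dplyr::arrange(.data$group, .data$marker)
}

#' Partitions across the full integer LOD threshold ladder
#'
#' Computes the single-linkage partition at each integer independence-LOD
#' threshold from 1 up to `max_lod` (default 50, the configured grouping
#' maximum), the ladder that the group-splitting heuristic scans.
#'
#' @inheritParams group_markers
#' @param max_lod highest threshold on the ladder.
#' @return A tibble `(lod, n_groups, partition)` where `partition` is a
#'   list-column of `(marker, group)` tibbles.
#' @export
grouping_ladder <- function(pairs, max_lod = 50, markers = NULL) {
  markers <- markers %||% sort(unique(c(pairs$marker1, pairs$marker2)))
  parts <- purrr::map(seq_len(max_lod), function(t)
    group_markers(pairs, t, markers = markers))
  tibble::tibble(
    lod = seq_len(max_lod),
    n_groups = vapply(parts, function(p) max(p$group), 0L),
    partition = parts
  )
}

#' Split one linkage group at the lowest separating LOD threshold
#'
#' Scans the integer threshold ladder upward and returns the partition at
#' the lowest threshold that separates the group into exactly two connected
#' components, each with at least `min_markers` markers. If no threshold on
#' the ladder does so, the group is returned unchanged and flagged.
#'
#' @param group character vector of the group's markers.
#' @param pairs pairwise tibble from [pairwise_linkage()].
#' @param min_markers minimum size of each resulting group.
#' @param max_lod highest threshold scanned.
#' @return A list: `groups` (list of one or two marker vectors), `split`
#'   (logical), `lod` (the splitting threshold, or `NA`).
#' @export
split_group <- function(group, pairs, min_markers, max_lod = 50) {
  sub <- pairs[pairs$marker1 %in% group & pairs$marker2 %in% group, ]
  for (t in seq_len(max_lod)) {
    part <- group_markers(sub, t, markers = group)
    sizes <- table(part$group)
    if (length(sizes) == 2 && all(sizes >= min_markers)) {
      gs <- split(part$marker, part$group)
      return(list(groups = unname(gs), split = TRUE, lod = t))
    }
    if (length(sizes) > 2) break # shattered past a clean two-way split
  }
  list(groups = list(group), split = FALSE, lod = NA_real_)
}
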
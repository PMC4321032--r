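#' Read a 12-column tabular alignment (BLAST outfmt-6 style) file
#'
#' Parses the standard 12 columns (qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore); `#`-prefixed
#' header lines are ignored. Rows with an e-value above `evalue_cutoff`
#' (default 10, the search cutoff) are dropped. A malformed row raises an
#' error naming its line number.
#'
#' @param path file path.
#' @param evalue_cutoff maximum retained e-value.
#' @return A tibble of hit records.
#' @export
read_hit_table <- function(path, evalue_cutoff = 10) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(empty_hits())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- lengths(fields) != 12
  if (any(bad))
    abort(sprintf("malformed alignment row at line %d: expected 12 fields, got %d",
                  lineno[which(bad)[1]], lengths(fields)[which(bad)[1]]))
  m <- do.call(rbind, fields)
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  out <- tibble::tibble(
    qseqid = m[, 1], sseqid = m[, 2], pident = num(3),
    length = as.integer(num(4)), mismatch = as.integer(num(5)),
    gapopen = as.integer(num(6)), qstart = as.integer(num(7)),
    qend = as.integer(num(8)), sstart = num(9), send = num(10),
    evalue = num(11), bitscore = num(12)
  )
  badnum <- which(!stats::complete.cases(out[, 3:12]))
  if (length(badnum))
    abort(sprintf("malformed alignment row at line %d: non-numeric field",
                  lineno[badnum[1]]))
  out[out$evalue <= evalue_cutoff, ]
}

#' Collapse hits to one alignment per marker-target pairing
#'
#' Both allele variants of a marker's tag share the marker id, so a marker
#' may hit one target several times; for each (marker, target) pair only the
#' lowest-e-value alignment is retained (ties broken by higher percent
#' identity, then longer alignment, then lexicographically smallest target
#' position).
#'
#' @param hits hit tibble (one or many markers).
#' @return The collapsed tibble, one row per (qseqid, sseqid).
#' @export
collapse_per_target <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits %>%
    dplyr::group_by(.data$qseqid, .data$sseqid) %>%
    dplyr::arrange(.data$evalue, dplyr::desc(.data$pident),
                   dplyr::desc(.data$length), .data$sstart,
                   .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
}

#' Per-linkage-group support sets from single-hit markers
#'
#' For every linkage group, the set of targets reported by that group's
#' markers that returned only a single (robust) hit. Markers absent from
#' the map contribute no support.
#'
#' @param collapsed collapsed hit tibble (see [collapse_per_target()]).
#' @param map a `genetic_map` or tibble `(group, marker, pos_cM)`.
#' @return A named list: linkage group -> tibble `(target, supporters)`.
#' @export
build_support_sets <- function(collapsed, map) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  singles <- collapsed %>%
    dplyr::count(.data$qseqid) %>%
    dplyr::filter(.data$n == 1) %>%
    dplyr::pull(.data$qseqid)
  sup <- collapsed %>%
    dplyr::filter(.data$qseqid %in% singles) %>%
    dplyr::inner_join(tbl[, c("group", "marker")],
                      by = c(qseqid = "marker")) %>%
    dplyr::group_by(.data$group, target = .data$sseqid) %>%
    dplyr::summarise(supporters = list(sort(.data$qseqid)), .groups = "drop")
  split(sup[, c("target", "supporters")], sup$group)
}

#' Resolve one marker's collapsed hits to a single retained location
#'
#' Implements the best-hit resolution rules. With a single hit the marker is
#' `single_robust`. With several, the top hit has the lowest e-value
#' (e-value ties broken by highest percent identity): if its target is in
#' the group's support set the marker is `top_supported`; otherwise, if any
#' other hit's target is supported, that hit is retained as
#' `not_top_supported` (lowest e-value among the supported ones); otherwise
#' the top hit is retained without support (`top_unsupported`). When no top
#' hit can be determined — e-value and identity both tied across different
#' targets and no support available — the marker is `unresolved` and
#' discarded.
#'
#' @param hits collapsed hits of one marker (>= 1 row).
#' @param support character vector of supported targets for the marker's
#'   linkage group (may be empty).
#' @return A one-row tibble `(qseqid, target, sstart, send, pos_bp, pident,
#'   evalue, category)`; `target` is `NA` for unresolved markers.
#' @export
resolve_marker <- function(hits, support = character()) {
  stopifnot(nrow(hits) >= 1)
  res <- function(row, category) tibble::tibble(
    qseqid = row$qseqid, target = row$sseqid,
    sstart = row$sstart, send = row$send,
    pos_bp = (row$sstart + row$send) / 2,
    pident = row$pident, evalue = row$evalue, category = category
  )
  if (nrow(hits) == 1) return(res(hits[1, ], "single_robust"))

  ord <- order(hits$evalue, -hits$pident, -hits$length, hits$sseqid,
               hits$sstart)
  hits <- hits[ord, ]
  top_tied <- hits$evalue == hits$evalue[1] & hits$pident == hits$pident[1]
  tied_targets <- unique(hits$sseqid[top_tied])
  supported <- hits[hits$sseqid %in% support, , drop = FALSE]

  if (length(tied_targets) == 1) {
    if (hits$sseqid[1] %in% support) return(res(hits[1, ], "top_supported"))
    if (nrow(supported) > 0) return(res(supported[1, ], "not_top_supported"))
    return(res(hits[1, ], "top_unsupported"))
  }
  # top ambiguous: fall back on support, else unresolved
  tied_sup <- intersect(tied_targets, support)
  if (length(tied_sup) >= 1) {
    pick <- hits[top_tied & hits$sseqid %in% tied_sup, , drop = FALSE]
    return(res(pick[1, ], "top_supported"))
  }
  if (nrow(supported) > 0) return(res(supported[1, ], "not_top_supported"))
  tibble::tibble(qseqid = hits$qseqid[1], target = NA_character_,
                 sstart = NA_real_, send = NA_real_, pos_bp = NA_real_,
                 pident = NA_real_, evalue = NA_real_,
                 category = "unresolved")
}

#' Resolve all markers of one route against the map
#'
#' Two-pass resolution: hits are collapsed per (marker, target), support
#' sets are built from the single-hit markers of each linkage group, then
#' every marker is resolved against its group's support set. Markers not on
#' the map receive no support (and give none).
#'
#' @param hits raw hit tibble for one route.
#' @param map a `genetic_map` or tibble `(group, marker, pos_cM)`.
#' @param route route label stored on the output.
#' @return A tibble of [resolve_marker()] rows plus `route`, `group` and
#'   `supporters` columns.
#' @export
resolve_assignments <- function(hits, map, route = "direct") {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  collapsed <- collapse_per_target(hits)
  if (nrow(collapsed) == 0) {
    return(tibble::tibble(qseqid = character(), target = character(),
                          sstart = numeric(), send = numeric(),
                          pos_bp = numeric(), pident = numeric(),
                          evalue = numeric(), category = character(),
                          route = character(), group = integer(),
                          supporters = character()))
  }
  support <- build_support_sets(collapsed, tbl)
  marker_group <- setNames(tbl$group, tbl$marker)

  out <- collapsed %>%
    dplyr::group_split(.data$qseqid) %>%
    purrr::map_dfr(function(h) {
      mk <- h$qseqid[1]
      grp <- marker_group[mk]
      sup_tbl <- if (!is.na(grp)) support[[as.character(grp)]] else NULL
      sup <- if (is.null(sup_tbl)) character() else sup_tbl$target
      r <- resolve_marker(h, sup)
      r$route <- route
      r$group <- if (is.na(grp)) NA_integer_ else as.integer(grp)
      r$supporters <- if (!is.null(sup_tbl) && !is.na(r$target) &&
                          r$target %in% sup_tbl$target) {
        sups <- setdiff(sup_tbl$supporters[[match(r$target, sup_tbl$target)]], mk)
        paste(sups, collapse = ";")
      } else ""
      r
    })
  out
}

#' Combine per-route assignments into one per marker
#'
#' Treats each route's retained hit as a candidate and re-applies the
#' resolution rules against support sets rebuilt from the combined
#' single-candidate markers. Exact ties across routes (same target, e-value
#' and identity) are broken by route priority genomic > transcriptomic >
#' direct. The winning route is recorded.
#'
#' @param route_assignments list of tibbles from [resolve_assignments()].
#' @param map a `genetic_map` or tibble `(group, marker, pos_cM)`.
#' @return A combined assignment tibble, one row per marker with a retained
#'   target.
#' @export
combine_routes <- function(route_assignments, map) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  cand <- dplyr::bind_rows(route_assignments) %>%
    dplyr::filter(!is.na(.data$target))
  if (nrow(cand) == 0) return(cand)
  route_rank <- c(genomic = 1, transcriptomic = 2, transcript = 2, direct = 3)
  cand$route_priority <- route_rank[cand$route]

  # candidate set as pseudo-hits; keep best candidate per (marker, target)
  pseudo <- cand %>%
    dplyr::transmute(.data$qseqid, sseqid = .data$target, .data$pident,
                     length = abs(.data$send - .data$sstart) + 1,
                     .data$sstart, .data$send, .data$evalue, .data$route,
                     .data$route_priority) %>%
    dplyr::group_by(.data$qseqid, .data$sseqid) %>%
    dplyr::arrange(.data$evalue, dplyr::desc(.data$pident),
                   .data$route_priority, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()

  marker_group <- setNames(tbl$group, tbl$marker)
  singles <- pseudo %>% dplyr::count(.data$qseqid) %>%
    dplyr::filter(.data$n == 1) %>% dplyr::pull(.data$qseqid)
  support <- pseudo %>%
    dplyr::filter(.data$qseqid %in% singles,
                  .data$qseqid %in% names(marker_group)) %>%
    dplyr::mutate(group = marker_group[.data$qseqid]) %>%
    dplyr::group_by(.data$group, target = .data$sseqid) %>%
    dplyr::summarise(supporters = list(sort(.data$qseqid)), .groups = "drop")
  support <- split(support[, c("target", "supporters")], support$group)

  pseudo %>%
    dplyr::group_split(.data$qseqid) %>%
    purrr::map_dfr(function(h) {
      mk <- h$qseqid[1]
      grp <- marker_group[mk]
      sup_tbl <- if (!is.na(grp)) support[[as.character(grp)]] else NULL
      sup <- if (is.null(sup_tbl)) character() else sup_tbl$target
      r <- resolve_marker(h, sup)
      r$route <- if (is.na(r$target)) NA_character_ else
        h$route[h$sseqid == r$target][1]
      r$group <- if (is.na(grp)) NA_integer_ else as.integer(grp)
      r$supporters <- if (!is.null(sup_tbl) && !is.na(r$target) &&
                          r$target %in% sup_tbl$target) {
        sups <- setdiff(sup_tbl$supporters[[match(r$target, sup_tbl$target)]], mk)
        paste(sups, collapse = ";")
      } else ""
      r
    }) %>%
    dplyr::filter(!is.na(.data$target))
}

#' Centered genomic flank around a marker tag
#'
#' Returns the 1-based inclusive interval of total width `min(width,
#' scaffold length)` centered on the 64-bp tag at `position`, clipped at the
#' scaffold ends; the interval always contains the tag.
#'
#' @param scaffold_length scaffold length, bp.
#' @param position 1-based bp position of the tag start on the scaffold.
#' @param width total flank width (default 2000 bp).
#' @param tag_length tag length (default 64 bp).
#' @return Integer vector `c(start, end)`.
#' @examples
#' extract_flank(100000, 5000) # c(4032, 6031)
#' @export
extract_flank <- function(scaffold_length, position, width = 2000,
                          tag_length = 64) {
  if (position < 1 || position > scaffold_length)
    abort("marker position lies outside the scaffold")
  width <- min(width, scaffold_length)
  pad <- width - tag_length
  start <- position - floor(pad / 2)
  end <- start + width - 1
  if (start < 1) { start <- 1; end <- width }
  if (end > scaffold_length) { end <- scaffold_length; start <- end - width + 1 }
  c(start = as.integer(start), end = as.integer(end))
}
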
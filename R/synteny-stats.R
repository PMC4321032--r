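#' Synteny link set from resolved assignments
#'
#' One link per resolved, mapped marker: its linkage-group position joined
#' to its retained target-chromosome position.
#'
#' @param assignments combined assignment tibble ([combine_routes()] or
#'   [resolve_assignments()]).
#' @param map a `genetic_map` or tibble `(group, marker, pos_cM)`.
#' @return A tibble `(marker, group, pos_cM, chrom, pos_bp, category,
#'   route)`.
#' @export
synteny_links <- function(assignments, map) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  assignments %>%
    dplyr::filter(!is.na(.data$target)) %>%
    dplyr::inner_join(tbl, by = c(qseqid = "marker")) %>%
    dplyr::transmute(marker = .data$qseqid, group = .data$group.y,
                     .data$pos_cM, chrom = .data$target, .data$pos_bp,
                     .data$category, .data$route)
}

#' Synteny summary statistics
#'
#' Per target chromosome: the number of links, the linkage groups
#' represented (flagging groups harbouring five or more links), and links
#' per megabase. Map-wide: the mean per-chromosome link count, and a pooled
#' two-sample t test comparing links/Mb between chromosomes with and
#' without a strong concentration (at least `strong_links` links on a
#' single linkage group). Also returns the Oxford-plot count matrix
#' (linkage group x chromosome).
#'
#' @param links tibble from [synteny_links()] (columns `group`, `chrom`
#'   required; `pos_cM`/`pos_bp` needed only for the Circos export).
#' @param chrom_lengths optional tibble `(chrom, length_bp)`; chromosomes
#'   without a length are excluded from per-Mb ratios with a warning.
#' @param chroms optional character vector of all target chromosomes;
#'   chromosomes with zero links then appear in the per-chromosome table
#'   and enter the mean link count (as in published comparisons).
#' @param flag_links per-group link count printed bold in study tables
#'   (default 5).
#' @param strong_links single-group concentration defining "strong" synteny
#'   (default 10).
#' @return A list: `per_chrom` tibble, `totals` (total links, mean links
#'   per chromosome, mean links/Mb), `concentration_test` (htest or NULL),
#'   `oxford` (count matrix as tibble).
#' @export
synteny_stats <- function(links, chrom_lengths = NULL, chroms = NULL,
                          flag_links = 5, strong_links = 10) {
  if (nrow(links) == 0) {
    return(list(per_chrom = tibble::tibble(), totals = tibble::tibble(
      n_links = 0L, mean_links_per_chrom = NA_real_,
      mean_links_per_mb = NA_real_), concentration_test = NULL,
      oxford = tibble::tibble()))
  }
  ox <- links %>% dplyr::count(.data$group, .data$chrom)
  per_chrom <- links %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(
      n_links = dplyr::n(),
      groups = paste(sort(unique(.data$group)), collapse = ","),
      .groups = "drop")
  strong <- ox %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(max_one_group = max(.data$n),
                     flagged_groups = paste(sort(.data$group[.data$n >= flag_links]),
                                            collapse = ","))
  per_chrom <- dplyr::left_join(per_chrom, strong, by = "chrom") %>%
    dplyr::mutate(strong = .data$max_one_group >= strong_links)
  if (!is.null(chroms)) {
    missing_chroms <- setdiff(chroms, per_chrom$chrom)
    if (length(missing_chroms)) {
      per_chrom <- dplyr::bind_rows(per_chrom, tibble::tibble(
        chrom = missing_chroms, n_links = 0L, groups = "",
        max_one_group = 0L, flagged_groups = "", strong = FALSE))
    }
  }

  if (!is.null(chrom_lengths)) {
    per_chrom <- dplyr::left_join(per_chrom, chrom_lengths, by = "chrom")
    if (anyNA(per_chrom$length_bp))
      warn(paste("no length for chromosome(s):",
                 paste(per_chrom$chrom[is.na(per_chrom$length_bp)],
                       collapse = ", ")))
    per_chrom$links_per_mb <- per_chrom$n_links / (per_chrom$length_bp / 1e6)
  } else {
    per_chrom$links_per_mb <- NA_real_
  }

  tt <- NULL
  has_mb <- !is.na(per_chrom$links_per_mb)
  if (sum(per_chrom$strong[has_mb]) >= 2 &&
      sum(!per_chrom$strong[has_mb]) >= 2) {
    tt <- stats::t.test(links_per_mb ~ strong, data = per_chrom[has_mb, ],
                        var.equal = TRUE)
  }

  totals <- tibble::tibble(
    n_links = nrow(links),
    mean_links_per_chrom = mean(per_chrom$n_links),
    mean_links_per_mb = mean(per_chrom$links_per_mb[has_mb])
  )
  list(per_chrom = per_chrom, totals = totals, concentration_test = tt,
       oxford = ox)
}

#' Write a Circos-format link file
#'
#' One line per link: `lg<group> <start> <end> <chrom> <start> <end>`, with
#' the map side in integer cM units and the target side in bp.
#'
#' @param links tibble from [synteny_links()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_circos_links <- function(links, path) {
  lines <- sprintf("lg%d %d %d %s %d %d",
                   links$group, round(links$pos_cM), round(links$pos_cM) + 1,
                   links$chrom, round(links$pos_bp),
                   round(links$pos_bp) + 1)
  writeLines(lines, path)
  invisible(path)
}

#' Route success rates
#'
#' Percentage of queried markers whose cross-genome position was identified,
#' overall and per route. Accepts either a combined assignment tibble (the
#' per-route counts are tallied from the winning routes) or a named count
#' vector.
#'
#' @param x combined assignment tibble with a `route` column (per-route
#'   counts are tallied from the winning routes and an `overall` row is
#'   added), or a named integer vector of identified-marker counts (one row
#'   per entry; route counts may overlap, so no total is added).
#' @param total_queries number of markers queried.
#' @return A tibble `(route, n_identified, pct)`; percentages rounded to
#'   one decimal as conventionally printed.
#' @examples
#' route_success_rates(c(genomic = 593, transcript = 298, direct = 26), 2235)
#' @export
route_success_rates <- function(x, total_queries) {
  if (is.data.frame(x)) {
    counts <- tapply(x$qseqid, x$route, length)
    counts <- counts[!is.na(counts)]
    counts <- c(counts, overall = sum(counts))
  } else {
    counts <- x
  }
  tibble::tibble(
    route = names(counts),
    n_identified = as.integer(counts),
    pct = round(100 * as.numeric(counts) / total_queries, 1)
  )
}
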
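#' Trim sparse distal markers from an ordered linkage group
#'
#' Iteratively removes a terminal marker whose gap to its neighbour exceeds
#' `max(min_gap_cM, gap_factor * mean intermarker distance)`, re-evaluating
#' after each removal until stable. This limits map-length inflation from
#' markers sparsely populating the distal ends of otherwise dense groups.
#'
#' @param group ordered tibble `(marker, pos_cM)` from [order_group()].
#' @param gap_factor multiple of the group's mean intermarker distance.
#' @param min_gap_cM floor on the trimming gap, cM.
#' @return The trimmed group tibble (positions re-zeroed); removed marker
#'   ids in `attr(, "removed")`.
#' @examples
#' g <- tibble::tibble(marker = c("m1", "m2", "m3", "m4"),
#'                     pos_cM = c(0, 1, 2, 42))
#' trim_distal(g)
#' @export
trim_distal <- function(group, gap_factor = 3, min_gap_cM = 10) {
  removed <- character()
  repeat {
    n <- nrow(group)
    if (n < 3) break
    gaps <- diff(group$pos_cM)
    thresh <- max(min_gap_cM, gap_factor * (group$pos_cM[n] - group$pos_cM[1]) / (n - 1))
    if (gaps[n - 1] >= gaps[1] && gaps[n - 1] > thresh) {
      removed <- c(removed, group$marker[n])
      group <- group[-n, ]
    } else if (gaps[1] > thresh) {
      removed <- c(removed, group$marker[1])
      group <- group[-1, ]
    } else break
  }
  group$pos_cM <- group$pos_cM - group$pos_cM[1]
  attr(group, "removed") <- removed
  group
}

#' Build a genetic map from coded markers
#'
#' Orchestrates the mapping protocol: single-linkage grouping on the
#' independence LOD, regression-style ordering with Kosambi distances, then
#' for a configured number of rounds: dropping small or sparse groups,
#' splitting the largest groups at the lowest separating LOD on the
#' threshold ladder, trimming sparse distal markers and re-ordering. An
#' audit log records every eliminated marker or group and the rule that
#' removed it.
#'
#' When `grouping_lod` is `NULL` the threshold is chosen automatically by
#' sweeping the integer ladder and taking the threshold that opens the
#' longest stable plateau of the count of groups with at least `min_size`
#' markers (chance linkage bridges dissolve just above the noise floor;
#' real chromosomes only fragment at much higher thresholds).
#'
#' @param qc a `marker_qc` object (its retained codes are mapped) or a
#'   genotype-code matrix as in [pairwise_linkage()].
#' @param grouping_lod independence-LOD grouping threshold, or `NULL`.
#' @param max_lod top of the grouping threshold ladder (default 50).
#' @param rounds mapping rounds (default 3).
#' @param min_size groups below this size are dropped.
#' @param max_spacing_cM groups with a larger mean intermarker distance are
#'   dropped.
#' @param split_min minimum half-size for group splitting per round
#'   (recycled over rounds; no splitting in the final round). Only groups
#'   at least 1.5 times the median group size (and at least twice
#'   `split_min`) are candidates, mirroring how fused chromosomes show up
#'   as outlier-large groups.
#' @param gap_factor,min_gap_cM distal trimming parameters, see
#'   [trim_distal()].
#' @param rf_fit_max recombination-fraction cutoff for the position fit,
#'   see [order_group()].
#' @param pairs optionally, a precomputed [pairwise_linkage()] table.
#' @return An object of class `genetic_map`: list with `map` (tibble
#'   `group`, `marker`, `pos_cM`), `audit` (round-by-round eliminations),
#'   `grouping_lod`, and `pairs`.
#' @examples
#' sim <- simulate_cross(sim_config(n_chromosomes = 2,
#'                                  markers_per_chromosome = 12, n_f2 = 100,
#'                                  frac_parentNA = 0, frac_monomorphic = 0,
#'                                  frac_distorted = 0, trait_locus = NULL,
#'                                  seed = 11))
#' qc <- screen_markers(sim$genotypes)
#' gm <- build_map(qc, min_size = 5)
#' map_summary(gm)
#' @export
build_map <- function(qc, grouping_lod = NULL, max_lod = 50, rounds = 3,
                      min_size = 10, max_spacing_cM = 4,
                      split_min = c(20, 10), gap_factor = 3, min_gap_cM = 10,
                      rf_fit_max = 0.2, pairs = NULL) {
  codes <- if (inherits(qc, "marker_qc")) qc$codes else qc
  stopifnot(is.matrix(codes))
  all_markers <- rownames(codes)
  pairs <- pairs %||% pairwise_linkage(codes)

  if (is.null(grouping_lod)) {
    grouping_lod <- auto_grouping_lod(pairs, all_markers, min_size, max_lod)
  }
  part <- group_markers(pairs, grouping_lod, markers = all_markers)
  groups <- split(part$marker, part$group)

  audit <- list()
  log_audit <- function(round, action, detail, markers) {
    audit[[length(audit) + 1]] <<- tibble::tibble(
      round = round, action = action, detail = detail,
      n_markers = length(markers), markers = paste(markers, collapse = ";"))
  }

  ordered <- unname(purrr::map(groups, order_group, pairs = pairs,
                               rf_fit_max = rf_fit_max))
  split_min <- rep_len(split_min, max(1, rounds - 1))

  for (k in seq_len(rounds)) {
    # drop small or sparse groups
    keep <- vapply(ordered, function(g) {
      n <- nrow(g)
      if (n < min_size) return(FALSE)
      mean_gap <- g$pos_cM[n] / (n - 1)
      mean_gap <= max_spacing_cM
    }, TRUE)
    for (i in which(!keep)) {
      log_audit(k, "drop_group",
                sprintf("size %d or mean spacing above %.1f cM",
                        nrow(ordered[[i]]), max_spacing_cM),
                ordered[[i]]$marker)
    }
    ordered <- ordered[keep]
    if (length(ordered) == 0) abort("no linkage groups survived the protocol")

    # split anomalously large groups (suspected fusions) at the lowest
    # separating threshold; typical-size groups are left intact
    if (k < rounds) {
      smin <- split_min[k]
      sizes <- vapply(ordered, nrow, 0L)
      big <- max(2 * smin, ceiling(1.5 * stats::median(sizes)))
      for (i in order(-sizes)) {
        if (sizes[i] < big) next
        sp <- split_group(ordered[[i]]$marker, pairs, smin, max_lod)
        if (sp$split) {
          log_audit(k, "split_group",
                    sprintf("split at independence LOD %d", sp$lod),
                    ordered[[i]]$marker)
          ordered[[i]] <- order_group(sp$groups[[1]], pairs, rf_fit_max)
          ordered[[length(ordered) + 1]] <-
            order_group(sp$groups[[2]], pairs, rf_fit_max)
        }
      }
    }

    # trim sparse distal markers and refresh positions
    ordered <- purrr::imap(ordered, function(g, i) {
      t <- trim_distal(g, gap_factor, min_gap_cM)
      if (length(attr(t, "removed")))
        log_audit(k, "trim_marker", "distal gap above threshold",
                  attr(t, "removed"))
      if (nrow(t) < nrow(g)) order_group(t$marker, pairs, rf_fit_max) else t
    })
  }

  # canonical group numbering: by size, then lead marker
  lead <- vapply(ordered, function(g) min(g$marker), "")
  sizes <- vapply(ordered, nrow, 0L)
  ordered <- unname(ordered[order(-sizes, lead)])
  map <- dplyr::bind_rows(purrr::map2(ordered, seq_along(ordered),
    function(g, i) dplyr::mutate(g, group = i, .before = 1)))

  placed <- map$marker
  dropped <- unlist(purrr::map(audit, ~ strsplit(.x$markers, ";")[[1]]))
  unplaced <- setdiff(all_markers, c(placed, dropped))
  if (length(unplaced))
    log_audit(rounds, "unplaced", "never entered a surviving group", unplaced)

  structure(list(map = map,
                 audit = dplyr::bind_rows(audit),
                 grouping_lod = grouping_lod,
                 pairs = pairs),
            class = "genetic_map")
}

# Sweep the integer ladder and pick the threshold opening the longest
# stable plateau of the count of groups with >= min_size markers: chance
# linkage bridges dissolve just above the noise floor, while real
# chromosomes only start to fragment at much higher thresholds, so the
# chromosome-level partition shows up as the widest plateau.
auto_grouping_lod <- function(pairs, markers, min_size, max_lod) {
  n_big <- vapply(seq_len(max_lod), function(t) {
    part <- group_markers(pairs, t, markers = markers)
    sum(table(part$group) >= min_size)
  }, 0L)
  runs <- rle(n_big)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pick <- which.max(runs$lengths) # ties resolve to the lowest threshold
  as.integer(starts[pick])
}

#' Summarise a genetic map
#'
#' Per-group marker counts, lengths and mean intermarker distances
#' (`length / (n - 1)`), plus map totals: total markers, total length,
#' marker density (markers per cM), the map-wide mean intermarker distance
#' `total length / (markers - groups)`, and the mean of the per-group mean
#' intermarker distances (both candidate definitions are reported).
#'
#' @param map a `genetic_map` or a tibble `(group, marker, pos_cM)`.
#' @return A list with `groups` (per-group tibble) and `totals`
#'   (one-row tibble).
#' @examples
#' m <- tibble::tibble(group = 1, marker = c("a", "b", "c"),
#'                     pos_cM = c(0, 5, 10))
#' map_summary(m)$totals
#' @export
map_summary <- function(map) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  groups <- tbl %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      n_markers = dplyr::n(),
      length_cM = max(.data$pos_cM) - min(.data$pos_cM),
      mean_intermarker_cM = ifelse(dplyr::n() > 1,
                                   .data$length_cM / (dplyr::n() - 1), NA_real_)
    )
  totals <- tibble::tibble(
    n_groups = nrow(groups),
    n_markers = sum(groups$n_markers),
    length_cM = sum(groups$length_cM),
    density_per_cM = sum(groups$n_markers) / sum(groups$length_cM),
    mean_intermarker_cM = sum(groups$length_cM) /
      (sum(groups$n_markers) - nrow(groups)),
    mean_of_group_means_cM = mean(groups$mean_intermarker_cM, na.rm = TRUE)
  )
  list(groups = groups, totals = totals)
}

#' @export
print.genetic_map <- function(x, ...) {
  s <- map_summary(x)
  cat("<genetic_map> ", s$totals$n_markers, " markers in ",
      s$totals$n_groups, " linkage groups, ",
      round(s$totals$length_cM, 1), " cM (density ",
      round(s$totals$density_per_cM, 2), "/cM)\n", sep = "")
  invisible(x)
}
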
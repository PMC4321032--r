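# broom-style tidiers for the fitted objects

#' @export
tidy.genetic_map <- function(x, ...) x$map

#' @export
glance.genetic_map <- function(x, ...) map_summary(x)$totals

#' @export
tidy.marker_qc <- function(x, ...) x$markers

#' @export
glance.marker_qc <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_input = r$remaining[1],
    n_unsuitable = r$removed[r$stage == "parental_screen"],
    n_uninformative = r$removed[r$stage == "uninformative_filter"],
    n_distorted = r$removed[r$stage == "distortion_filter"],
    n_retained = r$remaining[nrow(r)]
  )
}

#' @export
tidy.scan_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.scan_result <- function(x, ...) {
  attr(x, "peaks") %>%
    dplyr::select("method", peak_group = "group", peak_pos_cM = "pos_cM",
                  peak_marker = "marker", peak_lod = "lod")
}

#' @export
tidy.scaffold_anchors <- function(x, ...) x$anchors

#' @export
glance.scaffold_anchors <- function(x, ...) x$summary

#' @export
tidy.gbs_sim <- function(x, ...) x$truth$map

#' @export
glance.gbs_sim <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$truth$map),
    n_chromosomes = x$config$n_chromosomes,
    n_f2 = x$config$n_f2,
    n_scaffolds = nrow(x$truth$scaffolds)
  )
}
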
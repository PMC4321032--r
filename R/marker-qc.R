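#' Parental consensus call for one founder panel
#'
#' Assigns a founder nucleotide by consensus: the nucleotide carried by at
#' least three of the four panel individuals (missing calls count as
#' non-matching), otherwise `NA`. IUPAC heterozygote codes never form a
#' parental consensus. For non-default panel sizes the threshold generalises
#' to `ceiling(3 n / 4)`.
#'
#' @param calls character vector of IUPAC genotype calls from one founder
#'   panel (`NA` = missing).
#' @param panel_size expected panel size (default 4); a different input
#'   length is an error.
#' @return A single nucleotide, or `NA_character_` when no consensus exists.
#' @examples
#' assign_parental_consensus(c("A", "A", "A", "G")) # "A"
#' assign_parental_consensus(c("A", "A", "G", "G")) # NA
#' @export
assign_parental_consensus <- function(calls, panel_size = 4) {
  if (length(calls) != panel_size)
    abort(sprintf("expected %d panel calls, got %d", panel_size, length(calls)))
  need <- ceiling(3 * panel_size / 4)
  tab <- table(calls[calls %in% .nucleotides])
  hit <- names(tab)[tab >= need]
  if (length(hit) == 1) hit else NA_character_
}

#' Heterozygote consensus for the F1 panel
#'
#' Returns the IUPAC heterozygote code shared by at least three of the four
#' F1 individuals, confirming the hybrid state of a marker; `NA` when no
#' heterozygous consensus exists (including an all-homozygous panel).
#'
#' @inheritParams assign_parental_consensus
#' @return A single IUPAC heterozygote code, or `NA_character_`.
#' @examples
#' assign_f1_heterozygote(c("R", "R", "R", "A")) # "R"
#' @export
assign_f1_heterozygote <- function(calls, panel_size = 4) {
  if (length(calls) != panel_size)
    abort(sprintf("expected %d panel calls, got %d", panel_size, length(calls)))
  need <- ceiling(3 * panel_size / 4)
  tab <- table(calls[is_het_code(calls)])
  hit <- names(tab)[tab >= need]
  if (length(hit) == 1) hit else NA_character_
}

#' Pearson chi-square against the 1:2:1 F2 segregation ratio
#'
#' @param n_a,n_h,n_b counts of the surface-homozygous, heterozygous and
#'   cave-homozygous F2 classes (missing calls excluded).
#' @return The chi-square statistic (2 df).
#' @examples
#' chisq_segregation(50, 100, 50) # 0
#' chisq_segregation(170, 0, 0)   # 510
#' @export
chisq_segregation <- function(n_a, n_h, n_b) {
  if (any(c(n_a, n_h, n_b) < 0)) abort("class counts must be >= 0")
  n <- n_a + n_h + n_b
  if (any(n < 1)) abort("chi-square undefined with no scored individuals")
  e <- cbind(n / 4, n / 2, n / 4)
  o <- cbind(n_a, n_h, n_b)
  unname(rowSums((o - e)^2 / e))
}

#' Screen and code GBS markers for linkage mapping
#'
#' Applies the marker-selection rules in order: (1) markers with neither
#' parental genotype assignable, or with identical assigned parental
#' genotypes, are discarded as unsuitable; (2) uninformative markers (a
#' single genotype class across all scored F2 individuals) are discarded;
#' (3) markers whose F2 class counts depart from 1:2:1 with a chi-square
#' above `chi2_cutoff` are discarded as distorted. Surviving markers are
#' coded per F2 individual as `a` (homozygous surface), `h` (heterozygous)
#' or `b` (homozygous cave); calls inconsistent with the two assigned
#' alleles are set missing and counted.
#'
#' F1 confirmation is advisory: markers whose F1 heterozygote consensus is
#' missing or inconsistent with the assigned allele pair are flagged
#' (`f1_confirmed = FALSE`) but only discarded under `require_f1 = TRUE`.
#'
#' @param genotypes genotype tibble as produced by [simulate_cross()] (or
#'   read with [read_genotypes()]): column `marker`, then one call column
#'   per individual, with founder columns prefixed `S`/`C`, F1 columns
#'   `F1_`, and F2 columns `F2_`.
#' @param chi2_cutoff segregation-distortion threshold (default 50).
#' @param panel_size founder/F1 panel size (default 4).
#' @param require_f1 discard markers lacking F1 confirmation.
#' @return An object of class `marker_qc`: list with
#'   * `markers`: tibble (marker, surface_allele, cave_allele, n_a, n_h,
#'     n_b, n_missing, n_inconsistent, chi2, f1_confirmed, status);
#'   * `codes`: character matrix (retained markers x F2 individuals) over
#'     `"a"/"h"/"b"/NA`;
#'   * `report`: telescoping stage-count tibble (see [qc_report()]).
#' @examples
#' sim <- simulate_cross(sim_config(n_chromosomes = 2,
#'                                  markers_per_chromosome = 10,
#'                                  n_f2 = 30, trait_locus = NULL, seed = 5))
#' qc <- screen_markers(sim$genotypes)
#' qc$report
#' @export
screen_markers <- function(genotypes, chi2_cutoff = 50, panel_size = 4,
                           require_f1 = FALSE) {
  stopifnot(is.data.frame(genotypes), names(genotypes)[1] == "marker")
  ind <- names(genotypes)[-1]
  sur_cols <- grep("^S[0-9]+$", ind, value = TRUE)
  cav_cols <- grep("^C[0-9]+$", ind, value = TRUE)
  f1_cols <- grep("^F1_", ind, value = TRUE)
  f2_cols <- grep("^F2_", ind, value = TRUE)
  if (length(sur_cols) != panel_size || length(cav_cols) != panel_size)
    abort("founder panels do not match `panel_size`")
  if (length(f2_cols) == 0) abort("no F2 individuals found")

  calls <- as.matrix(genotypes[, -1])
  rownames(calls) <- genotypes$marker
  bad <- !is.na(calls) & !(calls %in% .call_alphabet)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("illegal genotype symbol '%s' at marker %s, individual %s",
                  calls[w[1], w[2]], rownames(calls)[w[1]], colnames(calls)[w[2]]))
  }

  n_mark <- nrow(calls)
  sur <- apply(calls[, sur_cols, drop = FALSE], 1, assign_parental_consensus,
               panel_size = panel_size)
  cav <- apply(calls[, cav_cols, drop = FALSE], 1, assign_parental_consensus,
               panel_size = panel_size)
  f1 <- apply(calls[, f1_cols, drop = FALSE], 1, assign_f1_heterozygote,
              panel_size = panel_size)

  het <- ifelse(!is.na(sur) & !is.na(cav) & sur != cav, het_code_safe(sur, cav),
                NA_character_)
  f1_ok <- !is.na(f1) & !is.na(het) & f1 == het

  f2 <- calls[, f2_cols, drop = FALSE]
  codes <- matrix(NA_character_, n_mark, length(f2_cols),
                  dimnames = list(rownames(calls), f2_cols))
  has_pair <- !is.na(het)
  sur_m <- matrix(sur, n_mark, length(f2_cols))
  cav_m <- matrix(cav, n_mark, length(f2_cols))
  het_m <- matrix(het, n_mark, length(f2_cols))
  codes[has_pair & !is.na(f2) & f2 == sur_m] <- "a"
  codes[has_pair & !is.na(f2) & f2 == het_m] <- "h"
  codes[has_pair & !is.na(f2) & f2 == cav_m] <- "b"

  n_a <- rowSums(codes == "a", na.rm = TRUE)
  n_h <- rowSums(codes == "h", na.rm = TRUE)
  n_b <- rowSums(codes == "b", na.rm = TRUE)
  n_raw_missing <- rowSums(is.na(f2))
  n_inconsistent <- rowSums(is.na(codes)) - n_raw_missing
  n_scored <- n_a + n_h + n_b
  n_classes <- (n_a > 0) + (n_h > 0) + (n_b > 0)
  chi2 <- ifelse(n_scored > 0,
                 (n_a - n_scored / 4)^2 / (n_scored / 4) +
                   (n_h - n_scored / 2)^2 / (n_scored / 2) +
                   (n_b - n_scored / 4)^2 / (n_scored / 4),
                 NA_real_)

  # statuses in screening order
  status <- rep("retained", n_mark)
  status[!is.na(sur) & !is.na(cav) & sur == cav] <- "discarded_identical_parents"
  status[is.na(sur) & is.na(cav)] <- "discarded_no_parent"
  # one assigned parent but no allele pair: cannot code the cross, treat as
  # unassignable (the screening rule requires both genotypes)
  status[status == "retained" & !has_pair] <- "discarded_no_parent"
  suitable <- status == "retained"
  status[suitable & n_classes <= 1] <- "discarded_uninformative"
  screened <- status == "retained"
  status[screened & chi2 > chi2_cutoff] <- "discarded_distorted"
  if (require_f1) status[status == "retained" & !f1_ok] <- "discarded_no_f1"

  markers <- tibble::tibble(
    marker = rownames(calls),
    surface_allele = unname(sur), cave_allele = unname(cav),
    n_a = unname(n_a), n_h = unname(n_h), n_b = unname(n_b),
    n_missing = unname(n_raw_missing),
    n_inconsistent = unname(n_inconsistent),
    chi2 = unname(chi2), f1_confirmed = unname(f1_ok),
    status = status
  )

  report <- qc_report(
    total = n_mark,
    unsuitable = sum(status %in% c("discarded_no_parent",
                                   "discarded_identical_parents")),
    uninformative = sum(status == "discarded_uninformative"),
    distorted = sum(status == "discarded_distorted"),
    other = sum(status == "discarded_no_f1")
  )

  structure(list(markers = markers,
                 codes = codes[status == "retained", , drop = FALSE],
                 report = report),
            class = "marker_qc")
}

het_code_safe <- function(a1, a2) {
  out <- rep(NA_character_, length(a1))
  ok <- !is.na(a1) & !is.na(a2) & a1 != a2 &
    a1 %in% .nucleotides & a2 %in% .nucleotides
  if (any(ok)) out[ok] <- het_code(a1[ok], a2[ok])
  out
}

#' Telescoping marker-screening bookkeeping
#'
#' Builds the stage-count chain of the marker screen: markers suitable after
#' the parental screen, the screened set after removing uninformative
#' markers, and the final retained set after the segregation-distortion
#' filter. Each stage equals the previous stage minus its removals; the
#' identity is checked.
#'
#' @param total markers entering the screen.
#' @param unsuitable removed because no/identical parental genotypes.
#' @param uninformative removed because a single F2 genotype class.
#' @param distorted removed by the chi-square filter.
#' @param other removed by optional extra rules (e.g. strict F1 mode).
#' @return A tibble (stage, removed, remaining).
#' @examples
#' qc_report(total = 7956, unsuitable = 1950, uninformative = 107,
#'           distorted = 2896)
#' @export
qc_report <- function(total, unsuitable = 0, uninformative = 0,
                      distorted = 0, other = 0) {
  suitable <- total - unsuitable
  screened <- suitable - uninformative
  after_chi <- screened - distorted
  retained <- after_chi - other
  if (retained < 0) abort("stage removals exceed the available markers")
  tibble::tibble(
    stage = c("input", "parental_screen", "uninformative_filter",
              "distortion_filter", if (other > 0) "f1_filter",
              "retained"),
    removed = c(0, unsuitable, uninformative, distorted,
                if (other > 0) other, 0),
    remaining = c(total, suitable, screened, after_chi,
                  if (other > 0) retained, retained)
  )
}

#' @export
print.marker_qc <- function(x, ...) {
  r <- x$report
  cat("<marker_qc> ", r$remaining[1], " markers in, ",
      r$remaining[nrow(r)], " retained\n", sep = "")
  print(r)
  invisible(x)
}
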
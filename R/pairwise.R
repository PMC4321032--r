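# Two-point statistics for an F2 intercross with codominant markers.
#
# The EM estimator works on the 9-cell joint genotype table. Every cell
# carries a known number of recombinant gametes except the double
# heterozygote, which mixes the two phase classes; its E-step weight is
# r^2 / (r^2 + (1-r)^2). All computations below are vectorised over pairs,
# so the full marker-by-marker scan is nine cross-products plus an
# elementwise EM loop.

# expected log-likelihood pieces: cell probabilities for coupling-phase F2
.ll_cells <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22, r) {
  p <- r; q <- 1 - r
  term <- function(n, pr) ifelse(n > 0, n * log(pr), 0)
  term(n00 + n22, q^2 / 4) + term(n02 + n20, p^2 / 4) +
    term(n01 + n10 + n12 + n21, p * q / 2) + term(n11, (p^2 + q^2) / 2)
}

# vectorised EM over pair count vectors; returns list(rf, lod)
em_rf_core <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                       tol = 1e-8, max_iter = 200, r_init = 0.25) {
  n_tot <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  r_det <- n01 + n10 + n12 + n21 + 2 * (n02 + n20)
  r <- rep(r_init, length(n_tot))
  ok <- n_tot > 0
  if (any(ok)) {
    for (it in seq_len(max_iter)) {
      w <- 2 * r^2 / (r^2 + (1 - r)^2)
      r_new <- ifelse(ok, (r_det + n11 * w) / (2 * n_tot), NA_real_)
      r_new <- pmin(pmax(r_new, 0), 0.5)
      if (max(abs(r_new - r)[ok]) < tol) { r <- r_new; break }
      r <- r_new
    }
  } else r <- rep(NA_real_, length(n_tot))
  ll_hat <- .ll_cells(n00, n01, n02, n10, n11, n12, n20, n21, n22,
                      pmin(r, 0.5 - 1e-12))
  ll_null <- .ll_cells(n00, n01, n02, n10, n11, n12, n20, n21, n22, 0.5)
  lod <- pmax((ll_hat - ll_null) / log(10), 0)
  list(rf = r, lod = lod)
}

# G-squared independence statistic on the 3x3 table, as a LOD
ind_lod_core <- function(n00, n01, n02, n10, n11, n12, n20, n21, n22) {
  n <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  r0 <- n00 + n01 + n02; r1 <- n10 + n11 + n12; r2 <- n20 + n21 + n22
  c0 <- n00 + n10 + n20; c1 <- n01 + n11 + n21; c2 <- n02 + n12 + n22
  g <- function(nij, ri, cj) ifelse(nij > 0, nij * log(nij * n / (ri * cj)), 0)
  g2 <- 2 * (g(n00, r0, c0) + g(n01, r0, c1) + g(n02, r0, c2) +
               g(n10, r1, c0) + g(n11, r1, c1) + g(n12, r1, c2) +
               g(n20, r2, c0) + g(n21, r2, c1) + g(n22, r2, c2))
  pmax(g2, 0) / (2 * log(10))
}

#' All pairwise two-point linkage statistics
#'
#' For every marker pair, estimates the recombination fraction by EM over
#' the 9-cell joint genotype table, the linkage LOD
#' (\eqn{\log_{10} L(\hat r) - \log_{10} L(0.5)}), and the independence LOD
#' (the G-squared statistic of the 3x3 independence test divided by
#' \eqn{2 \ln 10}), which is robust to segregation distortion and is the
#' grouping statistic. Individuals missing either call are dropped per pair;
#' pairs with fewer than `min_n` complete individuals get `NA` estimates and
#' are excluded from grouping.
#'
#' @param codes character matrix (markers x F2 individuals) of
#'   `"a"/"h"/"b"/NA` genotype codes, e.g. `screen_markers()$codes`.
#' @param min_n minimum complete individuals per pair (default 2).
#' @return A tibble with one row per unordered pair: `marker1`, `marker2`,
#'   `n`, `rf`, `lod`, `ind_lod`.
#' @examples
#' sim <- simulate_cross(sim_config(n_chromosomes = 2,
#'                                  markers_per_chromosome = 5,
#'                                  n_f2 = 50, trait_locus = NULL, seed = 7))
#' qc <- screen_markers(sim$genotypes)
#' pl <- pairwise_linkage(qc$codes)
#' @export
pairwise_linkage <- function(codes, min_n = 2) {
  stopifnot(is.matrix(codes), nrow(codes) >= 2)
  m <- nrow(codes)
  A <- t(!is.na(codes) & codes == "a") * 1
  H <- t(!is.na(codes) & codes == "h") * 1
  B <- t(!is.na(codes) & codes == "b") * 1
  N <- list(
    crossprod(A, A), crossprod(A, H), crossprod(A, B),
    crossprod(H, A), crossprod(H, H), crossprod(H, B),
    crossprod(B, A), crossprod(B, H), crossprod(B, B)
  )
  ut <- upper.tri(N[[1]])
  cells <- lapply(N, function(x) x[ut])
  idx <- which(ut, arr.ind = TRUE)
  n_tot <- Reduce(`+`, cells)

  em <- em_rf_core(cells[[1]], cells[[2]], cells[[3]], cells[[4]],
                   cells[[5]], cells[[6]], cells[[7]], cells[[8]], cells[[9]])
  il <- ind_lod_core(cells[[1]], cells[[2]], cells[[3]], cells[[4]],
                     cells[[5]], cells[[6]], cells[[7]], cells[[8]], cells[[9]])
  ok <- n_tot >= min_n
  tibble::tibble(
    marker1 = rownames(codes)[idx[, 1]],
    marker2 = rownames(codes)[idx[, 2]],
    n = as.integer(n_tot),
    rf = ifelse(ok, em$rf, NA_real_),
    lod = ifelse(ok, em$lod, NA_real_),
    ind_lod = ifelse(ok, il, NA_real_)
  )
}

#' Two-point EM estimate for a single marker pair
#'
#' @param codes_i,codes_j genotype code vectors (`"a"/"h"/"b"/NA`) over the
#'   same F2 individuals.
#' @param marker_ids length-2 character vector naming the pair.
#' @return A one-row tibble as in [pairwise_linkage()].
#' @examples
#' x <- c("a", "h", "h", "b", "a")
#' estimate_rf_em(x, x)
#' @export
estimate_rf_em <- function(codes_i, codes_j, marker_ids = c("m1", "m2")) {
  stopifnot(length(codes_i) == length(codes_j))
  keep <- !is.na(codes_i) & !is.na(codes_j)
  lev <- c("a", "h", "b")
  tab <- table(factor(codes_i[keep], lev), factor(codes_j[keep], lev))
  rf_from_table(tab, marker_ids)
}

# shared scalar path used by the grid-search cross-checks and single pairs
rf_from_table <- function(tab, marker_ids = c("m1", "m2")) {
  n <- as.numeric(t(tab)) # row-major: n00, n01, ..., n22
  args <- as.list(n)
  em <- do.call(em_rf_core, args)
  il <- do.call(ind_lod_core, args)
  n_tot <- sum(n)
  ok <- n_tot >= 2
  tibble::tibble(
    marker1 = marker_ids[1], marker2 = marker_ids[2],
    n = as.integer(n_tot),
    rf = if (ok) em$rf else NA_real_,
    lod = if (ok) em$lod else NA_real_,
    ind_lod = if (ok) il else NA_real_
  )
}
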
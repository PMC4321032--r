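# Regression-style marker ordering.
#
# Orders one linkage group by incremental insertion: seed with the
# most-informative pair, then repeatedly insert the unplaced marker with the
# strongest linkage to the current order at the position minimising the
# weighted least-squares criterion
#     sum_ij w_ij (d_ij(order) - kosambi_cM(rf_ij))^2,  w_ij = linkage LOD,
# where d_ij(order) comes from cumulative adjacent Kosambi distances. Each
# insertion is followed by a local width-3 permutation polish around the
# insertion point, and the finished order by full polish passes until no
# window improves. Final cM positions are re-fitted by weighted least
# squares over all pairs with rf below a cutoff (non-negative gaps).
# The orientation of a group is arbitrary; orders are canonicalised with the
# lexicographically smaller terminal marker first.

#' Order the markers of one linkage group and assign cM positions
#'
#' @param markers character vector of the group's markers.
#' @param pairs pairwise tibble from [pairwise_linkage()] (superset allowed).
#' @param rf_fit_max pairs with `rf` below this enter the final
#'   weighted-least-squares position fit (default 0.2; longer-range pairs
#'   span many intervals, where two-point Kosambi distances are
#'   systematically sub-additive and would shrink the map).
#' @return A tibble `(marker, pos_cM)` ordered along the group, positions
#'   starting at 0.
#' @examples
#' # three markers with rf (m1,m2)=0.1, (m2,m3)=0.1, (m1,m3)=0.18
#' pl <- tibble::tibble(marker1 = c("m1", "m2", "m1"),
#'                      marker2 = c("m2", "m3", "m3"),
#'                      n = 100, rf = c(0.1, 0.1, 0.18), lod = c(10, 10, 6),
#'                      ind_lod = c(10, 10, 6))
#' order_group(c("m1", "m2", "m3"), pl)
#' @export
order_group <- function(markers, pairs, rf_fit_max = 0.2) {
  markers <- sort(unique(markers))
  m <- length(markers)
  if (m == 1) return(tibble::tibble(marker = markers, pos_cM = 0))

  sub <- pairs[pairs$marker1 %in% markers & pairs$marker2 %in% markers, ]
  i1 <- match(sub$marker1, markers)
  i2 <- match(sub$marker2, markers)
  D <- matrix(kosambi_cM(0.4999, cap = TRUE), m, m)
  W <- matrix(0, m, m)
  R <- matrix(NA_real_, m, m)
  okp <- !is.na(sub$rf)
  d_val <- kosambi_cM(pmin(sub$rf[okp], 0.4999), cap = TRUE)
  D[cbind(i1, i2)[okp, , drop = FALSE]] <- d_val
  D[cbind(i2, i1)[okp, , drop = FALSE]] <- d_val
  W[cbind(i1, i2)[okp, , drop = FALSE]] <- sub$lod[okp]
  W[cbind(i2, i1)[okp, , drop = FALSE]] <- sub$lod[okp]
  R[cbind(i1, i2)[okp, , drop = FALSE]] <- sub$rf[okp]
  R[cbind(i2, i1)[okp, , drop = FALSE]] <- sub$rf[okp]
  diag(D) <- 0; diag(W) <- 0

  # upper-triangle pair vectors for the objective
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  # objective over the currently placed markers (the full order, once complete)
  obj_placed <- function(ord) {
    pos_ord <- c(0, cumsum(D[cbind(ord[-length(ord)], ord[-1])]))
    pos <- numeric(m); pos[ord] <- pos_ord
    sel <- ut[, 1] %in% ord & ut[, 2] %in% ord
    sum(W[ut[sel, , drop = FALSE]] *
          (abs(pos[ut[sel, 1]] - pos[ut[sel, 2]]) - D[ut[sel, , drop = FALSE]])^2)
  }

  # seed with the most informative pair (max linkage LOD, tie -> lexicographic)
  Wseed <- W; Wseed[lower.tri(Wseed, diag = TRUE)] <- -Inf
  best <- which(Wseed == max(Wseed), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  ord <- as.integer(best)
  placed <- logical(m); placed[ord] <- TRUE

  while (!all(placed)) {
    cand <- which(!placed)
    strength <- vapply(cand, function(k) max(W[k, placed]), 0)
    k <- cand[order(-strength, cand)][1]
    len <- length(ord)
    scores <- vapply(0:len, function(p)
      obj_placed(append(ord, k, after = p)), 0)
    p <- which.min(scores) - 1L
    ord <- append(ord, k, after = p)
    placed[k] <- TRUE
    ord <- polish_windows(ord, obj_placed,
                          from = max(1, p - 1), to = min(length(ord) - 2, p + 2))
  }

  # full polish passes until stable
  repeat {
    new_ord <- polish_windows(ord, obj_placed)
    if (identical(new_ord, ord)) break
    ord <- new_ord
  }

  pos <- fit_positions(ord, D, W, R, rf_fit_max)

  # canonical orientation: lexicographically smaller terminal marker first
  if (markers[ord[1]] > markers[ord[length(ord)]]) {
    ord <- rev(ord)
    pos <- max(pos) - rev(pos)
  }
  tibble::tibble(marker = markers[ord], pos_cM = unname(pos - pos[1]))
}

# sliding width-3 window permutations; accepts strict improvements
polish_windows <- function(ord, objective, from = 1, to = length(ord) - 2) {
  if (length(ord) < 3 || to < from) return(ord)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  cur <- objective(ord)
  for (w in from:to) {
    win <- ord[w:(w + 2)]
    for (p in perms[-1]) {
      trial <- ord
      trial[w:(w + 2)] <- win[p]
      sc <- objective(trial)
      if (sc < cur - 1e-12) { ord <- trial; cur <- sc }
    }
  }
  ord
}

# weighted least-squares fit of inter-marker gaps over pairs with rf below
# the cutoff; gaps clamped non-negative, uncovered gaps fall back to the
# adjacent two-point distance
fit_positions <- function(ord, D, W, R, rf_fit_max) {
  m <- length(ord)
  adj_d <- D[cbind(ord[-m], ord[-1])]
  if (m == 2) return(c(0, adj_d))
  pos_rank <- match(seq_len(m), ord) # marker index -> rank in order
  ut <- which(upper.tri(W) & W > 0 & !is.na(R) & R < rf_fit_max,
              arr.ind = TRUE)
  if (nrow(ut) == 0) return(c(0, cumsum(adj_d)))
  r1 <- pmin(pos_rank[ut[, 1]], pos_rank[ut[, 2]])
  r2 <- pmax(pos_rank[ut[, 1]], pos_rank[ut[, 2]])
  X <- matrix(0, nrow(ut), m - 1)
  for (k in seq_len(nrow(ut))) X[k, r1[k]:(r2[k] - 1)] <- 1
  fit <- stats::lm.wfit(X, D[ut], W[ut])
  gaps <- fit$coefficients
  gaps[is.na(gaps)] <- adj_d[is.na(gaps)]
  gaps <- pmax(gaps, 0)
  c(0, cumsum(gaps))
}
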
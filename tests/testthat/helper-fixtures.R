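# shared fixtures and independent oracles used across test files

# small clean cross reused by several tests (no artifacts, no noise)
clean_sim <- function(seed = 7, n_chr = 2, m = 10, n_f2 = 60, len = 50,
                      trait = NULL, missing_rate = 0, error_rate = 0, ...) {
  simulate_cross(sim_config(
    n_chromosomes = n_chr, markers_per_chromosome = m, chrom_length_cM = len,
    n_f2 = n_f2, missing_rate = missing_rate, error_rate = error_rate,
    frac_monomorphic = 0, frac_parentNA = 0, frac_distorted = 0,
    trait_locus = trait, seed = seed, ...))
}

# adjusted Rand index from a contingency table (independent of any package)
adjusted_rand <- function(tab) {
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  sn <- choose(n, 2)
  (si - sa * sb / sn) / ((sa + sb) / 2 - sa * sb / sn)
}

# brute-force likelihood grid search for the F2 two-point model; the
# independent oracle for the EM estimator
grid_search_rf <- function(tab, step = 1e-4) {
  r <- seq(0, 0.5, by = step)
  p <- r; q <- 1 - r
  probs <- rbind(
    q^2 / 4, p * q / 2, p^2 / 4,
    p * q / 2, (p^2 + q^2) / 2, p * q / 2,
    p^2 / 4, p * q / 2, q^2 / 4
  )
  n <- as.numeric(t(tab)) # row-major 9-cell counts
  lp <- log(probs)
  lp[!is.finite(lp)] <- -1e10
  ll <- as.numeric(n %*% lp)
  r[which.max(ll)]
}

# random 9-cell tables drawn around plausible two-point configurations
random_tables <- function(n_tables, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n_tables), function(i) {
      r <- runif(1, 0.01, 0.49)
      p <- r; q <- 1 - r
      cell_p <- c(q^2 / 4, p * q / 2, p^2 / 4,
                  p * q / 2, (p^2 + q^2) / 2, p * q / 2,
                  p^2 / 4, p * q / 2, q^2 / 4)
      n <- sample(30:200, 1)
      matrix(rmultinom(1, n, cell_p), 3, 3, byrow = TRUE)
    })
  })
}

# independent re-statement of the hit-resolution rules as plain nested
# conditions; the oracle for resolve_marker
resolve_oracle <- function(hits, support) {
  if (nrow(hits) == 1) return(list(target = hits$sseqid, cat = "single_robust"))
  best_e <- min(hits$evalue)
  at_e <- hits[hits$evalue == best_e, ]
  best_i <- max(at_e$pident)
  tops <- unique(at_e$sseqid[at_e$pident == best_i])
  sup_hits <- hits[hits$sseqid %in% support, ]
  if (length(tops) == 1) {
    if (tops %in% support) return(list(target = tops, cat = "top_supported"))
    if (nrow(sup_hits) > 0) {
      sh <- sup_hits[order(sup_hits$evalue, -sup_hits$pident), ]
      return(list(target = sh$sseqid[1], cat = "not_top_supported"))
    }
    return(list(target = tops, cat = "top_unsupported"))
  }
  sup_tops <- intersect(tops, support)
  if (length(sup_tops) >= 1)
    return(list(target = sort(sup_tops)[1], cat = "top_supported"))
  if (nrow(sup_hits) > 0) {
    sh <- sup_hits[order(sup_hits$evalue, -sup_hits$pident), ]
    return(list(target = sh$sseqid[1], cat = "not_top_supported"))
  }
  list(target = NA_character_, cat = "unresolved")
}

make_hits <- function(targets, evalues, pidents, marker = "q1") {
  tibble::tibble(
    qseqid = marker, sseqid = targets, pident = pidents,
    length = 64L, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 64L,
    sstart = seq(1000, by = 1000, length.out = length(targets)),
    send = seq(1063, by = 1000, length.out = length(targets)),
    evalue = evalues, bitscore = 120
  )
}
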
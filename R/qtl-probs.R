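# F2 genotype transition matrix between two positions with recombination
# fraction r (states SS, SC, CC; two independent meioses)
f2_transition <- function(r) {
  q <- 1 - r
  matrix(c(q^2, 2 * r * q, r^2,
           r * q, q^2 + r^2, r * q,
           r^2, 2 * r * q, q^2),
         3, 3, byrow = TRUE)
}

#' Genotype probabilities along the map (hidden Markov reconstruction)
#'
#' Runs the forward-backward algorithm for each F2 individual over each
#' linkage group: a Markov chain on \{SS, SC, CC\} with prior (1/4, 1/2,
#' 1/4), transition probabilities from `kosambi_inverse()` of inter-position
#' distances (no interference, intervals independent), and an emission error
#' `epsilon` (the observed code matches the true genotype with probability
#' `1 - epsilon`, each other class with `epsilon / 2`; missing calls emit
#' uniformly). Evaluation positions are the typed markers plus a pseudo-
#' marker grid at `step_cM` spacing.
#'
#' @param map a `genetic_map` or tibble `(group, marker, pos_cM)`.
#' @param codes genotype-code matrix (markers x F2 individuals) over
#'   `"a"/"h"/"b"/NA`.
#' @param step_cM pseudomarker grid spacing (default 1 cM); `Inf` for
#'   markers only.
#' @param epsilon genotyping-error parameter in `[0, 0.2)`.
#' @return An object of class `geno_probs`: per linkage group a list with
#'   `positions` (tibble `pos_cM`, `marker` — `NA` for pseudomarkers) and
#'   `probs` (array individuals x positions x 3). The observed codes and
#'   individual ids are carried along for the scan methods.
#' @examples
#' m <- tibble::tibble(group = 1, marker = c("m1", "m2"), pos_cM = c(0, 10))
#' codes <- rbind(m1 = c("a", "h", "b"), m2 = c("a", "h", "b"))
#' gp <- genotype_probs(m, codes, step_cM = 5, epsilon = 0)
#' @export
genotype_probs <- function(map, codes, step_cM = 1, epsilon = 0.001) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  if (nrow(tbl) == 0) abort("empty map")
  if (epsilon < 0 || epsilon >= 0.2) abort("`epsilon` must be in [0, 0.2)")
  stopifnot(is.matrix(codes))
  ind <- colnames(codes)
  n <- length(ind)

  norm_rows <- function(x) {
    rs <- rowSums(x)
    zero <- rs == 0 | !is.finite(rs)
    if (any(zero)) { x[zero, ] <- 1; rs[zero] <- 3 }
    x / rs
  }

  groups <- split(tbl, tbl$group)
  out <- purrr::map(groups, function(g) {
    g <- g[order(g$pos_cM), ]
    mpos <- g$pos_cM
    # tied marker positions get a hair of separation so each keeps its data
    while (any(dup <- duplicated(round(mpos, 9))))
      mpos[dup] <- mpos[dup] + 1e-6
    grid <- if (is.finite(step_cM))
      seq(0, max(mpos), by = step_cM) else numeric()
    pos <- sort(unique(round(c(mpos, grid), 9)))
    mk <- rep(NA_character_, length(pos))
    mk[match(round(mpos, 9), pos)] <- g$marker
    np <- length(pos)

    # emission matrices: n x 3 per position (all-ones at pseudomarkers)
    emis <- vector("list", np)
    for (p in seq_len(np)) {
      e <- matrix(1, n, 3)
      if (!is.na(mk[p]) && mk[p] %in% rownames(codes)) {
        obs <- codes[mk[p], ind]
        gi <- match(obs, c("a", "h", "b"))
        typed <- !is.na(gi)
        if (any(typed)) {
          e[typed, ] <- epsilon / 2
          e[cbind(which(typed), gi[typed])] <- 1 - epsilon
        }
      }
      emis[[p]] <- e
    }
    trans <- lapply(kosambi_inverse(diff(pos)), f2_transition)

    prior <- c(0.25, 0.5, 0.25)
    alpha <- vector("list", np)
    a <- norm_rows(sweep(emis[[1]], 2, prior, `*`))
    alpha[[1]] <- a
    for (p in seq_len(np)[-1]) {
      a <- norm_rows((a %*% trans[[p - 1]]) * emis[[p]])
      alpha[[p]] <- a
    }
    b <- matrix(1, n, 3)
    probs <- array(NA_real_, c(n, np, 3),
                   dimnames = list(ind, NULL, c("SS", "SC", "CC")))
    probs[, np, ] <- alpha[[np]]
    for (p in rev(seq_len(np))[-1]) {
      b <- norm_rows((b * emis[[p + 1]]) %*% t(trans[[p]]))
      probs[, p, ] <- norm_rows(alpha[[p]] * b)
    }
    list(positions = tibble::tibble(pos_cM = pos, marker = mk), probs = probs)
  })

  structure(list(groups = out, individuals = ind, codes = codes,
                 epsilon = epsilon, step_cM = step_cM),
            class = "geno_probs")
}
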
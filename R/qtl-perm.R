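#' Genome-wide permutation thresholds for the binary-trait scan
#'
#' Permutes the phenotype labels `n_perm` times, records the genome-wide
#' maximum LOD of each permuted scan, and returns the empirical
#' `1 - alpha` quantiles of those maxima. Seeded and reproducible; the
#' caller's RNG state is untouched.
#'
#' For `mr` and `hk` the permuted scans are computed in a single batch: the
#' residual sum of squares of every permuted phenotype against each
#' position's fixed design is obtained by projecting the permutation matrix
#' on precomputed orthonormal bases, so thousands of permutations cost a
#' handful of matrix products. The `em` method is refit permutation by
#' permutation and is correspondingly slower.
#'
#' @inheritParams scanone_binary
#' @param method one scan method (`"hk"`, `"mr"` or `"em"`).
#' @param n_perm number of permutations; must be at least `1 / min(alphas)`.
#' @param alphas genome-wide significance levels.
#' @param seed integer seed.
#' @return A tibble `(alpha, threshold)`; the permutation maxima are kept in
#'   `attr(, "max_lods")`.
#' @examples
#' m <- tibble::tibble(group = 1, marker = c("m1", "m2"), pos_cM = c(0, 10))
#' codes <- rbind(m1 = rep(c("a", "h", "b"), 10), m2 = rep(c("a", "h", "b"), 10))
#' colnames(codes) <- paste0("F2_", 1:30)
#' gp <- genotype_probs(m, codes, step_cM = 5)
#' permutation_threshold(rep(0:1, 15), gp, n_perm = 20, alphas = 0.1, seed = 1)
#' @export
permutation_threshold <- function(phenotypes, grid, method = "hk",
                                  n_perm = 1000,
                                  alphas = c(0.05, 0.001), seed = 1) {
  stopifnot(inherits(grid, "geno_probs"))
  method <- match.arg(method, c("hk", "mr", "em"))
  if (n_perm < 1 / min(alphas))
    abort(sprintf("n_perm = %d is too small for alpha = %g", n_perm,
                  min(alphas)))
  y <- phenotype_vector(phenotypes, grid$individuals)
  n <- length(y)

  max_lods <- with_seed(stage_seed(seed, "perm"), {
    Y <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
    if (method == "em") {
      vapply(seq_len(n_perm), function(i) {
        sc <- scanone_binary(Y[, i], grid, methods = "em")
        max(sc$lod)
      }, 0)
    } else {
      batch_max_lods(Y, grid, method)
    }
  })

  thr <- vapply(alphas, function(a)
    as.numeric(stats::quantile(max_lods, 1 - a, type = 1)), 0)
  structure(tibble::tibble(alpha = alphas, threshold = thr),
            max_lods = max_lods)
}

# batch permutation scan for the regression methods: for each position the
# fitted RSS of every permuted phenotype comes from one projection
batch_max_lods <- function(Y, grid, method) {
  n <- nrow(Y)
  css <- colSums(scale(Y, scale = FALSE)^2) # RSS0, identical across positions
  maxl <- rep(0, ncol(Y))
  for (g in grid$groups) {
    np <- nrow(g$positions)
    for (p in seq_len(np)) {
      mk <- g$positions$marker[p]
      if (method == "mr") {
        if (is.na(mk)) next
        gi <- match(grid$codes[mk, grid$individuals], c("a", "h", "b"))
        keep <- !is.na(gi)
        nk <- sum(keep)
        if (nk < 3) next
        X <- stats::model.matrix(~ factor(gi[keep], 1:3))
        Yk <- Y[keep, , drop = FALSE]
        rss0 <- colSums(scale(Yk, scale = FALSE)^2)
      } else {
        X <- cbind(1, g$probs[, p, 2], g$probs[, p, 3])
        Yk <- Y
        nk <- n
        rss0 <- css
      }
      Q <- qr.Q(qr(X))
      rss1 <- pmax(colSums(Yk^2) - colSums(crossprod(Q, Yk)^2), nk * 1e-4)
      lod <- pmax((nk / 2) * log10(pmax(rss0, 1e-12) / rss1), 0)
      maxl <- pmax(maxl, lod)
    }
  }
  maxl
}
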
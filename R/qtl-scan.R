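#' Single-QTL genome scan for a binary trait
#'
#' Scans the genome with up to three methods, treating the 0/1 phenotype as
#' numeric under a Gaussian working model (the standard scan for a
#' binary-coded trait, which reproduces the LOD scale expected for a
#' Mendelian trait):
#'
#' * `mr` — marker regression: at each typed marker, individuals missing the
#'   genotype are dropped and `LOD = (n/2) log10(RSS0 / RSS1)` from the
#'   one-way genotype-class regression;
#' * `hk` — Haley-Knott regression: the same LOD formula with the three
#'   genotype-class probabilities as regressors, at every grid position;
#' * `em` — interval mapping: a three-component Gaussian mixture with class
#'   weights from the genotype probabilities, maximised by EM;
#'   `LOD = log10 L1 - log10 L0`. Positions where every individual's
#'   genotype is certain short-circuit to the Haley-Knott computation.
#'
#' @param phenotypes 0/1 vector over F2 individuals (order of
#'   `grid$individuals`), or a tibble `(individual, phenotype)`.
#' @param grid a [genotype_probs()] object.
#' @param methods subset of `c("mr", "em", "hk")`.
#' @return An object of class `scan_result`: tibble `(group, pos_cM, marker,
#'   method, lod)` with per-method peaks in `attr(, "peaks")`.
#' @examples
#' m <- tibble::tibble(group = 1, marker = c("m1", "m2"), pos_cM = c(0, 10))
#' codes <- rbind(m1 = c("a", "h", "b", "b"), m2 = c("a", "a", "h", "b"))
#' colnames(codes) <- paste0("F2_", 1:4)
#' gp <- genotype_probs(m, codes, step_cM = 5, epsilon = 0.001)
#' scanone_binary(c(0, 0, 1, 1), gp)
#' @export
scanone_binary <- function(phenotypes, grid, methods = c("mr", "em", "hk")) {
  stopifnot(inherits(grid, "geno_probs"))
  methods <- match.arg(methods, c("mr", "em", "hk"), several.ok = TRUE)
  y <- phenotype_vector(phenotypes, grid$individuals)
  n <- length(y)
  if (length(unique(y)) < 2) {
    warn("constant phenotype: all LOD scores are zero")
  }

  res <- purrr::imap_dfr(grid$groups, function(g, gname) {
    np <- nrow(g$positions)
    purrr::map_dfr(methods, function(method) {
      lod <- rep(NA_real_, np)
      if (method == "mr") {
        for (p in seq_len(np)) {
          mk <- g$positions$marker[p]
          if (is.na(mk)) next
          lod[p] <- mr_lod(grid$codes[mk, grid$individuals], y)
        }
      } else if (method == "hk") {
        for (p in seq_len(np)) lod[p] <- hk_lod(g$probs[, p, ], y)
      } else {
        for (p in seq_len(np)) lod[p] <- em_lod(g$probs[, p, ], y)
      }
      tibble::tibble(group = gname, pos_cM = g$positions$pos_cM,
                     marker = g$positions$marker, method = method, lod = lod)
    })
  })
  res$group <- as.integer(res$group)
  res <- res[!is.na(res$lod), ] # MR rows exist only at typed markers

  peaks <- res %>%
    dplyr::filter(!is.na(.data$lod)) %>%
    dplyr::group_by(.data$method) %>%
    dplyr::slice_max(.data$lod, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  structure(res, peaks = peaks, class = c("scan_result", class(res)))
}

phenotype_vector <- function(phenotypes, individuals) {
  if (is.data.frame(phenotypes)) {
    i <- match(individuals, phenotypes$individual)
    if (anyNA(i)) abort("phenotype table is missing some F2 individuals")
    y <- phenotypes$phenotype[i]
  } else {
    if (length(phenotypes) != length(individuals))
      abort("phenotype length does not match the cohort size")
    y <- phenotypes
  }
  as.numeric(y)
}

# one-way genotype-class regression at a typed marker
mr_lod <- function(codes_row, y) {
  gi <- match(codes_row, c("a", "h", "b"))
  keep <- !is.na(gi)
  if (sum(keep) < 3) return(NA_real_)
  yy <- y[keep]; gg <- factor(gi[keep], 1:3)
  n <- length(yy)
  rss0 <- sum((yy - mean(yy))^2)
  mu <- tapply(yy, gg, mean)
  fit <- mu[as.integer(gg)]
  rss1 <- sum((yy - fit)^2)
  lod_from_rss(n, rss0, rss1)
}

# Haley-Knott regression on the class probabilities
hk_lod <- function(P, y) {
  n <- length(y)
  X <- cbind(1, P[, 2], P[, 3])
  fit <- stats::lm.fit(X, y)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((y - mean(y))^2)
  lod_from_rss(n, rss0, rss1)
}

# residual variance is floored at 1e-4 (phenotype units^2): a fully
# penetrant binary trait can separate perfectly, where the unconstrained
# Gaussian working likelihood diverges; the common floor keeps all three
# methods finite and mutually consistent
lod_from_rss <- function(n, rss0, rss1) {
  rss1 <- max(rss1, n * 1e-4)
  if (rss0 <= 0) return(0)
  max((n / 2) * log10(rss0 / rss1), 0)
}

# EM for the 3-component Gaussian mixture with fixed class weights.
# The common sigma is floored at 0.01: with a fully penetrant binary trait
# the mixture is degenerate (a component collapses on 0 or 1) and the
# likelihood is otherwise unbounded.
em_lod <- function(P, y, tol = 1e-6, max_iter = 100) {
  n <- length(y)
  certain <- max(1 - apply(P, 1, max)) < 1e-8
  if (certain) return(hk_lod(P, y))
  rss0 <- sum((y - mean(y))^2)
  if (rss0 <= 0) return(0)
  sig0 <- sqrt(rss0 / n)
  ll0 <- sum(stats::dnorm(y, mean(y), sig0, log = TRUE))

  # start from the HK fit
  Xb <- cbind(1, P[, 2], P[, 3])
  hk <- stats::lm.fit(Xb, y)
  mu <- c(hk$coefficients[1],
          hk$coefficients[1] + hk$coefficients[2],
          hk$coefficients[1] + hk$coefficients[3])
  mu[is.na(mu)] <- mean(y)
  sig <- max(sqrt(sum(hk$residuals^2) / n), 1e-2)

  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(g) stats::dnorm(y, mu[g], sig), numeric(n))
    num <- P * dens
    tot <- rowSums(num)
    tot[tot < 1e-300] <- 1e-300
    z <- num / tot
    cs <- colSums(z)
    mu_new <- ifelse(cs > 1e-8, colSums(z * y) / cs, mu)
    resid2 <- vapply(1:3, function(g) (y - mu_new[g])^2, numeric(n))
    sig_new <- max(sqrt(sum(z * resid2) / n), 1e-2)
    ll <- sum(log(tot))
    mu <- mu_new; sig <- sig_new
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  dens <- vapply(1:3, function(g) stats::dnorm(y, mu[g], sig), numeric(n))
  ll1 <- sum(log(pmax(rowSums(P * dens), 1e-300)))
  max((ll1 - ll0) / log(10), 0)
}

#' Per-genotype-class phenotype effect summary at one marker
#'
#' @param codes_row genotype codes (`"a"/"h"/"b"/NA`) at one marker, or a
#'   marker name together with a `geno_probs`/code matrix via `codes`.
#' @param phenotypes 0/1 phenotype vector over the same individuals.
#' @return A tibble `(class, n, mean, se)` over SS, SC, CC; `attr(, "class_labels")`
#'   maps codes to class names.
#' @examples
#' effect_summary(c("a", "a", "h", "b", "b"), c(0, 0, 0, 1, 1))
#' @export
effect_summary <- function(codes_row, phenotypes) {
  y <- as.numeric(phenotypes)
  gi <- factor(match(codes_row, c("a", "h", "b")), 1:3,
               labels = c("SS", "SC", "CC"))
  keep <- !is.na(gi)
  out <- tibble::tibble(class = factor(c("SS", "SC", "CC"),
                                       c("SS", "SC", "CC"))) %>%
    dplyr::left_join(
      tibble::tibble(class = gi[keep], y = y[keep]) %>%
        dplyr::group_by(.data$class) %>%
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                         se = stats::sd(.data$y) / sqrt(dplyr::n())),
      by = "class")
  out$n[is.na(out$n)] <- 0L
  structure(out, class = c("effect_summary", class(out)))
}
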
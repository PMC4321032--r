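#' Simulate a GBS-genotyped F2 intercross
#'
#' Generates a complete synthetic dataset with the statistical structure the
#' downstream analysis assumes: founder panels fixed for alternate SNP
#' alleles, heterozygous F1s, and an F2 cohort produced by independent
#' meioses through a Markov recombination model in which each inter-marker
#' interval recombines with probability `kosambi_inverse(d)` of its true map
#' distance (intervals independent, so mapping back with the Kosambi function
#' is self-consistent). A fully penetrant recessive trait segregates from a
#' configurable locus. Artifact markers (unassignable parents, monomorphic,
#' distorted) are planted at the configured fractions, then per-call errors
#' and missingness are applied, in that order.
#'
#' @param config a [sim_config()].
#' @return An object of class `gbs_sim`: a list with elements
#'   * `genotypes`: tibble, one row per marker; first column `marker`, then
#'     one IUPAC-call column per individual (`S1..`, `C1..`, `F1_..`,
#'     `F2_..`); missing calls are `NA`.
#'   * `phenotypes`: tibble `(individual, phenotype)` with 0 = pigmented,
#'     1 = trait-positive (absent when `trait_locus` is `NULL`).
#'   * `truth`: ground truth — `$map` (marker, chrom, pos_cM, alleles,
#'     scaffold, scaffold_bp), `$scaffolds` (tiling and planted orientation),
#'     `$artifacts` (planted marker ids per class), `$trait`
#'     (locus and per-individual trait genotype), `$tags` (64-base tag
#'     sequence per allele).
#'   * `config`: the configuration used.
#' @examples
#' sim <- simulate_cross(sim_config(n_chromosomes = 2,
#'                                  markers_per_chromosome = 8,
#'                                  n_f2 = 20, trait_locus = NULL, seed = 4))
#' dim(sim$genotypes)
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "simulate"), simulate_cross_impl(config))
}

simulate_cross_impl <- function(cfg) {
  n_chr <- cfg$n_chromosomes
  m_chr <- cfg$markers_per_chromosome
  n_f2 <- cfg$n_f2
  L <- cfg$chrom_length_cM

  ids <- individual_ids(cfg)

  # true map: markers evenly tiled along each chromosome
  pos1 <- if (m_chr == 1) L / 2 else seq(0, L, length.out = m_chr)
  map <- tidyr::expand_grid(chrom = seq_len(n_chr), idx = seq_len(m_chr)) %>%
    dplyr::mutate(
      marker = sprintf("M%02d_%03d", .data$chrom, .data$idx),
      pos_cM = pos1[.data$idx]
    )

  # alleles: distinct nucleotides for every marker
  sur <- sample(.nucleotides, nrow(map), replace = TRUE)
  cav <- vapply(sur, function(a) sample(setdiff(.nucleotides, a), 1), "")
  map$surface_allele <- sur
  map$cave_allele <- unname(cav)
  map$het <- het_code(map$surface_allele, map$cave_allele)

  # scaffold embedding: chromosomes tiled by scaffolds with random
  # planted orientation; marker bp = cM position x fixed bp/cM scale
  map$chrom_bp <- round(map$pos_cM * cfg$bp_per_cM) + 1
  chrom_len_bp <- round(L * cfg$bp_per_cM) + 1
  tile <- (map$chrom_bp - 1) %/% cfg$scaffold_bp
  map$scaffold <- sprintf("scf%02d.%02d", map$chrom, tile + 1)
  scaffolds <- map %>%
    dplyr::distinct(.data$chrom, .data$scaffold) %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(tile = dplyr::row_number() - 1) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(
      start_bp = .data$tile * cfg$scaffold_bp + 1,
      end_bp = pmin((.data$tile + 1) * cfg$scaffold_bp, chrom_len_bp),
      length_bp = .data$end_bp - .data$start_bp + 1,
      orientation = sample(c("forward", "reverse"), dplyr::n(), replace = TRUE)
    )
  map <- dplyr::left_join(map,
    dplyr::select(scaffolds, "scaffold", "start_bp", "length_bp", "orientation"),
    by = "scaffold")
  raw_off <- map$chrom_bp - map$start_bp + 1
  map$scaffold_bp <- ifelse(map$orientation == "reverse",
                            map$length_bp - raw_off + 1, raw_off)
  map <- dplyr::select(map, "marker", "chrom", "pos_cM", "surface_allele",
                       "cave_allele", "het", "chrom_bp", "scaffold",
                       "scaffold_bp")

  # 64-base tag pair per marker, SNP at base 32
  tag_bg <- vapply(seq_len(nrow(map)), function(i)
    paste(sample(.nucleotides, 64, replace = TRUE), collapse = ""), "")
  tags <- tibble::tibble(
    marker = map$marker,
    tag_surface = paste0(substr(tag_bg, 1, 31), map$surface_allele,
                         substr(tag_bg, 33, 64)),
    tag_cave = paste0(substr(tag_bg, 1, 31), map$cave_allele,
                      substr(tag_bg, 33, 64))
  )

  # resolve trait locus
  trait <- NULL
  if (!is.null(cfg$trait_locus)) {
    tchr <- as.integer(cfg$trait_locus[1])
    tcm <- cfg$trait_locus[2]
    if (is.na(tcm)) {
      cand <- map$pos_cM[map$chrom == tchr]
      tcm <- cand[which.min(abs(cand - L / 2))]
    }
    trait <- list(chrom = tchr, pos_cM = tcm)
  }

  # simulate F2 genotypes chromosome by chromosome (cave-allele dosage 0/1/2)
  geno <- matrix(0L, nrow(map), n_f2,
                 dimnames = list(map$marker, ids$f2))
  trait_geno <- NULL
  for (chr in seq_len(n_chr)) {
    rows <- which(map$chrom == chr)
    pos <- map$pos_cM[rows]
    t_here <- !is.null(trait) && trait$chrom == chr
    sim_pos <- pos
    t_at <- NA_integer_
    if (t_here) {
      hit <- which(abs(pos - trait$pos_cM) < 1e-9)
      if (length(hit)) {
        t_at <- hit[1]
      } else {
        sim_pos <- sort(c(pos, trait$pos_cM))
        t_at <- which(abs(sim_pos - trait$pos_cM) < 1e-9)[1]
      }
    }
    g <- sim_chrom_genotypes(sim_pos, n_f2)
    if (t_here) {
      trait_geno <- g[t_at, ]
      if (length(sim_pos) > length(pos)) g <- g[-t_at, , drop = FALSE]
    }
    geno[rows, ] <- g
  }

  # phenotype: fully penetrant recessive (trait-positive iff cave homozygote)
  phen <- NULL
  if (!is.null(trait)) {
    trait$genotype <- trait_geno
    trait$marker <- {
      rows <- which(map$chrom == trait$chrom & abs(map$pos_cM - trait$pos_cM) < 1e-9)
      if (length(rows)) map$marker[rows[1]] else NA_character_
    }
    phen <- tibble::tibble(individual = ids$f2,
                           phenotype = as.integer(trait_geno == 2L))
  }

  # assemble the clean call matrix
  calls <- build_calls(map, geno, ids, cfg)
  panels <- new_marker_panels(calls, map, ids)

  # plant artifacts, then error, then missingness
  panels <- plant_artifacts(panels, cfg)
  panels$calls <- apply_call_errors(panels$calls, map, cfg$error_rate)
  panels$calls <- apply_missingness(panels$calls, cfg$missing_rate)

  genotypes <- tibble::as_tibble(panels$calls, rownames = "marker")

  structure(list(
    genotypes = genotypes,
    phenotypes = phen,
    truth = list(map = map, scaffolds = scaffolds,
                 artifacts = panels$artifacts, trait = trait, tags = tags),
    config = cfg
  ), class = "gbs_sim")
}

individual_ids <- function(cfg) {
  p <- cfg$panel_size
  list(
    surface = paste0("S", seq_len(p)),
    cave = paste0("C", seq_len(p)),
    f1 = paste0("F1_", seq_len(p)),
    f2 = sprintf("F2_%03d", seq_len(cfg$n_f2))
  )
}

# haplotype dosages along one chromosome: 2 * n_f2 independent gametes,
# each a Markov chain over marker positions with per-interval
# recombination probability kosambi_inverse(gap)
sim_chrom_genotypes <- function(pos, n_f2) {
  m <- length(pos)
  n_gam <- 2L * n_f2
  h0 <- matrix(stats::runif(n_gam) < 0.5, n_gam, 1)
  if (m > 1) {
    r <- kosambi_inverse(diff(pos))
    sw <- matrix(stats::runif(n_gam * (m - 1)), n_gam, m - 1) <
      matrix(r, n_gam, m - 1, byrow = TRUE)
    cum <- t(apply(cbind(h0, sw), 1, cumsum)) %% 2
  } else {
    cum <- h0 %% 2
  }
  hap <- matrix(as.integer(cum), n_gam, m)
  t(hap[seq_len(n_f2), , drop = FALSE] +
      hap[n_f2 + seq_len(n_f2), , drop = FALSE])
}

build_calls <- function(map, geno, ids, cfg) {
  n_mark <- nrow(map)
  all_ids <- unlist(ids, use.names = FALSE)
  calls <- matrix(NA_character_, n_mark, length(all_ids),
                  dimnames = list(map$marker, all_ids))
  for (id in ids$surface) calls[, id] <- map$surface_allele
  for (id in ids$cave) calls[, id] <- map$cave_allele
  for (id in ids$f1) calls[, id] <- map$het
  class_call <- cbind(map$surface_allele, map$het, map$cave_allele)
  for (k in seq_along(ids$f2)) {
    calls[, ids$f2[k]] <- class_call[cbind(seq_len(n_mark), geno[, k] + 1L)]
  }
  calls
}

new_marker_panels <- function(calls, map, ids) {
  structure(list(calls = calls,
                 info = dplyr::select(map, "marker", "surface_allele",
                                      "cave_allele", "het"),
                 panels = ids,
                 artifacts = list(parent_na = character(),
                                  monomorphic = character(),
                                  distorted = character())),
            class = "marker_panels")
}

#' Plant pathological markers into a simulated panel set
#'
#' Makes the configured fractions of markers (a) parent-unassignable by
#' scrambling both founder panels into 2-2 allele splits, (b) monomorphic
#' (every F2 individual shares one genotype), and (c) segregation-distorted
#' by resampling F2 genotypes with the cave-homozygote class down-weighted by
#' `1 - distortion_strength` (renormalised). The three artifact sets are
#' disjoint; planted marker ids are recorded in `$artifacts`.
#'
#' Called internally by [simulate_cross()] inside its seeded scope; when used
#' standalone the session RNG governs which markers are chosen.
#'
#' @param panelset a `marker_panels` object (see [simulate_cross()]).
#' @param config a [sim_config()] providing the fractions.
#' @return The modified `marker_panels` object.
#' @export
plant_artifacts <- function(panelset, config) {
  stopifnot(inherits(panelset, "marker_panels"))
  cfg <- config
  if (cfg$frac_monomorphic + cfg$frac_parentNA + cfg$frac_distorted > 1)
    abort("artifact fractions must sum to at most 1")
  calls <- panelset$calls
  info <- panelset$info
  ids <- panelset$panels
  n_mark <- nrow(calls)
  n_pick <- function(f) round(f * n_mark)

  pool <- rownames(calls)
  pick <- function(k) {
    sel <- sort(sample(pool, min(k, length(pool))))
    pool <<- setdiff(pool, sel)
    sel
  }
  pna <- pick(n_pick(cfg$frac_parentNA))
  mono <- pick(n_pick(cfg$frac_monomorphic))
  dist <- pick(n_pick(cfg$frac_distorted))

  info_at <- function(mk) match(mk, info$marker)

  # parent-unassignable: 2-2 split of the two alleles in both founder panels
  if (length(pna)) {
    i <- info_at(pna)
    half <- length(ids$surface) %/% 2
    for (j in seq_along(ids$surface)) {
      al <- if (j <= half) info$surface_allele[i] else info$cave_allele[i]
      calls[pna, ids$surface[j]] <- al
      calls[pna, ids$cave[j]] <- al
    }
  }

  # monomorphic: one genotype class shared by the whole F2 cohort
  if (length(mono)) {
    i <- info_at(mono)
    calls[mono, ids$f2] <- matrix(info$surface_allele[i], length(mono),
                                  length(ids$f2))
  }

  # distorted: resample F2 genotypes iid with probabilities (1, 2, 1-s)/(4-s)
  if (length(dist)) {
    s <- cfg$distortion_strength
    p <- c(1, 2, 1 - s) / (4 - s)
    i <- info_at(dist)
    cls <- cbind(info$surface_allele[i], info$het[i], info$cave_allele[i])
    for (k in seq_along(dist)) {
      g <- sample.int(3L, length(ids$f2), replace = TRUE, prob = p)
      calls[dist[k], ids$f2] <- cls[k, g]
    }
  }

  panelset$calls <- calls
  panelset$artifacts <- list(parent_na = pna, monomorphic = mono,
                             distorted = dist)
  panelset
}

# symmetric call-swap error: with prob `rate` a call moves to a uniformly
# chosen other genotype class of its marker
apply_call_errors <- function(calls, map, rate) {
  if (rate <= 0) return(calls)
  cls <- cbind(map$surface_allele, map$het, map$cave_allele)
  err <- matrix(stats::runif(length(calls)) < rate,
                nrow(calls), ncol(calls)) & !is.na(calls)
  if (!any(err)) return(calls)
  idx <- which(err, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    other <- setdiff(cls[i, ], calls[i, j])
    calls[i, j] <- other[sample.int(length(other), 1)]
  }
  calls
}

apply_missingness <- function(calls, rate) {
  if (rate <= 0) return(calls)
  miss <- matrix(stats::runif(length(calls)) < rate, nrow(calls), ncol(calls))
  calls[miss] <- NA_character_
  calls
}

#' @export
print.gbs_sim <- function(x, ...) {
  cat("<gbs_sim> ", nrow(x$genotypes), " markers x ",
      ncol(x$genotypes) - 1, " individuals (",
      x$config$n_chromosomes, " chromosomes, n_f2 = ", x$config$n_f2, ")\n",
      sep = "")
  invisible(x)
}
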
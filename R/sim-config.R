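#' Configuration for the synthetic GBS cross generator
#'
#' Defines the study conditions emulated by [simulate_cross()]: an F2
#' intercross between two divergent founder morphotypes (surface and cave),
#' genotyped at SNP markers carried on 64-bp GBS tags, with small founder
#' panels, per-call error and missingness, and a configurable fraction of
#' pathological markers (unassignable parents, monomorphic F2 calls,
#' segregation distortion).
#'
#' Defaults follow the emulated study design where it states them: 25
#' chromosomes (the karyotype number), 170 F2 individuals, founder/F1 panels
#' of 4, a genome of roughly 2100 cM (84 cM per chromosome), and a fully
#' penetrant recessive trait locus on chromosome 13. Rates the study does not
#' state (error, missingness, artifact fractions) are set to values typical
#' of filtered GBS data; see the methods vignette.
#'
#' @param n_chromosomes number of chromosomes (default 25).
#' @param markers_per_chromosome markers evenly tiled per chromosome.
#' @param chrom_length_cM genetic length of every chromosome, cM.
#' @param n_f2 F2 cohort size.
#' @param panel_size individuals per founder panel and per F1 panel.
#' @param missing_rate per-call missingness probability, applied last.
#' @param error_rate per-call probability of swapping to a uniformly chosen
#'   other genotype class, applied before missingness.
#' @param frac_monomorphic fraction of markers made uninformative (a single
#'   F2 genotype class).
#' @param frac_parentNA fraction of markers whose founder panels are
#'   scrambled so no parental consensus exists.
#' @param frac_distorted fraction of markers with segregation distortion.
#' @param distortion_strength selection coefficient \eqn{s \in [0,1]} against
#'   the cave homozygote: distorted F2 class probabilities are
#'   \eqn{(1, 2, 1-s)/(4-s)}.
#' @param trait_locus `c(chromosome, cM)` for the recessive trait locus, or
#'   `NULL` for no trait. An `NA` cM places the locus at the typed marker
#'   nearest the chromosome midpoint.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param bp_per_cM physical scale used to embed markers on scaffolds.
#' @param scaffold_bp scaffold tile size in bp; chromosomes are tiled by
#'   scaffolds of this size, each with a random planted orientation.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_chromosomes = 3, markers_per_chromosome = 10, seed = 1)
#' @export
sim_config <- function(n_chromosomes = 25,
                       markers_per_chromosome = 40,
                       chrom_length_cM = 84,
                       n_f2 = 170,
                       panel_size = 4,
                       missing_rate = 0.02,
                       error_rate = 0.005,
                       frac_monomorphic = 0.02,
                       frac_parentNA = 0.05,
                       frac_distorted = 0.05,
                       distortion_strength = 0.6,
                       trait_locus = c(13, NA),
                       seed = 1,
                       bp_per_cM = 5e5,
                       scaffold_bp = 4e6) {
  cfg <- list(
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes"),
    markers_per_chromosome = check_count(markers_per_chromosome, "markers_per_chromosome"),
    chrom_length_cM = chrom_length_cM,
    n_f2 = check_count(n_f2, "n_f2"),
    panel_size = check_count(panel_size, "panel_size"),
    missing_rate = check_prob(missing_rate, "missing_rate"),
    error_rate = check_prob(error_rate, "error_rate"),
    frac_monomorphic = check_prob(frac_monomorphic, "frac_monomorphic"),
    frac_parentNA = check_prob(frac_parentNA, "frac_parentNA"),
    frac_distorted = check_prob(frac_distorted, "frac_distorted"),
    distortion_strength = check_prob(distortion_strength, "distortion_strength"),
    trait_locus = trait_locus,
    seed = check_count(seed, "seed", min = 0L),
    bp_per_cM = bp_per_cM,
    scaffold_bp = scaffold_bp
  )
  if (!is.numeric(chrom_length_cM) || chrom_length_cM <= 0)
    abort("`chrom_length_cM` must be a positive length in cM")
  tot <- cfg$frac_monomorphic + cfg$frac_parentNA + cfg$frac_distorted
  if (tot > 1) abort("artifact fractions must sum to at most 1")
  if (!is.null(trait_locus)) {
    if (length(trait_locus) != 2)
      abort("`trait_locus` must be c(chromosome, cM) or NULL")
    chr <- trait_locus[1]
    if (is.na(chr) || chr < 1 || chr > cfg$n_chromosomes || chr != floor(chr))
      abort("trait locus chromosome is outside the simulated map")
    if (!is.na(trait_locus[2]) &&
        (trait_locus[2] < 0 || trait_locus[2] > chrom_length_cM))
      abort("trait locus position is outside the simulated map")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_chromosomes, " chromosomes x ",
      x$markers_per_chromosome, " markers (", x$chrom_length_cM,
      " cM each), n_f2 = ", x$n_f2, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
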
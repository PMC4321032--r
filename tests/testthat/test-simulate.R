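test_that("identical seeds give identical datasets", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 8,
                    n_f2 = 30, trait_locus = NULL, seed = 13)
  s1 <- simulate_cross(cfg)
  s2 <- simulate_cross(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$map, s2$truth$map)
  s3 <- simulate_cross(sim_config(n_chromosomes = 2,
                                  markers_per_chromosome = 8,
                                  n_f2 = 30, trait_locus = NULL, seed = 14))
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("with no noise every F1 call is the heterozygote of its allele pair", {
  sim <- clean_sim(seed = 3)
  f1_cols <- grep("^F1_", names(sim$genotypes), value = TRUE)
  truth <- sim$truth$map
  for (col in f1_cols) {
    expect_identical(sim$genotypes[[col]],
                     het_code(truth$surface_allele, truth$cave_allele))
  }
  # founder panels fixed for the alternate alleles
  expect_identical(sim$genotypes$S1, truth$surface_allele)
  expect_identical(sim$genotypes$C3, truth$cave_allele)
})

test_that("the recessive trait is fully penetrant at the trait locus", {
  sim <- clean_sim(seed = 5, n_chr = 3, m = 12, n_f2 = 170, trait = c(2, NA))
  tm <- sim$truth$trait$marker
  expect_false(is.na(tm))
  calls <- unlist(sim$genotypes[sim$genotypes$marker == tm,
                                sim$phenotypes$individual])
  cave <- sim$truth$map$cave_allele[sim$truth$map$marker == tm]
  expect_identical(as.integer(calls == cave), sim$phenotypes$phenotype)
  expect_gt(sum(sim$phenotypes$phenotype), 0)
})

test_that("a trait locus off the simulated map is rejected", {
  expect_error(sim_config(n_chromosomes = 2, trait_locus = c(5, 10)),
               "outside the simulated map")
  expect_error(sim_config(n_chromosomes = 2, chrom_length_cM = 50,
                          trait_locus = c(1, 80)),
               "outside the simulated map")
})

test_that("recombination between two markers matches the Kosambi inverse", {
  # two markers 25 * log(3) cM apart: r = 0.25 exactly; 10,000 meioses
  d <- 25 * log(3)
  sim <- simulate_cross(sim_config(
    n_chromosomes = 1, markers_per_chromosome = 2, chrom_length_cM = d,
    n_f2 = 5000, missing_rate = 0, error_rate = 0, frac_monomorphic = 0,
    frac_parentNA = 0, frac_distorted = 0, trait_locus = NULL, seed = 99))
  qc <- screen_markers(sim$genotypes)
  est <- estimate_rf_em(qc$codes[1, ], qc$codes[2, ])
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(est$rf - 0.25), 3 * se)
})

test_that("F2 segregation at undistorted markers is 1:2:1", {
  sim <- clean_sim(seed = 17, n_chr = 4, m = 25, n_f2 = 170)
  qc <- screen_markers(sim$genotypes)
  m <- qc$markers
  crit <- stats::qchisq(0.99, df = 2)
  expect_gte(mean(m$chi2 < crit), 0.95)
})

test_that("artifact fractions of zero leave the panel set unchanged", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 10,
                    n_f2 = 20, frac_monomorphic = 0, frac_parentNA = 0,
                    frac_distorted = 0, trait_locus = NULL, seed = 1)
  sim <- simulate_cross(cfg)
  expect_identical(sim$truth$artifacts,
                   list(parent_na = character(), monomorphic = character(),
                        distorted = character()))
})

test_that("planted monomorphic markers share a single F2 genotype class", {
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 20,
                    n_f2 = 50, missing_rate = 0, error_rate = 0,
                    frac_monomorphic = 1, frac_parentNA = 0,
                    frac_distorted = 0, trait_locus = NULL, seed = 2)
  sim <- simulate_cross(cfg)
  f2 <- as.matrix(sim$genotypes[, grep("^F2_", names(sim$genotypes))])
  expect_true(all(apply(f2, 1, function(x) length(unique(x)) == 1)))
})

test_that("full distortion against CC gives the expected 1:2:0 chi-square", {
  # expected counts under s = 1 with n = 170: (170/3, 340/3, 0);
  # plugging into the chi-square formula by hand gives 170/3.
  n <- 170
  exp_chi2 <- (n / 3 - n / 4)^2 / (n / 4) +
    (2 * n / 3 - n / 2)^2 / (n / 2) + (n / 4)
  expect_equal(chisq_segregation(n / 3, 2 * n / 3, 0), exp_chi2)
  expect_gt(exp_chi2, 50)

  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 50,
                    n_f2 = 170, missing_rate = 0, error_rate = 0,
                    frac_monomorphic = 0, frac_parentNA = 0,
                    frac_distorted = 1, distortion_strength = 1,
                    trait_locus = NULL, seed = 4)
  sim <- simulate_cross(cfg)
  qc <- screen_markers(sim$genotypes)
  expect_true(all(qc$markers$n_b == 0))
  expect_gt(mean(qc$markers$chi2), 40)
})

test_that("QC discard categories recover the planted artifact fractions", {
  cfg <- sim_config(n_chromosomes = 5, markers_per_chromosome = 80,
                    n_f2 = 400, missing_rate = 0, error_rate = 0,
                    frac_monomorphic = 0.1, frac_parentNA = 0.1,
                    frac_distorted = 0.1, distortion_strength = 1,
                    trait_locus = NULL, seed = 31)
  sim <- simulate_cross(cfg)
  qc <- screen_markers(sim$genotypes)
  g <- glance(qc)
  n <- 400
  binom3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(g$n_unsuitable / n - 0.1), binom3(0.1))
  expect_lt(abs(g$n_uninformative / n - 0.1), binom3(0.1))
  # at n_f2 = 400 the expected distortion chi-square (400/3 = 133) is far
  # above the cutoff, so essentially every planted marker is caught
  expect_lt(abs(g$n_distorted / n - 0.1), binom3(0.1))
})

test_that("simulated hit tables honour conserved fraction and decoy rate", {
  sim <- clean_sim(seed = 11, n_chr = 3, m = 12)
  h1 <- simulate_hit_tables(sim, decoy_rate = 0, conserved_fraction = 1,
                            seed = 1)
  for (rt in c("direct", "genomic", "transcript")) {
    tab <- table(h1[[rt]]$qseqid)
    expect_equal(length(tab), nrow(sim$truth$map))
    expect_true(all(tab == 1))
    j <- merge(h1[[rt]], h1$truth, by.x = "qseqid", by.y = "marker")
    expect_true(all(j$sseqid == j$true_target))
  }
  h0 <- simulate_hit_tables(sim, decoy_rate = 0, conserved_fraction = 0,
                            seed = 1)
  expect_equal(nrow(h0$genomic), 0)
  h2 <- simulate_hit_tables(sim, decoy_rate = 1, conserved_fraction = 1,
                            seed = 1)
  n_targets <- tapply(h2$genomic$sseqid, h2$genomic$qseqid,
                      function(x) length(unique(x)))
  expect_true(all(n_targets >= 2))
  expect_true(all(n_targets <= 3))
  expect_identical(h2$genomic,
                   simulate_hit_tables(sim, 1, 1, seed = 1)$genomic)
})

test_that("hit-table writers round-trip through the reader", {
  sim <- clean_sim(seed = 19, n_chr = 2, m = 6)
  h <- simulate_hit_tables(sim, decoy_rate = 0.5, conserved_fraction = 0.9,
                           seed = 3)$genomic
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(h, f)
  h2 <- read_hit_table(f)
  expect_equal(as.data.frame(h2), as.data.frame(h), tolerance = 1e-12)
})
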
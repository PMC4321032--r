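test_that("identical complete code vectors give zero recombination", {
  x <- rep(c("a", "h", "b"), times = c(20, 45, 20))
  est <- estimate_rf_em(x, x)
  expect_equal(est$rf, 0, tolerance = 1e-7)
  expect_gt(est$lod, 0)
  expect_gt(est$ind_lod, 0)
})

test_that("unlinked markers estimate near one half with tiny independence LOD", {
  sim <- simulate_cross(sim_config(
    n_chromosomes = 2, markers_per_chromosome = 1, chrom_length_cM = 10,
    n_f2 = 10000, missing_rate = 0, error_rate = 0, frac_monomorphic = 0,
    frac_parentNA = 0, frac_distorted = 0, trait_locus = NULL, seed = 53))
  qc <- screen_markers(sim$genotypes)
  est <- estimate_rf_em(qc$codes[1, ], qc$codes[2, ])
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_lt(abs(est$rf - 0.5), 3 * se)
  expect_lt(est$ind_lod, 3)
})

test_that("EM matches the brute-force likelihood grid on random tables", {
  tabs <- random_tables(200, seed = 61)
  for (tab in tabs) {
    em <- cavemapr:::rf_from_table(tab)
    grid <- grid_search_rf(tab)
    expect_lt(abs(em$rf - grid), 1e-3)
  }
})

test_that("EM log-likelihood never decreases across iterations", {
  ll_cells <- cavemapr:::.ll_cells
  tabs <- random_tables(25, seed = 67)
  for (tab in tabs) {
    n <- as.numeric(t(tab))
    r <- 0.25
    ll_prev <- -Inf
    for (it in 1:50) {
      ll <- do.call(ll_cells, c(as.list(n), list(r = max(min(r, 0.4999), 1e-12))))
      expect_gte(ll, ll_prev - 1e-9)
      ll_prev <- ll
      w <- 2 * r^2 / (r^2 + (1 - r)^2)
      r_det <- n[2] + n[4] + n[6] + n[8] + 2 * (n[3] + n[7])
      r <- min(max((r_det + n[5] * w) / (2 * sum(n)), 0), 0.5)
    }
  }
})

test_that("pairwise statistics are symmetric and bounded", {
  sim <- clean_sim(seed = 71, n_chr = 2, m = 6, n_f2 = 80)
  qc <- screen_markers(sim$genotypes)
  pl <- pairwise_linkage(qc$codes)
  expect_true(all(pl$rf >= 0 & pl$rf <= 0.5, na.rm = TRUE))
  expect_true(all(pl$lod >= 0, na.rm = TRUE))
  expect_true(all(pl$ind_lod >= 0, na.rm = TRUE))
  # single-pair path agrees with the vectorised path
  for (k in c(1, 10, 30)) {
    est <- estimate_rf_em(qc$codes[pl$marker1[k], ], qc$codes[pl$marker2[k], ])
    expect_equal(est$rf, pl$rf[k], tolerance = 1e-6)
    expect_equal(est$ind_lod, pl$ind_lod[k], tolerance = 1e-6)
  }
})

test_that("pairs with fewer than two complete individuals are flagged", {
  codes <- rbind(m1 = c("a", NA, NA, "b"), m2 = c(NA, "h", "h", NA))
  colnames(codes) <- paste0("F2_", 1:4)
  pl <- pairwise_linkage(codes)
  expect_true(is.na(pl$rf))
  expect_true(is.na(pl$ind_lod))
})

test_that("grouping is a partition with threshold monotonicity", {
  sim <- clean_sim(seed = 73, n_chr = 3, m = 10, n_f2 = 150)
  qc <- screen_markers(sim$genotypes)
  pl <- pairwise_linkage(qc$codes)
  markers <- rownames(qc$codes)
  p_low <- group_markers(pl, 5, markers = markers)
  p_high <- group_markers(pl, 15, markers = markers)
  expect_setequal(p_low$marker, markers)
  expect_equal(anyDuplicated(p_low$marker), 0)
  # raising the threshold never merges two separated groups
  key <- function(p) setNames(p$group, p$marker)
  kl <- key(p_low); kh <- key(p_high)
  for (pair in combn(markers[1:12], 2, simplify = FALSE)) {
    if (kl[pair[1]] != kl[pair[2]])
      expect_false(kh[pair[1]] == kh[pair[2]])
  }
  # a threshold above every pairwise LOD leaves all singletons
  p_top <- group_markers(pl, max(pl$ind_lod, na.rm = TRUE) + 1,
                         markers = markers)
  expect_equal(max(p_top$group), length(markers))
  # true chromosomes are recovered at a moderate threshold
  truth <- sim$truth$map
  j <- merge(p_low, truth[, c("marker", "chrom")])
  expect_equal(adjusted_rand(table(j$group, j$chrom)), 1)
})

test_that("duplicated markers land in one group at any reachable threshold", {
  x <- rep(c("a", "h", "b"), times = c(25, 50, 25))
  codes <- rbind(m1 = x, m2 = x, m3 = x)
  colnames(codes) <- sprintf("F2_%03d", 1:100)
  pl <- pairwise_linkage(codes)
  p <- group_markers(pl, floor(min(pl$ind_lod)), markers = rownames(codes))
  expect_equal(max(p$group), 1)
})

test_that("three-marker ordering matches the exhaustive-order oracle", {
  pl <- tibble::tibble(
    marker1 = c("m1", "m2", "m1"), marker2 = c("m2", "m3", "m3"),
    n = 100, rf = c(0.10, 0.10, 0.18), lod = c(12, 12, 8),
    ind_lod = c(12, 12, 8))
  og <- order_group(c("m1", "m2", "m3"), pl)
  expect_equal(og$marker[2], "m2") # shares both 0.10 fractions
  # exhaustive check over the three distinct orders
  obj <- function(ord) {
    d <- c(m1m2 = kosambi_cM(0.10), m2m3 = kosambi_cM(0.10),
           m1m3 = kosambi_cM(0.18))
    w <- c(12, 12, 8)
    pos <- setNames(numeric(3), ord)
    key12 <- paste0(sort(ord[1:2]), collapse = "")
    key23 <- paste0(sort(ord[2:3]), collapse = "")
    dd <- c(m1m2 = d[["m1m2"]], m2m3 = d[["m2m3"]], m1m3 = d[["m1m3"]])
    adj <- function(a, b) dd[[paste0(sort(c(a, b)), collapse = "")]]
    pos[2] <- adj(ord[1], ord[2]); pos[3] <- pos[2] + adj(ord[2], ord[3])
    names(pos) <- ord
    sum(w * (abs(pos[c("m1", "m2", "m1")] - pos[c("m2", "m3", "m3")]) -
               dd)^2)
  }
  orders <- list(c("m1", "m2", "m3"), c("m2", "m1", "m3"), c("m1", "m3", "m2"))
  scores <- vapply(orders, obj, 0)
  expect_equal(orders[[which.min(scores)]][2], og$marker[2])
})

test_that("two-marker groups span the Kosambi distance of their rf", {
  x <- rep(c("a", "h", "b"), times = c(24, 50, 26))
  y <- x; y[c(1, 30, 60)] <- c("h", "a", "h")
  codes <- rbind(mA = x, mB = y)
  colnames(codes) <- sprintf("F2_%03d", seq_along(x))
  pl <- pairwise_linkage(codes)
  og <- order_group(c("mA", "mB"), pl)
  expect_equal(max(og$pos_cM), kosambi_cM(pl$rf[1]))
})

test_that("reversing a group leaves the ordering objective unchanged", {
  sim <- clean_sim(seed = 79, n_chr = 1, m = 12, n_f2 = 120)
  qc <- screen_markers(sim$genotypes)
  pl <- pairwise_linkage(qc$codes)
  og <- order_group(rownames(qc$codes), pl)
  # canonical orientation: lexicographically smaller terminal first
  expect_true(og$marker[1] < og$marker[nrow(og)])
  expect_true(all(diff(og$pos_cM) >= 0))
  expect_equal(og$pos_cM[1], 0)
})

test_that("a planted bridge between chromosomes is split off again", {
  sim <- clean_sim(seed = 83, n_chr = 2, m = 12, n_f2 = 150)
  qc <- screen_markers(sim$genotypes)
  pl <- pairwise_linkage(qc$codes)
  truth <- sim$truth$map
  # plant one spurious high-LOD pair joining the two chromosomes
  m1 <- truth$marker[truth$chrom == 1][1]
  m2 <- truth$marker[truth$chrom == 2][1]
  k <- which(pl$marker1 == min(m1, m2) & pl$marker2 == max(m1, m2))
  pl$ind_lod[k] <- 8
  fused <- group_markers(pl, 5, markers = rownames(qc$codes))
  expect_equal(max(fused$group), 1)
  sp <- split_group(rownames(qc$codes), pl, min_markers = 10)
  expect_true(sp$split)
  got <- lapply(sp$groups, sort)
  want <- unname(lapply(split(truth$marker, truth$chrom), sort))
  expect_true(identical(got, want) || identical(got, rev(want)))
  # a uniform single chromosome stays unsplit and flagged
  one <- truth$marker[truth$chrom == 1]
  sp1 <- split_group(one, pl[pl$marker1 %in% one & pl$marker2 %in% one, ],
                     min_markers = 5)
  expect_false(sp1$split)
})

test_that("distal trimming removes sparse terminal markers and is idempotent", {
  g <- tibble::tibble(marker = sprintf("m%02d", 1:21),
                      pos_cM = c(seq(0, 19, by = 1), 60))
  t1 <- trim_distal(g)
  expect_equal(attr(t1, "removed"), "m21")
  expect_equal(nrow(t1), 20)
  t2 <- trim_distal(t1)
  expect_equal(nrow(t2), 20)
  expect_equal(attr(t2, "removed"), character(0))
  # uniform spacing is untouched
  u <- tibble::tibble(marker = sprintf("m%02d", 1:10), pos_cM = 0:9)
  expect_equal(nrow(trim_distal(u)), 10)
})

test_that("build_map recovers chromosomes and conserves markers in the audit", {
  sim <- simulate_cross(sim_config(
    n_chromosomes = 4, markers_per_chromosome = 20, chrom_length_cM = 50,
    n_f2 = 170, trait_locus = NULL, seed = 89))
  qc <- screen_markers(sim$genotypes)
  gm <- build_map(qc)
  expect_equal(max(gm$map$group), 4)
  j <- merge(gm$map, sim$truth$map[, c("marker", "chrom")])
  expect_gte(adjusted_rand(table(j$group, j$chrom)), 0.95)
  # audit conservation: placed + eliminated = retained input
  audited <- unlist(strsplit(gm$audit$markers, ";"))
  audited <- audited[nzchar(audited)]
  expect_setequal(c(gm$map$marker, audited), rownames(qc$codes))
  expect_equal(anyDuplicated(gm$map$marker), 0)
})

test_that("map summaries report the documented quantities", {
  g52 <- tibble::tibble(group = 1, marker = sprintf("m%03d", 1:52),
                        pos_cM = seq(0, 67.061, length.out = 52))
  s <- map_summary(g52)
  expect_equal(round(s$groups$mean_intermarker_cM, 3), 1.315)
  two <- tibble::tibble(group = 1, marker = c("a", "b"), pos_cM = c(0, 10))
  expect_equal(map_summary(two)$groups$mean_intermarker_cM, 10)
  big <- tibble::tibble(group = 1, marker = sprintf("m%04d", 1:2235),
                        pos_cM = seq(0, 2110.7, length.out = 2235))
  expect_equal(round(map_summary(big)$totals$density_per_cM, 2), 1.06)
})
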
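test_that("hit tables parse, filter by e-value, and report malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f)
  expect_equal(nrow(read_hit_table(f)), 0)

  h <- make_hits(c("chr1", "chr2"), c(1e-20, 15), c(98, 95))
  write_hit_table(h, f)
  got <- read_hit_table(f, evalue_cutoff = 10)
  expect_equal(nrow(got), 1) # e-value 15 dropped at cutoff 10
  expect_equal(got$sseqid, "chr1")

  writeLines(c("q1\tchr1\tnot_enough_fields"), f)
  expect_error(read_hit_table(f), "line 1.*12 fields")
  writeLines(c(paste(c("q1", "chr1", "xx", rep("1", 9)), collapse = "\t")), f)
  expect_error(read_hit_table(f), "non-numeric")
})

test_that("per-target collapse keeps the single best alignment per pairing", {
  h1 <- make_hits("chr6", 1e-20, 98)
  expect_equal(collapse_per_target(h1), h1)

  # same pairing twice: the lower e-value wins
  h2 <- make_hits(c("chr6", "chr6"), c(1e-5, 1e-20), c(90, 95))
  expect_equal(collapse_per_target(h2)$evalue, 1e-20)

  # allele-pair collapse under a shared marker id: better alignment kept
  h3 <- make_hits(c("chr6", "chr6"), c(1e-12, 1e-15), c(97, 96))
  expect_equal(collapse_per_target(h3)$evalue, 1e-15)

  # e-value tie: identity, then length, then position break it
  h4 <- make_hits(c("chr6", "chr6"), c(1e-10, 1e-10), c(90, 99))
  expect_equal(collapse_per_target(h4)$pident, 99)
})

test_that("resolution follows the five-category decision rules", {
  one <- collapse_per_target(make_hits("chr6", 1e-20, 98))
  expect_equal(resolve_marker(one)$category, "single_robust")

  two <- collapse_per_target(make_hits(c("chr6", "chr3"), c(1e-20, 1e-5),
                                       c(98, 95)))
  r <- resolve_marker(two, support = "chr6")
  expect_equal(r$target, "chr6")
  expect_equal(r$category, "top_supported")

  r <- resolve_marker(two, support = "chr3")
  expect_equal(r$target, "chr3")
  expect_equal(r$category, "not_top_supported")

  r <- resolve_marker(two, support = character())
  expect_equal(r$target, "chr6")
  expect_equal(r$category, "top_unsupported")

  tied <- collapse_per_target(make_hits(c("chr6", "chr3"), c(1e-10, 1e-10),
                                        c(95, 95)))
  r <- resolve_marker(tied, support = character())
  expect_equal(r$category, "unresolved")
  expect_true(is.na(r$target))
})

test_that("resolution matches an independent oracle over all small configurations", {
  targets <- c("T1", "T2", "T3")
  evs <- c(1e-20, 1e-10, 1e-10)
  ids <- c(98, 95, 95)
  supports <- list(character(), "T1", "T2", c("T1", "T2"))
  combos <- list()
  for (n_hits in 1:3) {
    tg <- combn(targets, n_hits, simplify = FALSE)
    for (t in tg) {
      ev_perm <- unique(lapply(
        seq_len(factorial(n_hits)), function(i) {
          p <- sample(seq_len(n_hits))
          list(e = evs[p], i = ids[p])
        }))
      combos <- c(combos, lapply(ev_perm, function(x)
        list(targets = t, e = x$e, i = x$i)))
    }
  }
  withr::with_seed(11, {
    for (cmb in combos) {
      h <- collapse_per_target(make_hits(cmb$targets, cmb$e, cmb$i))
      for (sup in supports) {
        got <- resolve_marker(h, sup)
        want <- resolve_oracle(h, sup)
        expect_equal(got$category, want$cat,
                     info = paste(cmb$targets, cmb$e, collapse = "/"))
        if (!is.na(want$target)) expect_equal(got$target, want$target)
      }
    }
  })
})

test_that("resolution is invariant to hit row order", {
  h <- make_hits(c("chr6", "chr3", "chr9"), c(1e-20, 1e-8, 1e-4),
                 c(98, 95, 92))
  for (perm in list(3:1, c(2, 3, 1))) {
    expect_equal(resolve_marker(collapse_per_target(h[perm, ]), "chr3"),
                 resolve_marker(collapse_per_target(h), "chr3"))
  }
})

test_that("support sets come from single-hit markers of the same group", {
  map <- tibble::tibble(group = c(1, 1, 2), marker = c("q1", "q2", "q3"),
                        pos_cM = c(0, 10, 0))
  hits <- dplyr::bind_rows(
    make_hits("chr6", 1e-30, 99, marker = "q1"),
    make_hits(c("chr6", "chr2"), c(1e-9, 1e-12), c(95, 96), marker = "q2"),
    make_hits("chr4", 1e-25, 98, marker = "q3"))
  sup <- build_support_sets(collapse_per_target(hits), map)
  expect_equal(sup[["1"]]$target, "chr6")
  expect_equal(sup[["2"]]$target, "chr4")
  ra <- resolve_assignments(hits, map, route = "genomic")
  r2 <- ra[ra$qseqid == "q2", ]
  expect_equal(r2$target, "chr6") # supported beats the lower e-value decoy
  expect_equal(r2$category, "not_top_supported")
  expect_equal(r2$supporters, "q1")
})

test_that("markers with hits land in exactly one category", {
  sim <- clean_sim(seed = 113, n_chr = 4, m = 15, n_f2 = 60)
  map <- dplyr::transmute(sim$truth$map, group = chrom, marker, pos_cM)
  hits <- simulate_hit_tables(sim, decoy_rate = 0.5,
                              conserved_fraction = 0.8, seed = 7)
  ra <- resolve_assignments(hits$genomic, map, route = "genomic")
  expect_equal(nrow(ra), length(unique(hits$genomic$qseqid)))
  expect_true(all(ra$category %in% c("single_robust", "top_supported",
                                     "top_unsupported", "not_top_supported",
                                     "unresolved")))
  expect_equal(anyDuplicated(ra$qseqid), 0)
  expect_true(all(is.na(ra$target[ra$category == "unresolved"])))
})

test_that("support logic strictly improves assignment accuracy", {
  sim <- clean_sim(seed = 127, n_chr = 6, m = 25, n_f2 = 60)
  map <- dplyr::transmute(sim$truth$map, group = chrom, marker, pos_cM)
  hits <- simulate_hit_tables(sim, decoy_rate = 0.5,
                              conserved_fraction = 0.9, seed = 13)
  collapsed <- collapse_per_target(hits$genomic)
  with_support <- resolve_assignments(hits$genomic, map, route = "genomic")
  # no-support baseline: resolve every marker against an empty support set
  no_support <- do.call(rbind, lapply(
    split(collapsed, collapsed$qseqid),
    function(h) resolve_marker(h, character())))
  score <- function(a) {
    j <- merge(a[!is.na(a$target), c("qseqid", "target")], hits$truth,
               by.x = "qseqid", by.y = "marker")
    mean(j$target == j$true_target)
  }
  expect_gte(score(with_support), score(no_support))
  # decoys do mislead the no-support baseline somewhere, so the support
  # comparison is not vacuous
  multi <- names(which(table(collapsed$qseqid) > 1))
  expect_gt(length(multi), 10)
})

test_that("route combination prefers supported targets and records provenance", {
  map <- tibble::tibble(group = 1, marker = c("q1", "q2"), pos_cM = c(0, 5))
  ra_genomic <- resolve_assignments(
    make_hits("chr6", 1e-30, 99, marker = "q1"), map, route = "genomic")
  ra_direct <- resolve_assignments(
    make_hits("chr2", 1e-10, 92, marker = "q2"), map, route = "direct")
  comb <- combine_routes(list(ra_genomic, ra_direct), map)
  expect_equal(nrow(comb), 2)
  expect_equal(comb$route[comb$qseqid == "q1"], "genomic")
  expect_equal(comb$route[comb$qseqid == "q2"], "direct")

  # routes disagree; the supported target wins
  ra_g <- resolve_assignments(dplyr::bind_rows(
    make_hits("chr6", 1e-30, 99, marker = "q1"),
    make_hits("chr6", 1e-20, 97, marker = "q2")), map, route = "genomic")
  ra_t <- resolve_assignments(
    make_hits("chr4", 1e-35, 99, marker = "q2"), map, route = "transcript")
  comb2 <- combine_routes(list(ra_g, ra_t), map)
  q2 <- comb2[comb2$qseqid == "q2", ]
  expect_equal(q2$target, "chr6")
  expect_equal(q2$category, "not_top_supported")
})

test_that("flank extraction centres the tag and clips at scaffold ends", {
  expect_equal(unname(extract_flank(100000, 5000)), c(4032, 6031))
  expect_equal(unname(extract_flank(100000, 10)), c(1, 2000))
  expect_equal(unname(extract_flank(500, 300)), c(1, 500))
  f <- extract_flank(100000, 5000)
  expect_true(f["start"] <= 5000 && f["end"] >= 5063)
  expect_error(extract_flank(1000, 2000), "outside")
})

test_that("synteny statistics summarise links and flag strong chromosomes", {
  links <- tibble::tibble(
    marker = sprintf("m%02d", 1:30),
    group = rep(c(1, 2, 3), times = c(12, 12, 6)),
    pos_cM = rep(seq(0, 55, by = 5), length.out = 30),
    chrom = rep(c("Dre1", "Dre2", "Dre3"), times = c(12, 12, 6)),
    pos_bp = seq(1e6, 30e6, length.out = 30),
    category = "single_robust", route = "genomic")
  lens <- tibble::tibble(chrom = paste0("Dre", 1:3), length_bp = c(4e7, 4e7, 2e7))
  st <- synteny_stats(links, lens)
  expect_equal(st$totals$n_links, 30)
  expect_equal(st$totals$mean_links_per_chrom, 10)
  expect_equal(st$per_chrom$links_per_mb,
               st$per_chrom$n_links / (st$per_chrom$length_bp / 1e6))
  expect_true(all(st$per_chrom$strong == c(TRUE, TRUE, FALSE)))
  expect_equal(sum(st$oxford$n), 30)
  # zero links: empty report
  st0 <- synteny_stats(links[0, ])
  expect_equal(st0$totals$n_links, 0)
})

test_that("circos link export writes one well-formed line per link", {
  links <- tibble::tibble(marker = "m1", group = 13L, pos_cM = 12.4,
                          chrom = "Dre6", pos_bp = 24e6,
                          category = "single_robust", route = "genomic")
  f <- withr::local_tempfile()
  write_circos_links(links, f)
  expect_equal(readLines(f), "lg13 12 13 Dre6 24000000 24000001")
})
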
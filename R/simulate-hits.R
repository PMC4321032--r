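#' Simulate tabular alignment (BLAST outfmt-6 style) hit tables
#'
#' Emits 12-column tabular alignments for the three synteny routes (direct
#' 64-bp tag, ~2-kb genomic flank, transcript) against a fictitious target
#' genome with one chromosome per simulated chromosome, so the true
#' marker-to-chromosome correspondence is known. A `conserved_fraction` of
#' markers receive a true-target hit (always the lowest e-value); with
#' probability `decoy_rate` a conserved marker additionally receives 1-2
#' paralog decoy hits on other chromosomes at higher e-values. No query ever
#' has more than three distinct targets.
#'
#' @param truemap either a `gbs_sim` or its `truth$map` tibble (needs columns
#'   `marker`, `chrom`, `pos_cM`).
#' @param decoy_rate probability a conserved marker also gets decoy hits.
#' @param conserved_fraction probability a marker has a detectable homolog;
#'   either a single value for all three routes or a named vector with
#'   entries `direct`, `genomic`, `transcript`.
#' @param seed integer seed.
#' @param bp_per_cM physical scale of the target genome.
#' @return A list with one tibble of [hit-table][read_hit_table] rows per
#'   route (`direct`, `genomic`, `transcript`) and `truth`, a tibble
#'   `(marker, true_target)`.
#' @examples
#' sim <- simulate_cross(sim_config(n_chromosomes = 2,
#'                                  markers_per_chromosome = 6,
#'                                  n_f2 = 10, trait_locus = NULL, seed = 2))
#' hits <- simulate_hit_tables(sim, decoy_rate = 0.3,
#'                             conserved_fraction = 0.8, seed = 2)
#' @export
simulate_hit_tables <- function(truemap, decoy_rate, conserved_fraction,
                                seed, bp_per_cM = 5e5) {
  map <- if (inherits(truemap, "gbs_sim")) truemap$truth$map else truemap
  stopifnot(all(c("marker", "chrom", "pos_cM") %in% names(map)))
  check_prob(decoy_rate, "decoy_rate")
  if (is.null(names(conserved_fraction))) {
    conserved_fraction <- rep_len(conserved_fraction, 3)
    names(conserved_fraction) <- c("direct", "genomic", "transcript")
  }
  for (f in conserved_fraction) check_prob(f, "conserved_fraction")
  n_chr <- max(map$chrom)

  with_seed(stage_seed(seed, "hits"), {
    routes <- list(
      direct = list(len = c(60, 64), emax = c(1e-10, 1e-3)),
      genomic = list(len = c(900, 2000), emax = c(1e-60, 1e-20)),
      transcript = list(len = c(300, 1500), emax = c(1e-40, 1e-10))
    )
    out <- purrr::imap(routes, function(rt, route) {
      keep <- stats::runif(nrow(map)) < conserved_fraction[[route]]
      mk <- map[keep, , drop = FALSE]
      if (nrow(mk) == 0) return(empty_hits())
      n <- nrow(mk)
      len <- round(stats::runif(n, rt$len[1], rt$len[2]))
      ev <- 10^stats::runif(n, log10(rt$emax[1]), log10(rt$emax[2]))
      sstart <- round(mk$pos_cM * bp_per_cM) + 1
      true_hit <- tibble::tibble(
        qseqid = mk$marker,
        sseqid = paste0("Dre", mk$chrom),
        pident = round(stats::runif(n, 88, 100), 2),
        length = len,
        mismatch = round(len * (1 - .data$pident / 100)),
        gapopen = 0L,
        qstart = 1L, qend = len,
        sstart = sstart, send = sstart + len - 1L,
        evalue = signif(ev, 3),
        bitscore = round(2 * len * .data$pident / 100, 1)
      )
      # paralog decoys: 1-2 extra targets, strictly worse e-values
      dec <- which(stats::runif(n) < decoy_rate)
      decoys <- purrr::map_dfr(dec, function(i) {
        k <- sample.int(2L, 1)
        others <- if (n_chr > 1) setdiff(seq_len(n_chr), mk$chrom[i]) else mk$chrom[i]
        tgt <- sample(rep(others, 2), k)
        dl <- round(stats::runif(k, rt$len[1], rt$len[2]))
        dstart <- round(stats::runif(k, 1, 40e6))
        tibble::tibble(
          qseqid = mk$marker[i],
          sseqid = paste0("Dre", tgt),
          pident = round(stats::runif(k, 80, 97), 2),
          length = dl,
          mismatch = round(dl * (1 - .data$pident / 100)),
          gapopen = 0L,
          qstart = 1L, qend = dl,
          sstart = dstart, send = dstart + dl - 1L,
          evalue = signif(pmin(true_hit$evalue[i] * 10^stats::runif(k, 2, 10), 9), 3),
          bitscore = round(1.8 * dl * .data$pident / 100, 1)
        )
      })
      dplyr::arrange(dplyr::bind_rows(true_hit, decoys), .data$qseqid,
                     .data$evalue)
    })
    out$truth <- tibble::tibble(marker = map$marker,
                                true_target = paste0("Dre", map$chrom))
    out
  })
}

empty_hits <- function() {
  tibble::tibble(
    qseqid = character(), sseqid = character(), pident = numeric(),
    length = integer(), mismatch = integer(), gapopen = integer(),
    qstart = integer(), qend = integer(), sstart = numeric(),
    send = numeric(), evalue = numeric(), bitscore = numeric()
  )
}
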
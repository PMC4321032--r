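#' End-to-end pipeline driver
#'
#' Runs the analysis stages in order — simulate (optional), marker QC, map
#' construction, binary-trait QTL scan, synteny resolution, scaffold
#' anchoring — writing each stage's outputs plus a manifest (input hashes,
#' parameters, seed, package version) under `out_dir`. All randomness flows
#' from the single `seed` through named per-stage substreams; re-running
#' with the same seed reproduces every output byte for byte. A stage
#' failure aborts with the stage name.
#'
#' @param config a list as returned by [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of each executed
#'   stage.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  written <- character()
  emit <- function(writer, obj, name) {
    p <- file.path(cfg$out_dir, name)
    writer(obj, p)
    written <<- c(written, p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }

  if ("simulate" %in% cfg$stages) {
    res$sim <- stage("simulate", {
      sim_cfg <- cfg$sim_config %||% sim_config(seed = cfg$seed)
      sim <- simulate_cross(sim_cfg)
      emit(write_genotypes, sim$genotypes, "genotypes.tsv")
      if (!is.null(sim$phenotypes))
        emit(write_phenotypes, sim$phenotypes, "phenotypes.tsv")
      emit(write_marker_scaffolds,
           sim$truth$map[, c("marker", "scaffold", "scaffold_bp")],
           "marker_scaffolds.tsv")
      sim
    })
    genotypes <- res$sim$genotypes
    phenotypes <- res$sim$phenotypes
    scaffolds <- res$sim$truth$map[, c("marker", "scaffold", "scaffold_bp")]
  } else {
    genotypes <- stage("input", read_genotypes(cfg$genotypes))
    phenotypes <- if (!is.null(cfg$phenotypes))
      stage("input", read_phenotypes(cfg$phenotypes)) else NULL
    scaffolds <- if (!is.null(cfg$marker_scaffolds))
      stage("input", read_marker_scaffolds(cfg$marker_scaffolds)) else NULL
  }

  if ("qc" %in% cfg$stages) {
    res$qc <- stage("qc", {
      qc <- screen_markers(genotypes, chi2_cutoff = cfg$chi2_cutoff)
      emit(write_coded, qc, "coded.tsv")
      jsonlite::write_json(qc$report, file.path(cfg$out_dir, "qc_report.json"))
      written <<- c(written, file.path(cfg$out_dir, "qc_report.json"))
      qc
    })
  }

  if ("map" %in% cfg$stages) {
    res$map <- stage("map", {
      gm <- build_map(res$qc, grouping_lod = cfg$grouping_lod,
                      max_lod = cfg$max_lod, rounds = cfg$rounds,
                      min_size = cfg$min_size)
      emit(write_map, gm, "map.tsv")
      write_header_tsv(gm$pairs, file.path(cfg$out_dir, "pairwise.tsv"))
      written <<- c(written, file.path(cfg$out_dir, "pairwise.tsv"))
      gm
    })
  }

  if ("scan" %in% cfg$stages && !is.null(phenotypes)) {
    res$scan <- stage("scan", {
      grid <- genotype_probs(res$map, res$qc$codes, step_cM = cfg$step_cM,
                             epsilon = cfg$epsilon)
      sc <- scanone_binary(phenotypes, grid, methods = cfg$scan_methods)
      thr <- permutation_threshold(phenotypes, grid, method = "hk",
                                   n_perm = cfg$n_perm,
                                   alphas = cfg$alphas, seed = cfg$seed)
      emit(function(o, p) write_header_tsv(as.data.frame(o), p),
           sc, "scan.tsv")
      jsonlite::write_json(thr, file.path(cfg$out_dir, "thresholds.json"))
      written <<- c(written, file.path(cfg$out_dir, "thresholds.json"))
      list(scan = sc, thresholds = thr, grid = grid)
    })
  }

  if ("synteny" %in% cfg$stages) {
    res$synteny <- stage("synteny", {
      hit_sets <- if (!is.null(res$sim)) {
        simulate_hit_tables(res$sim, decoy_rate = cfg$decoy_rate,
                            conserved_fraction = cfg$conserved_fraction,
                            seed = cfg$seed)
      } else {
        list(direct = read_hit_table(cfg$hits_direct, cfg$evalue_cutoff),
             genomic = read_hit_table(cfg$hits_genomic, cfg$evalue_cutoff),
             transcript = read_hit_table(cfg$hits_transcript, cfg$evalue_cutoff))
      }
      ra <- purrr::imap(hit_sets[c("direct", "genomic", "transcript")],
                        function(h, route)
                          resolve_assignments(h, res$map, route = route))
      comb <- combine_routes(ra, res$map)
      links <- synteny_links(comb, res$map)
      stats <- synteny_stats(links)
      emit(write_header_tsv, comb, "assignments.tsv")
      emit(write_circos_links, links, "circos_links.txt")
      list(routes = ra, combined = comb, links = links, stats = stats)
    })
  }

  if ("anchor" %in% cfg$stages && !is.null(scaffolds)) {
    res$anchor <- stage("anchor", {
      an <- anchor_scaffolds(res$map, scaffolds)
      emit(function(o, p) write_header_tsv(o$anchors, p), an, "anchors.tsv")
      jsonlite::write_json(an$summary, file.path(cfg$out_dir, "anchor_summary.json"))
      written <<- c(written, file.path(cfg$out_dir, "anchor_summary.json"))
      an
    })
  }

  manifest <- list(
    package = "cavemapr",
    version = as.character(utils::packageVersion("cavemapr")),
    seed = cfg$seed,
    stages = cfg$stages,
    parameters = cfg[setdiff(names(cfg), c("out_dir", "stages"))],
    outputs = as.list(tools::md5sum(written))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(res)
}

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param stages stages to execute, in pipeline order.
#' @param seed single pipeline seed; per-stage substreams are derived from
#'   it.
#' @param sim_config optional [sim_config()] for the simulate stage.
#' @param genotypes,phenotypes,marker_scaffolds input paths when the
#'   simulate stage is not run.
#' @param hits_direct,hits_genomic,hits_transcript alignment-file paths for
#'   the synteny stage on real data.
#' @param chi2_cutoff,grouping_lod,max_lod,rounds,min_size,step_cM,epsilon,
#'   scan_methods,n_perm,alphas,evalue_cutoff,decoy_rate,conserved_fraction
#'   stage parameters, passed through to the stage functions.
#' @return A configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(out_dir,
                            stages = c("simulate", "qc", "map", "scan",
                                       "synteny", "anchor"),
                            seed = 1,
                            sim_config = NULL,
                            genotypes = NULL, phenotypes = NULL,
                            marker_scaffolds = NULL,
                            hits_direct = NULL, hits_genomic = NULL,
                            hits_transcript = NULL,
                            chi2_cutoff = 50, grouping_lod = NULL,
                            max_lod = 50, rounds = 3, min_size = 10,
                            step_cM = 1, epsilon = 0.001,
                            scan_methods = c("mr", "em", "hk"),
                            n_perm = 1000, alphas = c(0.05, 0.001),
                            evalue_cutoff = 10, decoy_rate = 0.2,
                            conserved_fraction = c(direct = 0.05,
                                                   genomic = 0.4,
                                                   transcript = 0.2)) {
  as.list(environment())
}
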
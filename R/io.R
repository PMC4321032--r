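# File formats. All tables are tab-separated with a single '#'-prefixed
# header line. Missing genotype calls are written "NA" in genotype files
# and "-" in coded files.

write_header_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

read_header_tsv <- function(path, na = "NA") {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#"))
    abort(paste0(path, ": expected a '#'-prefixed header line"))
  header <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1, col.names = header,
                          na.strings = na, colClasses = "character",
                          check.names = FALSE, quote = "",
                          comment.char = "")
  tibble::as_tibble(df)
}

#' Read and write genotype matrices
#'
#' Genotype files are marker-by-individual TSVs: a `#`-prefixed header of
#' individual ids (founder panels `S1..`, `C1..`, F1s `F1_..`, F2s
#' `F2_..`), one row per marker, calls in IUPAC code with `NA` for missing.
#' Any symbol outside the call alphabet raises an error naming the row and
#' column.
#'
#' @param genotypes genotype tibble (see [simulate_cross()]).
#' @param path file path.
#' @return `read_genotypes()` returns the genotype tibble;
#'   `write_genotypes()` returns `path` invisibly.
#' @export
write_genotypes <- function(genotypes, path) write_header_tsv(genotypes, path)

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  g <- read_header_tsv(path)
  if (names(g)[1] != "marker") abort("first genotype column must be 'marker'")
  calls <- as.matrix(g[, -1])
  bad <- !is.na(calls) & !(calls %in% .call_alphabet)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("illegal genotype symbol '%s' at row %d (marker %s), column %s",
                  calls[w[1], w[2]], w[1], g$marker[w[1]],
                  colnames(calls)[w[2]]))
  }
  g
}

#' Read and write coded-marker tables
#'
#' Coded files carry one row per marker: id, assigned alleles, chi-square,
#' status, then one `a`/`h`/`b`/`-` code per F2 individual.
#'
#' @param qc a `marker_qc` object.
#' @param path file path.
#' @return `read_coded()` returns a list `(markers, codes)`;
#'   `write_coded()` returns `path` invisibly.
#' @export
write_coded <- function(qc, path) {
  stopifnot(inherits(qc, "marker_qc"))
  m <- qc$markers
  codes_all <- matrix("-", nrow(m), ncol(qc$codes),
                      dimnames = list(m$marker, colnames(qc$codes)))
  codes_all[rownames(qc$codes), ] <- ifelse(is.na(qc$codes), "-", qc$codes)
  df <- dplyr::bind_cols(
    m[, c("marker", "surface_allele", "cave_allele", "chi2", "status")],
    tibble::as_tibble(codes_all)
  )
  write_header_tsv(df, path)
}

#' @rdname write_coded
#' @export
read_coded <- function(path) {
  df <- read_header_tsv(path)
  fixed <- c("marker", "surface_allele", "cave_allele", "chi2", "status")
  if (!all(fixed %in% names(df))) abort("not a coded-marker file")
  codes <- as.matrix(df[, setdiff(names(df), fixed)])
  codes[codes == "-"] <- NA_character_
  rownames(codes) <- df$marker
  markers <- df[, fixed]
  markers$chi2 <- as.numeric(markers$chi2)
  list(markers = markers,
       codes = codes[df$status == "retained", , drop = FALSE])
}

#' Read and write map, phenotype and marker-scaffold tables
#'
#' Simple three-column TSV dialects: map files `(group, marker, pos_cM)`,
#' phenotype files `(individual, phenotype)` with a 0/1 trait score, and
#' marker-scaffold files `(marker, scaffold, scaffold_bp)`.
#'
#' @param map,phenotypes,marker_scaffolds the corresponding tibbles (a
#'   `genetic_map` is accepted for `map`).
#' @param path file path.
#' @return Readers return tibbles with typed columns; writers return
#'   `path` invisibly.
#' @export
write_map <- function(map, path) {
  tbl <- if (inherits(map, "genetic_map")) map$map else map
  write_header_tsv(tbl, path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- read_header_tsv(path)
  if (!all(c("group", "marker", "pos_cM") %in% names(df)))
    abort("not a map file")
  df$group <- as.integer(df$group)
  df$pos_cM <- as.numeric(df$pos_cM)
  df
}

#' @rdname write_map
#' @export
write_phenotypes <- function(phenotypes, path)
  write_header_tsv(phenotypes, path)

#' @rdname write_map
#' @export
read_phenotypes <- function(path) {
  df <- read_header_tsv(path)
  if (!all(c("individual", "phenotype") %in% names(df)))
    abort("not a phenotype file")
  df$phenotype <- as.integer(df$phenotype)
  df
}

#' @rdname write_map
#' @export
write_marker_scaffolds <- function(marker_scaffolds, path)
  write_header_tsv(marker_scaffolds, path)

#' @rdname write_map
#' @export
read_marker_scaffolds <- function(path) {
  df <- read_header_tsv(path)
  if (!all(c("marker", "scaffold", "scaffold_bp") %in% names(df)))
    abort("not a marker-scaffold file")
  df$scaffold_bp <- as.numeric(df$scaffold_bp)
  df
}

#' Write a 12-column tabular alignment file
#'
#' @param hits hit tibble (see [read_hit_table()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' Minimal FASTA support for the simulator's tag and scaffold sequences:
#' wrapped and unwrapped files read identically.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @param width line-wrap width for writing.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort(paste0(path, ": not a FASTA file"))
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  setNames(seqs, sub("^>", "", lines[hdr]))
}
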
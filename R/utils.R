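# IUPAC ambiguity codes for the six biallelic heterozygote classes
.het_codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
.nucleotides <- c("A", "C", "G", "T")

#' IUPAC heterozygote code for an unordered nucleotide pair
#'
#' @param a1,a2 single nucleotides ("A", "C", "G" or "T"); order is ignored.
#' @return The one-letter IUPAC code ("M", "R", "W", "S", "Y" or "K").
#' @examples
#' het_code("A", "G") # "R"
#' @export
het_code <- function(a1, a2) {
  key <- paste0(pmin(a1, a2), pmax(a1, a2))
  out <- .het_codes[key]
  if (anyNA(out)) abort("het_code() needs two distinct nucleotides from A/C/G/T")
  unname(out)
}

is_het_code <- function(x) x %in% .het_codes

# full call alphabet for genotype matrices
.call_alphabet <- c(.nucleotides, unname(.het_codes))

# deterministic per-stage seed derived from a single pipeline seed.
# Kept below 2^31 - 1 so it is always a valid R integer.
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, qc = 23L, map = 37L, scan = 53L, perm = 71L,
            synteny = 89L, anchor = 97L, hits = 101L)
  k <- offs[[stage]]
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483629)
}

# local RNG scope: runs expr with a given seed, restoring the caller's
# RNG state afterwards so seeded helpers do not clobber the session stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# checked probability / count accessors for configuration lists
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  as.numeric(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}
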
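#' Kosambi map function and its inverse
#'
#' The Kosambi map function converts a recombination fraction \eqn{r} into a
#' genetic distance that accounts for moderate crossover interference:
#' \deqn{d = 25 \ln\frac{1 + 2r}{1 - 2r} \textrm{ cM},}
#' i.e. \eqn{\frac14 \ln((1+2r)/(1-2r))} Morgans. Its inverse is
#' \eqn{r = \frac12 \tanh(d / 50)}.
#'
#' @param r recombination fraction(s) in \eqn{[0, 0.5)}.
#' @param d genetic distance(s) in centimorgans, \eqn{d \ge 0}.
#' @param cap if `TRUE`, values of `r` at or above 0.5 are capped just below
#'   0.5 instead of raising an error (useful when mapping noisy pairwise
#'   estimates).
#' @return `kosambi_cM()` returns distances in cM; `kosambi_inverse()` returns
#'   recombination fractions in \eqn{[0, 0.5)}.
#' @examples
#' kosambi_cM(0.25)        # 25 * log(3) = 27.465 cM
#' kosambi_inverse(27.465) # 0.25
#' @export
kosambi_cM <- function(r, cap = FALSE) {
  if (any(r < 0, na.rm = TRUE)) abort("recombination fractions must be >= 0")
  if (any(r >= 0.5, na.rm = TRUE)) {
    if (!cap) abort("recombination fraction >= 0.5 has no finite Kosambi distance")
    r <- pmin(r, 0.5 - 1e-7)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @export
kosambi_inverse <- function(d) {
  if (any(d < 0, na.rm = TRUE)) abort("map distances must be >= 0")
  0.5 * tanh(d / 50)
}
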
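#' Kosambi map function and its inverse
#'
#' Convert a recombination fraction to a Kosambi map distance in centiMorgans,
#' \eqn{d = 25 \ln[(1+2r)/(1-2r)]}, or back. Kosambi distances allow partial
#' crossover interference and are the convention for plant linkage maps.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @param d map distance(s) in cM.
#' @return `kosambi()` returns cM; `kosambiInverse()` returns recombination
#'   fractions in \[0, 0.5).
#' @examples
#' kosambi(0.2)            # ~21.18 cM
#' kosambiInverse(kosambi(0.3))
#' @export
kosambi <- function(r) {
  stopifnot(all(is.na(r) | (r >= 0 & r < 0.5)))
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambiInverse <- function(d) {
  stopifnot(all(is.na(d) | d >= 0))
  0.5 * tanh(d / 50)
}

#' Haldane map function and its inverse
#'
#' No-interference map function, \eqn{d = -50 \ln(1 - 2r)}. The simulator
#' places crossovers under this model.
#'
#' @inheritParams kosambi
#' @return cM for `haldane()`, recombination fraction for `haldaneInverse()`.
#' @export
haldane <- function(r) {
  stopifnot(all(is.na(r) | (r >= 0 & r < 0.5)))
  -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @export
haldaneInverse <- function(d) {
  stopifnot(all(is.na(d) | d >= 0))
  0.5 * (1 - exp(-d / 50))
}

## Genotype call codes used throughout: 0 = homozygous reference, 1 =
## heterozygous, 2 = homozygous alternate, NA = missing. Kept as plain
## integers so call/depth matrices stay numeric.
GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

## Parental configuration labels for a double pseudo-testcross.
CONFIG_LEVELS <- c("ABxAA", "AAxAB", "ABxAB", "UNINFORMATIVE", "PARENT_MISSING")

## x*log(y) with the 0*log(0) = 0 convention, base 10.
xlog10 <- function(x, y) {
  out <- numeric(length(x))
  nz <- !is.na(x) & x > 0
  out[nz] <- x[nz] * log10(y[nz])
  out[is.na(x)] <- NA_real_
  out
}

## Deterministic RNG scope: evaluates expr with a local seed without
## disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a stream-specific child seed
#'
#' Deterministic scramble mapping a master seed and a stream index to a
#' seed below 2^31; used so that each pipeline stage consumes an
#' independent, reproducible random stream.
#'
#' @param seed integer master seed.
#' @param stream integer stream index.
#' @return A numeric seed in \[0, 2^31).
#' @export
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1299709) %% 2147483647
}
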
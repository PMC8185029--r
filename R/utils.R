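#' @importFrom methods is new validObject slot show
#' @importFrom stats fft mad pnorm pt qnorm rnorm runif sd var predict
NULL

# round half away from zero; base round() is banker's, which would make
# second -> sample conversions depend on parity
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

ifft <- function(z) stats::fft(z, inverse = TRUE) / length(z)

# smallest power of two >= n
nextPow2 <- function(n) 2^ceiling(log2(n))

.stageStreams <- c(
  simulate = 1L, preprocess = 2L, spectral = 3L,
  sme = 4L, decode = 5L, permute = 6L
)

#' Derive a per-stage seed from a master seed
#'
#' One master seed feeds a named-stream splitter so that pipeline stages can
#' be re-run independently with identical randomness. The scheme is
#' `(master * 48271 + 7919 * stream) mod (2^31 - 1)`, with streams numbered
#' simulate = 1, preprocess = 2, spectral = 3, sme = 4, decode = 5,
#' permute = 6.
#'
#' @param master integer master seed.
#' @param stage stage name, one of `"simulate"`, `"preprocess"`,
#'   `"spectral"`, `"sme"`, `"decode"`, `"permute"`.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
stageSeed <- function(master, stage) {
  stage <- match.arg(stage, names(.stageStreams))
  s <- (abs(as.numeric(master)) * 48271 + 7919 * .stageStreams[[stage]]) %%
    2147483647
  as.integer(max(1, s))
}

# stable hash of a configuration (recorded in every results bundle)
configHash <- function(x) rlang::hash(configAsList(x))
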
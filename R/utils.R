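logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 0.35 -> 0.4 at one
#' decimal), the convention used for printed percentage reports. Base R's
#' `round()` rounds ties to even, which would render e.g. 50.25 as 50.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(77.35, 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# One master seed drives every simulation stage through fixed per-stage
# offsets, so partial re-runs (e.g. regenerating only the qPCR table) are
# reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stages <- c("annotation", "effects", "intensities", "genesets", "qpcr")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown simulation stage: ", stage)
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483647)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
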
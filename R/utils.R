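#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor quantile rnorm runif rbinom plogis qlogis pnorm qnorm
#'   sd median predict var cov dist complete.cases setNames
#' @importFrom utils read.csv write.csv write.table read.table head modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib ginscreen, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' All stochastic stages (splitting, resampling, weight initialisation,
#' minibatching) draw their seed from one master seed through this fixed
#' rule, so that a single integer reproduces an entire run.  Results stay
#' below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(master, stage) {
  offsets <- c(
    cohort = 11L, cohort_test = 13L, split = 17L, made = 23L,
    u1 = 31L, u2 = 37L, smote = 41L, baseline = 53L, eval = 59L,
    attention = 61L
  )
  off <- offsets[[stage]] %||% (sum(utf8ToInt(stage)) %% 997L)
  as.integer((as.numeric(master) %% 1e6 * 1009 + off * 97) %% 2147483646) + 1L
}

# 32-bit polynomial rolling hash of a character scalar; used to fingerprint
# vocabularies, edge matrices and run configs in artifact metadata.  Not
# cryptographic -- it only needs to detect accidental artifact mixing.
content_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Percentage formatting used in cohort summaries: half-up rounding to three
# decimals, then half-up to two, matching the convention of reporting a
# 3-decimal rate and rounding it for display (0.9647% -> 0.965% -> 0.97%).
round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

format_pct <- function(count, n) {
  pct <- 100 * count / n
  round_half_up(round_half_up(pct, 3), 2)
}

stop_ginscreen <- function(..., class) {
  stop(structure(
    class = c(class, "ginscreen_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
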
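#' @useDynLib brainsexmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom density optim cor sd quantile
#' @importFrom utils write.csv read.csv
NULL

#' Derive a stage-specific seed from a global seed
#'
#' Stage seeds are obtained by mixing the global seed with a hash of the
#' stage name, so that individual pipeline stages can be re-run in isolation
#' while remaining reproducible from a single `--seed`.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% m
  out <- (abs(seed) %% m * 48271 + h + 1) %% m
  as.integer(out + (out == 0))
}

# Round half away from zero at `digits` decimals (printed-table convention;
# base round() uses banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable content hash of a configuration (hex string) for run manifests
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(lapply(unclass(cfg), unclass)),
                        auto_unbox = TRUE, digits = NA)
  m <- 2147483647
  h <- 0
  for (cc in utf8ToInt(as.character(s))) h <- (h * 131 + cc) %% m
  sprintf("%08x", as.integer(h))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("bsm_degenerate_input", "error")))
}
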
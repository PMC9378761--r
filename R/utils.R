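`%||%` <- function(a, b) if (is.null(a)) b else a

stop_eafg <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomized components draw from streams derived from one master seed,
#' so modules can be re-run independently and still reproduce the pipeline.
#' The derived seed is kept within the 32-bit signed integer range.
#'
#' @param seed Master integer seed.
#' @param label Character stream label (e.g. `"genotypes"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(seed) * 2654435 + h) %% 2147483647) + 1L
}

## Polynomial rolling hash over a string; used for config fingerprints in
## run manifests (not cryptographic, just change detection).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", h)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1
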
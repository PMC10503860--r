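# Shared internal helpers: seed derivation, small numeric utilities.

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.4375

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from one global seed
#'
#' All stochastic stages of the pipeline draw their seed from a single global
#' integer through this deterministic hash, so that one `--seed` reproduces
#' every stage while stages remain statistically decoupled.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label, e.g. `"genotypes"`.
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer(h + 1)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# FNV-1a over a character serialization; used for provenance config hashes.
fnv1a_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, vec.len = 1e6)), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
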
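#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic component of the pipeline (each simulated variant, each
#' resampling replicate, each fold assignment) receives its own seed derived
#' deterministically from a single master seed and a string label, so
#' sub-computations are independently reproducible and inserting a new
#' stochastic step never shifts the stream of an existing one.
#'
#' The derivation is a 31-bit multiplicative string hash folded into the
#' master seed; results always lie in `[1, 2^31 - 2]`.
#'
#' @param seed Master seed (single integer-valued number).
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (lab in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code) %% m
    }
    h <- (h * 31 + 7) %% m  # separator so c("ab","c") != c("a","bc")
  }
  as.integer(h %% (m - 1)) + 1L
}

# Internal: run `expr` with a local RNG state seeded at `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Internal: stop() with a consistent error class for domain errors.
domain_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("metpgx_domain_error", "error")))
}

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("metpgx_config_error", "error")))
}
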
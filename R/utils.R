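#' @keywords internal
"_PACKAGE"

# Design constants: the signed morph axis (happy positive) and the closed
# response vocabulary.
MORPH_LEVELS <- c(-80, -40, -20, -10, 0, 10, 20, 40, 80)
RESPONSES <- c("happy", "angry", "omitted")

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-participant substream: participant i's seed depends only on
# (master, i), so growing a cohort never reshuffles existing participants.
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483647 * 48271 + index * 7919) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
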
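# Internal helpers shared across the pipeline.

#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit seed derivation: mixes a base seed with any number of
# integer/string tokens so that every stage of the pipeline can be re-seeded
# independently from one global seed. Arithmetic stays below 2^53 so it is
# exact in doubles.
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1
  x <- (abs(seed) %% m)
  for (tok in list(...)) {
    codes <- if (is.character(tok)) utf8ToInt(paste(tok, collapse = "|")) else as.numeric(tok)
    for (cc in codes) {
      x <- (x * 69069 + (cc %% m) + 1) %% m
    }
  }
  as.integer(x %% (m - 2) + 1)
}

# with a local RNG state so library code never clobbers the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

clip01 <- function(x) pmin(pmax(x, 0), 1)

cg_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "cervigraph_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
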
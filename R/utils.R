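# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Deterministic 31-bit seed from a label
#'
#' FNV-1a style string hash folded to a positive 31-bit integer, used to give
#' every experiment cell its own reproducible seed stream.
#'
#' @param base_seed Integer base seed.
#' @param ... Character/numeric labels identifying the cell (variant, task,
#'   map, repetition, ...).
#' @return A single integer in `[1, 2^31 - 1]`.
#' @examples
#' seed_for(1, "original", "identity", "location", 2)
#' @export
seed_for <- function(base_seed, ...) {
  label <- paste(c(base_seed, ...), collapse = "|")
  bytes <- utf8ToInt(label)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 16777619 multiplication done in double precision, folded mod 2^31
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483646L) + 1L
}

# Stop unless `cond` holds; `fmt` is a sprintf template.
fail_unless <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
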
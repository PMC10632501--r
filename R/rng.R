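#' Derive a child seed from a master seed and a tag path
#'
#' All randomized elements of the pipeline draw from independent RNG streams
#' whose seeds are pure functions of the master seed and a string/integer tag
#' path. Adding a new randomized element therefore never perturbs the stream
#' of any existing element, and a run is bitwise reproducible from its master
#' seed alone.
#'
#' @param seed integer master seed.
#' @param ... tags (strings or integers) identifying the element and
#'   iteration, e.g. `derive_seed(42, "terrain", 3)`.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  tags <- list(...)
  # 31-bit polynomial rolling hash over the utf8 bytes of the tag path
  m <- 2147483647
  h <- as.numeric(seed %% m)
  for (tag in tags) {
    bytes <- utf8ToInt(paste0("/", as.character(tag)))
    for (b in bytes) h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded sub-draws never
#' interfere with each other.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
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

runif1 <- function(range) {
  if (range[1] == range[2]) return(range[1])
  stats::runif(1, range[1], range[2])
}

runif_int <- function(range) {
  lo <- as.integer(range[1]); hi <- as.integer(range[2])
  if (lo == hi) return(lo)
  lo + as.integer(floor(stats::runif(1) * (hi - lo + 1L))) %% (hi - lo + 1L)
}
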
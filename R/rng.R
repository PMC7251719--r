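#' Keyed uniform random stream
#'
#' Stateless counter-based generator: the uniform for a key
#' `(seed, id, stream, counter)` is a pure function of the key, so per-woman
#' substreams are independent of simulation order and batch size. Stream 1 is
#' reserved for natural-history draws and stream 2 for screening attendance
#' and detection, so changing the screening scenario never perturbs natural
#' history — the common-random-numbers contract of the parallel-universe
#' design.
#'
#' @param seed master seed, a non-negative integer below 2^31
#' @param id unit (woman) identifiers, recycled against `counter`
#' @param stream integer stream label (1 = natural history, 2 = screening)
#' @param counter draw index within `(id, stream)`
#' @return numeric vector of U(0,1) draws
#' @examples
#' stream_uniform(42, id = 1:5, stream = 1, counter = 1)
#' @export
stream_uniform <- function(seed, id, stream, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed < 2^31)
  stream_unif_cpp(as.numeric(seed), as.numeric(id), as.integer(stream),
                  as.numeric(counter))
}

# draw-purpose counters, natural-history stream
.CTR <- list(
  death = 1, onset = 2, dest = 3, udwell = 4, path = 5, pdwell = 6,
  ibcdwell = 7,
  # screening stream: start decision in calendar year y uses y - 1900;
  # detection at the k-th screen uses 1000 + k
  start_base = -1900, detect_base = 1000
)

# run code under a temporary R RNG seed, restoring global state after
with_seed_ <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
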
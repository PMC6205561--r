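#' Evaluate code under a temporary RNG seed
#'
#' Sets the global RNG to a known state, evaluates `code`, and restores the
#' previous state, so package functions are deterministic given their `seed`
#' argument without perturbing the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive an independent substream seed from a master seed
#'
#' Each pipeline stage (mosaic synthesis, observer simulation, optics jitter,
#' bootstrap) draws from its own named substream so that adding consumers to
#' one stage never perturbs another. The substream seed is a deterministic
#' hash of the master seed and the stream name, kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name.
#' @return Integer seed for the substream.
#' @keywords internal
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 8191) %% 2147483647)
}
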
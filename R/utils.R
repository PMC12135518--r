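#' @keywords internal
"_PACKAGE"

## Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
## seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## stopifnot with a readable message
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

## log-normal sdlog matched to a printed median and IQR
sdlog_from_iqr <- function(q1, q3) (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
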
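# internal helpers

abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "progmapper_error"),
                      call = sys.call(-1)))
}

# evaluate `expr` under a fixed RNG seed without clobbering the caller's stream
with_seed <- function(seed, expr) {
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

`%||%` <- function(a, b) if (is.null(a)) b else a

euclid <- function(a, b) sqrt(sum((a - b)^2))
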
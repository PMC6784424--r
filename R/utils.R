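# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Last observation carried forward; leading NAs stay NA.
locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  c(NA_real_, x[ok])[cumsum(ok) + 1L]
}

# Validation errors carry their own condition class so the command-line
# wrapper can map them to a dedicated exit code.
stop_validation <- function(...) {
  msg <- paste0(...)
  stop(structure(
    class = c("pbrtqc_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Stable hash of an R object (canonical JSON -> md5), used to stamp pipeline
# outputs so reruns can be matched to their configuration.
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), tf)
  unname(tools::md5sum(tf))
}
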
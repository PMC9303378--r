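# Internal helpers shared across modules.

#' Derive reproducible child seeds from one master seed
#'
#' All stochastic functions in rrasweep thread a single integer seed through
#' this splitting rule: the master seed initialises R's RNG, and `n` child
#' seeds are drawn as uniform integers below 2^31 - 1. Child seeds are logged
#' in output metadata so any individual sample can be regenerated in
#' isolation.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

# run code with a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(seed)) set.seed(as.integer(seed))
  force(code)
}

abort_param <- function(msg) stop(msg, call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_param(sprintf("`%s` must be a single finite number", name))
  }
  ok <- if (strict) x > lower else x >= lower
  if (!ok) {
    abort_param(sprintf(
      "`%s` must be %s %s", name, if (strict) ">" else ">=", lower
    ))
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_param(sprintf("`%s` must be a fraction in [0, 1]", name))
  }
  invisible(x)
}

# provenance comment lines prefixed with "#", written atop output files
provenance_header <- function(...) {
  extra <- c(...)
  c(
    sprintf(
      "# rrasweep %s",
      as.character(utils::packageVersion("rrasweep"))
    ),
    sprintf("# written %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (length(extra)) paste0("# ", extra)
  )
}

write_with_provenance <- function(df, path, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(...), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
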
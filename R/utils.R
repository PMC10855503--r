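#' @keywords internal
"_PACKAGE"

# Classed error so callers can distinguish bad inputs from bugs.
stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("dryopt_invalid_input", "error")))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop_invalid(sprintf("`%s` must be numeric and non-missing", name))
  if (finite && any(!is.finite(x))) stop_invalid(sprintf("`%s` must be finite", name))
  if (positive && any(x <= 0)) stop_invalid(sprintf("`%s` must be > 0", name))
  invisible(x)
}

# Run `code` under a given seed without disturbing the caller's RNG stream.
# A NULL seed leaves the RNG alone (results then depend on the session state).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Path to a shipped plain-text data file.
dryopt_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dryopt")
  if (identical(path, "")) stop("extdata file not found: ", file)
  path
}
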
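# Structured error conditions.  Every user-facing failure carries a subclass
# of "racewaysim_error" so callers (and tests) can discriminate failure modes
# without matching message text.

abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message,
                      class = c(class, "racewaysim_error"),
                      call = call))
}

abort_format     <- function(msg) abort(msg, "racewaysim_format_error")
abort_validation <- function(msg) abort(msg, "racewaysim_validation_error")
abort_domain     <- function(msg) abort(msg, "racewaysim_domain_error")
abort_config     <- function(msg) abort(msg, "racewaysim_config_error")
abort_data_gap   <- function(msg) abort(msg, "racewaysim_data_gap_error")
abort_lookup     <- function(msg) abort(msg, "racewaysim_lookup_error")
abort_io         <- function(msg) abort(msg, "racewaysim_io_error")

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}
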
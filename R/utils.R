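# Internal validation helpers. Errors carry subclasses so callers (and tests)
# can distinguish format, domain and consistency failures.

stop_format <- function(msg) abort(msg, class = "herbqc_format_error")
stop_domain <- function(msg) abort(msg, class = "herbqc_domain_error")
stop_validation <- function(msg) abort(msg, class = "herbqc_validation_error")
stop_ambiguity <- function(msg) abort(msg, class = "herbqc_ambiguity_error")
stop_insufficient <- function(msg) abort(msg, class = "herbqc_insufficient_data_error")
stop_consistency <- function(msg) abort(msg, class = "herbqc_consistency_error")
stop_config <- function(msg) abort(msg, class = "herbqc_config_error")

check_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be positive and non-missing.", what))
  }
  invisible(x)
}

check_nonnegative <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop_domain(sprintf("`%s` must be non-negative and non-missing.", what))
  }
  invisible(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
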
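# Internal condition helpers: every user-facing error carries a subclass so
# callers (and tests) can distinguish format, validation and domain problems.

stop_format <- function(msg) abort(msg, class = "bibtrend_format_error")
stop_validation <- function(msg) abort(msg, class = "bibtrend_validation_error")
stop_domain <- function(msg) abort(msg, class = "bibtrend_domain_error")
stop_lookup <- function(msg) abort(msg, class = "bibtrend_lookup_error")
stop_config <- function(msg) abort(msg, class = "bibtrend_config_error")
stop_fit <- function(msg) abort(msg, class = "bibtrend_fit_error")

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
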
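# Classed conditions so callers (and the CLI) can distinguish configuration
# mistakes from model-validity violations (target leaving the imaging view).

cbct_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cbct_error", "error")))
}

config_error <- function(msg) cbct_abort(msg, "cbct_config_error")
fov_error <- function(msg) cbct_abort(msg, "cbct_fov_error")
domain_error <- function(msg) cbct_abort(msg, "cbct_domain_error")
comparison_error <- function(msg) cbct_abort(msg, "cbct_comparison_error")
range_error <- function(msg) cbct_abort(msg, "cbct_range_error")
parse_error <- function(msg) cbct_abort(msg, "cbct_parse_error")

check_number <- function(x, name, lower = -Inf, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    config_error(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) config_error(sprintf("`%s` must be finite", name))
  if (strict && x <= lower) {
    config_error(sprintf("`%s` must be > %g", name, lower))
  }
  if (!strict && x < lower) {
    config_error(sprintf("`%s` must be >= %g", name, lower))
  }
  invisible(x)
}
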
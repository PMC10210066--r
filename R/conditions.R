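# Classed conditions so callers can distinguish failure modes programmatically.

zc_stop <- function(msg, type = "validation", ...) {
  stop(errorCondition(msg, ..., class = c(paste0("zincomp_", type),
                                          "zincomp_error", "error", "condition")))
}

#' @noRd
check_number <- function(x, name, min = -Inf, strict_min = NULL, len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    zc_stop(sprintf("`%s` must be finite and numeric", name))
  if (!is.null(len) && length(x) != len)
    zc_stop(sprintf("`%s` must have length %d", name, len))
  if (any(x < min))
    zc_stop(sprintf("`%s` must be >= %g", name, min))
  if (!is.null(strict_min) && any(x <= strict_min))
    zc_stop(sprintf("`%s` must be > %g", name, strict_min))
  invisible(x)
}
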
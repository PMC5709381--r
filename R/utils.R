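# internal helpers shared across modules

mc_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mc_error"), call = call))
}

mc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "mc_warning")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# positive scalar check used by most argument validators
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    mc_stop(sprintf("'%s' must be a positive finite scalar", name),
            "mc_argument_error")
  invisible(x)
}
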
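# internal argument checks shared across modules

check_fraction <- function(x, name, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) all(x >= 0) else all(x > 0)
  if (!lo_ok || !all(x < 1)) {
    lo <- if (allow_zero) "[0, 1)" else "(0, 1)"
    rlang::abort(sprintf("`%s` must be a proteome fraction in %s.", name, lo))
  }
  invisible(x)
}

# recycle named numeric arguments to a common length (scalar or equal length)
vctrs_recycle_common <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- !(lengths(args) %in% c(1L, n))
  if (any(bad)) {
    rlang::abort(sprintf(
      "arguments %s cannot be recycled to length %d",
      paste0("`", names(args)[bad], "`", collapse = ", "), n
    ))
  }
  lapply(args, rep_len, length.out = n)
}
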
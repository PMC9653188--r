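# Internal helpers shared across modules.

# Round half away from zero (table-style rounding, unlike base round()'s
# round-half-even). The epsilon guards against values such as 94.55 being
# stored as 94.54999...
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Stop unless `df` has all of `cols`; `what` names the offending table.
.checkCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
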
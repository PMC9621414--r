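`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_prob <- function(x, what, open = TRUE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(!is.finite(x)) || bad) {
    stopf("%s must lie strictly inside (0, 1); got %s", what,
          paste(format(x[!is.finite(x) | x <= 0 | x >= 1]), collapse = ", "))
  }
  invisible(x)
}

# Derive a stream of child seeds from one user seed, staying within the
# 32-bit integer range R requires of set.seed().
child_seeds <- function(seed, n) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

z975 <- stats::qnorm(0.975)
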
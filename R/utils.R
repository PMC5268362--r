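# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

unitVector <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v^2))
  if (n < tol) return(NULL)
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# mm-Hg per kPa
KPA_TO_MMHG <- 7.50062

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
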
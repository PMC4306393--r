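# internal helpers shared across modules

# numerically stable logistic transform; safe for |x| up to ~745 in either
# direction (exp() underflows gracefully to 0 beyond that)
.expit <- function(x) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

.logit <- function(p) log(p) - log1p(-p)

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x)) .stopf("'%s' must be numeric and non-missing", name)
  if (finite && any(!is.finite(x))) .stopf("'%s' must be finite", name)
  if (positive && any(x <= 0)) .stopf("'%s' must be strictly positive", name)
  invisible(x)
}
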
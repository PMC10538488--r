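# Small internal helpers shared across modules.

#' @importFrom Rcpp evalCpp
#' @useDynLib dsmlink, .registration = TRUE
NULL

.PROB_FLOOR <- 1e-12

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clipProb <- function(p) pmin(pmax(p, .PROB_FLOOR), 1 - .PROB_FLOOR)

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# FNV-1a 64-bit-ish hash over a character scalar, returned as hex. Used only
# to fingerprint configuration/eQTL-map content in provenance records, not for
# anything cryptographic.
.contentHash <- function(x) {
  stopifnot(is.character(x))
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  # multiply in two 16-bit limbs to stay inside exact double-precision integers
  h <- 0x811c9dc5
  prime <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- ((lo * prime) %% 4294967296 + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Full-batch Adam ascent step state helper.
.adamInit <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

.adamStep <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- lr * mhat / (sqrt(vhat) + eps)
  state
}
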
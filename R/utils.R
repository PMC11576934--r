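#' @useDynLib hyposeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif qf wilcox.test
#' @importFrom utils write.csv
NULL

.stopf <- function(class, fmt, ...) {
  stop(structure(class = c(class, "hyposegError", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Independent RNG sub-seeds per concern, derived from one master seed.
# Small multiplicative hash keeps results in [0, 2^31).
.deriveSeed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Robust min-max rescale to [0,1] using the 0.1 / 99.9 percentiles;
# a constant image maps to all zeros.
.robustRescale <- function(x) {
  q <- quantile(x, c(0.001, 0.999), names = FALSE, type = 7)
  if (q[2] - q[1] <= 0) return(array(0, dim(x)))
  .clamp((x - q[1]) / (q[2] - q[1]), 0, 1)
}

.isOdd <- function(n) n %% 2L == 1L

# fingerprint for checkpoint/LUT compatibility checks
.lutFingerprint <- function(lut) {
  tb <- lutTable(lut)
  key <- paste(tb$id, tb$name, tb$region, tb$partner, collapse = ";")
  sprintf("%08x", sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)) %% 0xFFFFFFF)
}
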
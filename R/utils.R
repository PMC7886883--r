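#' @useDynLib amlsubtypes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor var sd median optim pnorm pchisq plogis qnorm
#'   p.adjust wilcox.test rnbinom rnorm runif rbinom rexp uniroot
#'   integrate quantile predict coef
#' @importFrom utils read.table write.table head tail
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic package code funnels through this
# so that a single user-facing seed fixes every draw.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic substream seeds: a small integer hash of (seed, salt) kept in
# [0, 2^31). Distinct salts give effectively independent substreams.
derive_seed <- function(seed, salt) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (x in c(salt, 0)) {
    s <- (s * 69069 + as.double(x) * 2654435761 + 1013904223) %% 2147483648
  }
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
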
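## Internal numeric and seeding helpers.

#' @keywords internal
"_PACKAGE"

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

## Latent residual variance of the logistic threshold representation.
LOGISTIC_RESIDUAL <- pi^2 / 3

## Row-wise log-sum-exp for a matrix, guarded against -Inf rows.
row_logsumexp <- function(A) {
  mx <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  out <- mx + log(rowSums(exp(A - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

## Deterministic seed splitting: every stage that consumes randomness derives
## its own substream seed from the user-facing seed and a short purpose tag.
## Child seeds stay inside the 32-bit signed-integer range.
split_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)) * 1009)
  as.integer((abs(seed) * 69091 + h) %% 2147483629 + 1)
}

## Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Branchless numerically stable sigmoid / log-sigmoid used in hot loops
## (equivalent to plogis(x) and plogis(x, log.p = TRUE), without the
## per-call dispatch overhead).
sigmoid <- function(x) 1 / (1 + exp(-x))
log_sigmoid <- function(x) pmin(x, 0) - log1p(exp(-abs(x)))
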
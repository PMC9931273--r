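#' @keywords internal
"_PACKAGE"

#' @importFrom stats glm glm.fit binomial coef cor model.matrix median
#'   quantile kmeans qnorm qt plogis rbinom rnorm rpois rlnorm runif sd var
#'   density predict setNames
#' @importFrom utils read.csv write.csv
NULL

expit <- function(x) stats::plogis(x)

# Clip probabilities away from {0,1} so log-loss stays finite.
clip_prob <- function(p, eps = .Machine$double.eps) {
  pmin(pmax(p, eps), 1 - eps)
}

# Deterministic substream seed: mixes a root seed with a purpose label and an
# integer id, staying inside the 32-bit signed range.
substream_seed <- function(root, label, id = 0L) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  s <- (as.double(root) * 48271 + h * 16807 + as.double(id) * 69621) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
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

stop2 <- function(...) stop(..., call. = FALSE)
warn2 <- function(...) warning(..., call. = FALSE)
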
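#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join across n
#' @importFrom stats rnorm runif rbinom pnorm plogis qnorm quantile sd median
#'   p.adjust glm binomial coef vcov setNames
#' @importFrom utils head tail
NULL

# Deterministic sub-seed from a master seed and a key string.
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1; all intermediate
# products stay below 2^53 so double arithmetic is exact.
derive_seed <- function(master, ...) {
  p <- 2147483647
  key <- paste(c(...), collapse = "\r")
  h <- (as.numeric(master) %% p) * 48271 %% p
  for (b in utf8ToInt(key)) {
    h <- (h * 131 + b + 1) %% p
  }
  as.integer(h %% (p - 2L) + 1)
}

# Run code with a local RNG seeded deterministically; restores caller RNG.
with_sub_seed <- function(master, ..., code) {
  withr::with_seed(derive_seed(master, ...), code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
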
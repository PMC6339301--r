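#' Derive a child seed for a named operation
#'
#' One master seed fans out to per-operation child seeds by a stable string
#' hash of the operation name, so that stages are reproducible yet draw
#' from effectively independent streams.
#'
#' @param seed Integer master seed.
#' @param op Character scalar naming the operation.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "coverage") != child_seed(1, "genotypes")
child_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(op), length(op) == 1)
  h <- 0
  for (k in utf8ToInt(op)) h <- (h * 31 + k) %% 1000000007
  as.integer((abs(seed) + h) %% (.Machine$integer.max - 1))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Round half away from zero (presentation convention for percent and depth
# columns; base round() is round-half-even).
round_half_out <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_capkit <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "capkit_error")))
}

# Coerce a DNAStringSet (or any XStringSet) to a named character vector;
# plain character vectors pass through with their names intact.
as_named_sequences <- function(x) {
  if (methods::is(x, "XStringSet")) setNames(as.character(x), names(x)) else x
}
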
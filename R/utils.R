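#' @keywords internal
"_PACKAGE"

#' @importFrom methods is
#' @importFrom stats median p.adjust pbinom rbinom rlnorm runif fisher.test
#'   setNames cor
#' @importFrom utils head read.table write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic entry points funnel
# through this so that a given seed yields byte-identical output regardless
# of surrounding RNG use.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stage label, staying within
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_fraction <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
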
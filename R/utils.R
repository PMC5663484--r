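# Internal helpers shared across modules.

#' Evaluate code with a local RNG seed
#'
#' Saves and restores `.Random.seed` so generator functions are
#' deterministic given their `seed` argument without clobbering the
#' caller's RNG stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param code expression to evaluate.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered running mean with shrinking windows at the edges.
# O(n) via cumulative sums; used for zero-phase smoothing/high-pass.
runmean_centered <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  if (width <= 1L) return(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "breathcomplex_error")))
}

check_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name, class = "invalid_parameter")
  x
}

# Deterministic per-recording seed derived from (master_seed, group, index).
# Mixes the UTF-8 codes of the group label with the index; kept < 2^31.
derive_seed <- function(master_seed, group, index) {
  h <- sum(utf8ToInt(as.character(group)) * seq_along(utf8ToInt(as.character(group))))
  s <- (as.double(master_seed) %% 65521) * 31259 + h * 131 + index * 977
  as.integer(s %% 2147483629)
}
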
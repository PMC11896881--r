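# Internal helpers: deterministic hashing for hierarchical seeding, and
# small argument checks shared across modules.

MAXSEED <- 2147483647  # 2^31 - 1, largest value set.seed() accepts

#' @noRd
str_hash <- function(s) {
  # FNV-1a-flavoured string hash folded into [0, 2^31 - 1]; doubles hold
  # exact integers well past 2^31 so the modular loop is exact.
  h <- 2166136261 %% MAXSEED
  for (b in utf8ToInt(s)) {
    h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% MAXSEED
  }
  h
}

#' Derive a child seed from a parent seed and a label
#'
#' One global stream per cohort, split hierarchically by individual id (and a
#' purpose tag), so adding individuals to a config does not perturb the draws
#' of individuals that were already present.
#' @noRd
child_seed <- function(seed, label) {
  (seed * 48271 + str_hash(label)) %% MAXSEED
}

#' Run code with a private RNG state
#'
#' Seeds, evaluates, and restores the caller's .Random.seed, so library
#' functions never disturb user randomness.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("'%s' must be a finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}

#' Percentile interval of a sample (quantile type configurable, default 7)
#' @noRd
percentile_ci <- function(x, level = 0.95, type = 7L) {
  a <- (1 - level) / 2
  unname(quantile(x, probs = c(a, 1 - a), type = type, na.rm = TRUE, names = FALSE))
}
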
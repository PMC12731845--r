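# Internal helpers: weight (score) functions, seed derivation, RNG hygiene.

# L-statistic score functions.  J integrates to 0 on (0,1), as does Jbar;
# J' and Jbar' are the exponentiality-contrast scores (HNBUE testing).
score_J <- function(u) -log1p(-u) - 1
score_Jbar <- function(u) log(u) + 1
score_Jprime <- function(u) 2 + log1p(-u)
score_Jbarprime <- function(u) -log(u) + pi^2 / 6 - 2

# As-printed variants of the exponentiality scores (kept for comparison;
# they do not vanish at the exponential null).
score_Jprime_printed <- function(u) 2 - log1p(-u)
score_Jbarprime_printed <- function(u) -log(u) - pi^2 / 16 - 2

score_Jalpha <- function(u, alpha) {
  (1 - alpha * (1 - u)^(alpha - 1)) / (1 - alpha)
}

#' Derive a reproducible child seed from a master seed and a key
#'
#' Deterministic 31-bit hash of the master seed plus any number of string or
#' numeric key components.  Used so that independent simulation stages
#' (critical values vs power, different sample sizes, different families)
#' consume independent, reproducible streams.
#'
#' @param seed integer master seed.
#' @param ... key components (coerced to character).
#' @return an integer in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
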
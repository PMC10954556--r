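# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary random seed
#'
#' Sets the Mersenne-Twister seed for the duration of `code` and restores the
#' caller's random state afterwards, so that simulation functions are
#' deterministic given their `seed` argument without disturbing the session.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi) {
    stop(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  invisible(x)
}

# The other haplotype label.
.other_hap <- function(h) ifelse(h == "H1", "H2", "H1")
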
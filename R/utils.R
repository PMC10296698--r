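#' Sample skewness
#'
#' Moment-based sample skewness \eqn{g_1 = m_3 / m_2^{3/2}}, the statistic
#' used to flag raw test-score distributions that need a normalizing
#' transformation before control-referenced standardization.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @return A single number; `NaN` when the sample has zero variance.
#' @examples
#' skewness(rexp(500)) # close to 2
#' @export
skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NaN)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^3) / m2^1.5
}

# stop() with a class so callers can distinguish validation failures
cf_abort <- function(msg, class = "cogfrail_error") {
  abort(msg, class = c(class, "cogfrail_error"))
}

# checks a data frame has the named columns; error names the missing ones
check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    cf_abort(
      sprintf("%s is missing required column(s): %s",
              what, paste(missing, collapse = ", ")),
      class = "cogfrail_schema_error"
    )
  }
  invisible(df)
}

# evaluate expr with a private RNG state seeded by `seed`, restoring the
# caller's state afterwards (single root generator per spec'd seed policy)
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# truncated-normal draws by inverse-CDF (bounds in data units)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}
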
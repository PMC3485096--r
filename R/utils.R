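#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange bind_rows group_by summarise
#'   left_join across all_of
#' @importFrom stats rnorm rexp rpois runif optimize quantile sd var coef lm
#'   rstudent pchisq median setNames
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib firecomm, .registration = TRUE
NULL

# Run `expr` under a temporary RNG state seeded with `seed`; restore afterwards.
# seed = NULL uses (and advances) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying < 2^31.
child_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  chars <- utf8ToInt(as.character(label))
  h <- sum(chars * seq_along(chars)) %% 104729
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

#' Significance stars for a p-value
#'
#' Encodes the conventional thresholds 0.05, 0.01 and 0.001 as
#' `"*"`, `"**"`, `"***"`; p-values in (0.05, 0.1] get a dagger.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers ("" when p > 0.1).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else if (pi <= 0.1) "†"
    else ""
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
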
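#' Welch's two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] returning a tidy row, with
#' explicit contracts for degenerate (zero-variance) inputs: when both
#' groups have zero variance and equal means, `t = 0`, `p = 1`; when both
#' have zero variance and different means, `p = 0` with `t = +/-Inf` and
#' a `degenerate` flag.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @return A tibble with columns `t`, `df`, `p`, `method`, `degenerate`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(tibble(t = 0, df = Inf, p = 1, method = "welch",
                    degenerate = TRUE))
    return(tibble(t = sign(mean(x) - mean(y)) * Inf, df = Inf, p = 0,
                  method = "welch", degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, method = "welch", degenerate = FALSE)
}

#' Paired t-test
#'
#' Paired two-sided t-test with degenerate contracts: identical vectors
#' give `t = 0`, `p = 1`; a constant non-zero difference (zero variance
#' of differences) gives `p = 0` with a `degenerate` flag.
#'
#' @param x,y Numeric vectors of equal length (>= 2 pairs).
#' @return A tibble with columns `t`, `df`, `p`, `method`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("paired test needs equal-length vectors", call. = FALSE)
  if (length(x) < 2)
    stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0))
      return(tibble(t = 0, df = length(d) - 1, p = 1, method = "paired",
                    degenerate = TRUE))
    return(tibble(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                  method = "paired", degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, method = "paired", degenerate = FALSE)
}
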
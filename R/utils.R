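#' Derive a per-stage child seed from a global seed
#'
#' Fans a single global seed out to independent per-stage seeds by a stable
#' polynomial hash of the stage name, so partial reruns of one stage are
#' reproducible without replaying earlier stages.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"simulate"`, `"fit"`).
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' stage_seed(1L, "simulate")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% (m - 1L) + 1L)
}

# clip a numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# strict scalar-in-range check with a readable error
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must be in [%g, %g]", name, lo, hi), call. = FALSE)
  }
  invisible(x)
}

# round half away from zero: the convention used in the study's reported
# figures (2662/88 = 30.25 prints as 30.3), unlike R's round-half-even
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Report a count as a percentage
#'
#' Cohort descriptive arithmetic used throughout the reports: `k` events out
#' of `n`, expressed as a percentage rounded to a fixed number of digits
#' (e.g. 57 of 106 subtype calls, 1 of 106 mutated samples, 40 of 43
#' organoid takes).
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @param digits Decimal digits to keep (default 2).
#' @return Percentage as a bare number (53.77, not "53.77%").
#' @export
#' @examples
#' percent_of(57, 106) # 53.77
#' percent_of(40, 43, digits = 0) # 93
percent_of <- function(k, n, digits = 2) {
  stopifnot(n > 0, k >= 0)
  round_half_up(100 * k / n, digits)
}
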
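#' Construct a reciprocal-symmetric abundance significance band
#'
#' Abundance ratios (mutant / wild-type) are judged against a null band that
#' is symmetric on the log scale: a ratio r and its reciprocal 1/r are
#' equally (in)significant. The band can be built two ways:
#'
#' * from a log-ratio standard deviation `sd_log` and confidence `level`:
#'   `(exp(-z * sd_log), exp(+z * sd_log))` with `z` the two-sided normal
#'   quantile, an approximation to the null spread of measured ratios for an
#'   unchanged protein; or
#' * verbatim, by supplying `lower` and/or `upper` directly (a published
#'   interval such as 0.785-1.274). If only one bound is given the other is
#'   its reciprocal.
#'
#' Exactly one of the two parameterizations must be used.
#'
#' @param lower,upper Explicit band bounds (`lower` in (0,1), `upper` > 1).
#' @param sd_log Standard deviation of the null log abundance ratio (>= 0).
#' @param level Two-sided confidence level in (0,1); default 0.99.
#' @return An object of class `alascan_band`: a list with `lower`, `upper`,
#'   `level`, `sd_log` (NA when constructed verbatim).
#' @export
#' @examples
#' significance_band(upper = 1.274)          # published 99% band
#' significance_band(sd_log = 0.094)         # equivalent construction
significance_band <- function(lower = NULL, upper = NULL, sd_log = NULL,
                              level = 0.99) {
  explicit <- !is.null(lower) || !is.null(upper)
  if (explicit && !is.null(sd_log)) {
    abort("Supply either explicit bounds or `sd_log`, not both.")
  }
  if (!explicit && is.null(sd_log)) {
    abort("Supply explicit bounds (`lower`/`upper`) or `sd_log`.")
  }
  if (explicit) {
    if (is.null(upper)) upper <- 1 / lower
    if (is.null(lower)) lower <- 1 / upper
    if (!(lower > 0 && lower < 1 && upper > 1)) {
      abort("Band bounds must satisfy 0 < lower < 1 < upper.")
    }
    if (abs(lower * upper - 1) > 1e-3) {
      abort("Band is not reciprocal-symmetric: lower must equal 1/upper within 1e-3.")
    }
    sd_log <- NA_real_
  } else {
    if (sd_log < 0) abort("`sd_log` must be >= 0.")
    if (!(level > 0 && level < 1)) abort("`level` must be in (0, 1).")
    z <- qnorm(1 - (1 - level) / 2)
    lower <- exp(-z * sd_log)
    upper <- exp(+z * sd_log)
  }
  structure(
    list(lower = lower, upper = upper, level = level, sd_log = sd_log),
    class = "alascan_band"
  )
}

#' @export
print.alascan_band <- function(x, ...) {
  cat(sprintf(
    "<abundance significance band> lower = %.4g, upper = %.4g (%.0f%% level)\n",
    x$lower, x$upper, 100 * x$level
  ))
  invisible(x)
}

#' @rdname significance_band
#' @param x An `alascan_band` object.
#' @param ... Unused.
#' @method tidy alascan_band
#' @export
tidy.alascan_band <- function(x, ...) {
  tibble(lower = x$lower, upper = x$upper, level = x$level, sd_log = x$sd_log)
}

#' Classify abundance ratios against a significance band
#'
#' A ratio below the band's lower bound is called `low`, above the upper
#' bound `high`, otherwise `normal`. Low abundance indicates a defect in
#' synthesis, folding, translocation and/or stability of the mutant protein.
#'
#' @param ratio Numeric vector of abundance ratios (mutant / wild-type).
#' @param band An [significance_band()] object.
#' @return Character vector in `{low, normal, high}` (`NA` for `NA` input).
#' @export
#' @examples
#' band <- significance_band(upper = 1.274)
#' classify_abundance(c(0.660, 1.0, 1.51), band)
classify_abundance <- function(ratio, band) {
  stopifnot(inherits(band, "alascan_band"))
  dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    ratio < band$lower ~ "low",
    ratio > band$upper ~ "high",
    TRUE ~ "normal"
  )
}

#' Variance-ratio (F) test for a low internal-standard-normalized count
#'
#' Alternative significance mode: tests whether a mutant's log abundance
#' ratio is compatible with the null spread estimated from the
#' internal-standard variation, via a one-degree-of-freedom variance-ratio
#' statistic `(log A)^2 / sd_log^2` referred to an F(1, df) distribution.
#' Provided as an explicit alternative to the band rule; the band rule with
#' a configured interval is the default throughout the package.
#'
#' @param ratio Abundance ratio(s), > 0.
#' @param sd_log Null standard deviation of log ratios.
#' @param df Degrees of freedom used to estimate `sd_log`.
#' @return Tibble with `ratio`, `statistic`, `p_value`.
#' @export
abundance_f_test <- function(ratio, sd_log, df) {
  stopifnot(sd_log > 0, df >= 1)
  stat <- (log(ratio) / sd_log)^2
  tibble(
    ratio = ratio,
    statistic = stat,
    p_value = stats::pf(stat, 1, df, lower.tail = FALSE)
  )
}
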
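#' Percent change in prevalence
#'
#' `(baseline - followup) / baseline * 100`, rounded to two decimals as
#' reported.  Positive values are reductions in prevalence; negative values
#' mean prevalence rose.
#'
#' @param baseline_depressed Baseline case count (> 0).
#' @param followup_depressed Follow-up case count.
#' @return Signed percent, 2 decimal places.
#' @export
#' @examples
#' pct_change(6154, 5974)  # 2.92
#' pct_change(6157, 6944)  # -12.78
pct_change <- function(baseline_depressed, followup_depressed) {
  if (any(baseline_depressed <= 0))
    stop("baseline_depressed must be positive")
  round((baseline_depressed - followup_depressed) / baseline_depressed * 100, 2)
}

#' Test a baseline vs follow-up prevalence change
#'
#' Two methods, both two-sided and symmetric in direction:
#'
#' * `two_proportion_z` (default): pooled-variance z-test comparing the two
#'   prevalences `baseline/n` and `followup/n` as if independent samples of
#'   size `n`.
#' * `mcnemar`: exact binomial test on the discordant counts
#'   (`incident`, `reduced`), i.e. the paired-data test; requires the
#'   discordant counts.
#'
#' The original report does not name its test and its printed p-values are
#' not reproducible from the printed counts under either method; both are
#' provided and the choice is configuration.
#'
#' @param baseline_depressed,followup_depressed Case counts.
#' @param n Number of agents (> 0).
#' @param method `"two_proportion_z"` or `"mcnemar"`.
#' @param incident,reduced Discordant counts, required for `mcnemar`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' prevalence_test(6154, 5974, 17874)
#' prevalence_test(6154, 5974, 17874, method = "mcnemar",
#'                 incident = 0, reduced = 180)
prevalence_test <- function(baseline_depressed, followup_depressed, n,
                            method = c("two_proportion_z", "mcnemar"),
                            incident = NULL, reduced = NULL) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  stopifnot(baseline_depressed >= 0, followup_depressed >= 0,
            baseline_depressed <= n, followup_depressed <= n)
  if (method == "two_proportion_z") {
    p1 <- baseline_depressed / n
    p2 <- followup_depressed / n
    pooled <- (baseline_depressed + followup_depressed) / (2 * n)
    se <- sqrt(pooled * (1 - pooled) * (2 / n))
    if (se == 0) return(1)
    z <- (p1 - p2) / se
    2 * pnorm(-abs(z))
  } else {
    if (is.null(incident) || is.null(reduced))
      stop("mcnemar requires the discordant counts 'incident' and 'reduced'")
    discordant <- incident + reduced
    if (discordant == 0) return(1)
    binom.test(incident, discordant, p = 0.5)$p.value
  }
}
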
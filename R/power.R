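#' Power of a two-sample comparison at standardized effect d
#'
#' Exact two-sided power of the two-sample t-test (noncentral t) or its
#' large-sample normal approximation, for group sizes n1 and n2 and a
#' standardized mean difference (Cohen's d).
#'
#' @param d Standardized effect size.
#' @param n1,n2 Group sizes (> 1).
#' @param alpha Two-sided significance level; default 0.05.
#' @param method \code{"t"} (noncentral t, default) or \code{"normal"}.
#' @return Power in (0, 1).
#' @export
two_sample_power <- function(d, n1, n2, alpha = 0.05,
                             method = c("t", "normal")) {
  method <- match.arg(method)
  stopifnot(n1 > 1, n2 > 1, alpha > 0, alpha < 1)
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  if (method == "normal") {
    za <- stats::qnorm(1 - alpha / 2)
    return(stats::pnorm(ncp - za) + stats::pnorm(-ncp - za))
  }
  df <- n1 + n2 - 2
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Minimum detectable standardized effect size
#'
#' Smallest Cohen's d detectable with the requested power in a two-sample
#' comparison of groups n1 and n2 at two-sided level alpha. The default is
#' the closed-form normal approximation
#' \deqn{d = (z_{1-\alpha/2} + z_{power}) \sqrt{1/n_1 + 1/n_2},}
#' optionally refined by inverting the noncentral-t power curve (the two
#' differ by well under 0.001 at epidemiological sample sizes).
#'
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided level; default 0.05.
#' @param power Target power; default 0.80.
#' @param method \code{"normal"} (closed form, default) or \code{"t"}.
#' @return Minimum detectable d.
#' @examples
#' required_effect_size(396, 1046)  # prediabetes vs remainder of cohort
#' required_effect_size(140, 1302)  # isolated IGT vs remainder
#' @export
required_effect_size <- function(n1, n2, alpha = 0.05, power = 0.80,
                                 method = c("normal", "t")) {
  method <- match.arg(method)
  stopifnot(n1 > 1, n2 > 1, alpha > 0, alpha < 1, power > 0, power < 1)
  d0 <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
    sqrt(1 / n1 + 1 / n2)
  if (method == "normal") return(d0)
  stats::uniroot(function(d) two_sample_power(d, n1, n2, alpha) - power,
                 lower = d0 / 2, upper = d0 * 2, tol = 1e-10)$root
}

#' Minimal sample size for a standardized effect
#'
#' Smallest total n achieving the requested power for effect d under a
#' two-group allocation n2 = r * n1, inverting the noncentral-t power curve
#' (so at 1:1 allocation it matches \code{stats::power.t.test} up to
#' rounding).
#'
#' @param d Standardized effect size (non-zero).
#' @param alpha Two-sided level; default 0.05.
#' @param power Target power; default 0.80.
#' @param allocation_ratio r = n2/n1; default 1.
#' @param method \code{"t"} (default) or \code{"normal"}.
#' @return Named integer vector with \code{n1}, \code{n2}, \code{n_total}.
#' @examples
#' minimal_n_for_effect(0.232)  # 293 per arm
#' @export
minimal_n_for_effect <- function(d, alpha = 0.05, power = 0.80,
                                 allocation_ratio = 1,
                                 method = c("t", "normal")) {
  method <- match.arg(method)
  stopifnot(d != 0, allocation_ratio > 0)
  r <- allocation_ratio
  # closed-form start, then walk to the smallest integer n1 with power met
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n1 <- max(2, floor((z / abs(d))^2 * (1 + 1 / r)) - 2)
  repeat {
    n2 <- ceiling(r * n1)
    if (n2 > 1 &&
        two_sample_power(d, n1, n2, alpha, method = method) >= power) break
    n1 <- n1 + 1
  }
  c(n1 = n1, n2 = as.integer(ceiling(r * n1)),
    n_total = n1 + as.integer(ceiling(r * n1)))
}

#' Minimum detectable per-allele odds ratio
#'
#' Smallest per-allele odds ratio detectable with the requested power in a
#' logistic regression of a binary outcome on a continuous (approximately
#' normal) genetic risk score, by the Hsieh large-sample formula: the
#' detectable log odds ratio per SD of the score is
#' \deqn{\beta^* = (z_{1-\alpha/2} + z_{power}) / \sqrt{n\,P(1-P)},}
#' with P the outcome prevalence, converted to the per-allele (per score
#' unit) scale by dividing by the score SD.
#'
#' @param n Sample size.
#' @param score_sd Standard deviation of the risk score.
#' @param baseline_prevalence Outcome prevalence P in (0, 1).
#' @param alpha Two-sided level; default 0.05.
#' @param power Target power; default 0.80.
#' @return Minimum detectable per-allele OR (> 1).
#' @export
min_detectable_or <- function(n, score_sd, baseline_prevalence,
                              alpha = 0.05, power = 0.80) {
  stopifnot(n > 0, score_sd > 0,
            baseline_prevalence > 0, baseline_prevalence < 1)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  beta_sd <- z / sqrt(n * baseline_prevalence * (1 - baseline_prevalence))
  exp(beta_sd / score_sd)
}

#' Power table for a list of group-size configurations
#'
#' Convenience wrapper producing the minimum detectable effect size for
#' each (n1, n2) configuration.
#'
#' @param configs Data.frame with columns \code{label}, \code{n1}, \code{n2}.
#' @param alpha,power As in \code{\link{required_effect_size}}.
#' @return The input with columns \code{d_min} and \code{power_at_d_min}
#'   (exact noncentral-t power at the returned d) appended.
#' @export
power_table <- function(configs, alpha = 0.05, power = 0.80) {
  stopifnot(all(c("n1", "n2") %in% names(configs)))
  configs$d_min <- mapply(required_effect_size, configs$n1, configs$n2,
                          MoreArgs = list(alpha = alpha, power = power))
  configs$power_at_d_min <- mapply(two_sample_power, configs$d_min,
                                   configs$n1, configs$n2,
                                   MoreArgs = list(alpha = alpha))
  configs
}
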
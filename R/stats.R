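# Statistical relations: per-liver mean latent heat with 95% CI, latent heat
# vs water fraction regression, ice onset vs log10(cooling rate) fits and the
# low-rate plateau check.

fit_result <- function(estimates, ci95, n, residual_sd) {
  structure(list(estimates = estimates, ci95 = ci95, n = n,
                 residual_sd = residual_sd),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit (n = %d, residual sd = %.4g)\n", x$n, x$residual_sd))
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-12s %10.4g   95%% CI [%.4g, %.4g]\n", nm,
                x$estimates[[nm]], x$ci95[nm, 1], x$ci95[nm, 2]))
  }
  if (!is.null(x$plateau)) cat(sprintf("  plateau: %s\n", x$plateau))
  invisible(x)
}

# Unweighted OLS of y on x with t-based 95% CIs; degenerate df handled by
# collapsing the interval onto the estimate (exact two-point fits).
ols_ci <- function(x, y, xname = "slope") {
  df <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = df)
  est <- coef(fit)
  names(est) <- c("intercept", xname)
  dfree <- fit$df.residual
  if (dfree > 0) {
    s <- suppressWarnings(summary(fit))  # exact fits are legitimate here
    se <- s$coefficients[, 2]
    half <- qt(0.975, dfree) * se
    rsd <- s$sigma
    # exact fits: summary() reports NaN sigma when residuals are ~0
    if (!is.finite(rsd)) rsd <- 0
    if (any(!is.finite(half))) half <- rep(0, 2)
  } else {
    half <- c(0, 0)
    rsd <- 0
  }
  ci <- cbind(lower = est - half, upper = est + half)
  rownames(ci) <- names(est)
  fit_result(est, ci, n = length(x), residual_sd = rsd)
}

records_df <- function(records) {
  df <- as.data.frame(records)
  need <- c("water_fraction", "cooling_rate", "T_onset", "latent_heat")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("records lack columns: %s", paste(miss, collapse = ", "))
  if (any(df$cooling_rate <= 0)) stopf("cooling_rate must be positive (magnitude, K/min)")
  if (any(df$water_fraction <= 0 | df$water_fraction >= 1)) {
    stopf("water_fraction must lie strictly inside (0, 1)")
  }
  df
}

#' Mean latent heat with 95% confidence interval
#'
#' Student-t confidence interval for the mean of repeated latent-heat
#' measurements (half-width `qt(0.975, n-1) * sd / sqrt(n)`), as reported
#' per liver alongside the average.
#'
#' @param values Latent-heat measurements, J/g (n >= 2).
#' @return A `fit_result` with the `mean` estimate, its 95% CI, `n`, and the
#'   sample sd as `residual_sd`.
#' @export
#' @examples
#' mean_latent_ci(c(152, 158, 167))
mean_latent_ci <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stopf("insufficient-data: need at least 2 values for a confidence interval")
  m <- mean(values)
  s <- sd(values)
  half <- qt(0.975, n - 1) * s / sqrt(n)
  ci <- cbind(lower = m - half, upper = m + half)
  rownames(ci) <- "mean"
  fit_result(c(mean = m), ci, n = n, residual_sd = s)
}

#' Latent heat vs water mass fraction regression
#'
#' Ordinary least squares of latent heat on the water mass fraction, pooled
#' across livers. The linear dependence reflects that essentially the water
#' content of the tissue freezes; the dehydrated matrix contributes no
#' transition enthalpy.
#'
#' @param records A data.frame of sample records with columns
#'   `water_fraction`, `cooling_rate` (K/min, magnitude), `T_onset` (degC)
#'   and `latent_heat` (J/g); see [generate_cohort()].
#' @return A `fit_result` with `intercept` (J/g) and `slope`
#'   (J/g per unit water fraction).
#' @export
fit_latent_vs_water <- function(records) {
  df <- records_df(records)
  if (length(unique(df$water_fraction)) < 2) {
    stopf("rank-deficiency: need at least 2 distinct water fractions")
  }
  ols_ci(df$water_fraction, df$latent_heat, xname = "slope")
}

#' Ice onset vs log cooling rate regression
#'
#' Least squares of the onset temperature on `log10(cooling rate)` over the
#' fast-cooling regime (rates at or above `rate_threshold`), where the onset
#' falls linearly in a semi-log diagram. The slope is reported in K per
#' decade of cooling rate.
#'
#' @inheritParams fit_latent_vs_water
#' @param rate_threshold Minimum cooling rate (K/min) for a record to enter
#'   the fit. Default 5.
#' @return A `fit_result` with `intercept` (degC at 1 K/min) and `slope`
#'   (K/decade).
#' @export
fit_onset_vs_lograte <- function(records, rate_threshold = 5) {
  df <- records_df(records)
  df <- df[df$cooling_rate >= rate_threshold, ]
  if (nrow(df) < 2 || length(unique(df$cooling_rate)) < 2) {
    stopf("insufficient-data: need >= 2 records at distinct rates >= %g K/min",
          rate_threshold)
  }
  ols_ci(log10(df$cooling_rate), df$T_onset, xname = "slope")
}

#' Low-rate plateau check for the onset temperature
#'
#' Below roughly 1 K/min the onset temperature of tissue is practically
#' independent of the cooling rate. This fits the onset on
#' `log10(cooling rate)` over the slow-rate subset and flags a plateau when
#' the slope's 95% CI contains zero.
#'
#' @inheritParams fit_latent_vs_water
#' @param rate_cutoff Records with `cooling_rate` strictly below this value
#'   (K/min) enter the fit. Default 1.
#' @return A `fit_result` with an extra logical field `plateau`.
#' @export
plateau_test <- function(records, rate_cutoff = 1) {
  df <- records_df(records)
  df <- df[df$cooling_rate < rate_cutoff, ]
  if (nrow(df) < 2 || length(unique(df$cooling_rate)) < 2) {
    stopf("insufficient-data: need >= 2 records at distinct rates below %g K/min",
          rate_cutoff)
  }
  out <- ols_ci(log10(df$cooling_rate), df$T_onset, xname = "slope")
  out$plateau <- out$ci95["slope", 1] <= 0 && out$ci95["slope", 2] >= 0
  out
}
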
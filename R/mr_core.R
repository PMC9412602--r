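# Causal-effect estimators on harmonised instrument sets.

#' Per-SNP Wald ratio estimates
#'
#' The ratio estimate for instrument j is `theta_j = beta_y / beta_x`, with
#' a delta-method standard error. The first-order SE, `se_y / |beta_x|`,
#' ignores uncertainty in the SNP-exposure effect (the convention of most
#' two-sample MR software); the second-order SE adds the
#' `beta_y^2 * se_x^2 / beta_x^4` term.
#'
#' @param data Harmonised instrument tibble with columns `snp_id`,
#'   `beta_x`, `se_x`, `beta_y`, `se_y`.
#' @param order `"first"` (default) or `"second"` delta-method SE.
#' @return A tibble with columns `snp_id`, `theta`, `se_theta` and the
#'   inverse-variance `weight = 1 / se_theta^2`.
#' @export
wald_ratio <- function(data, order = c("first", "second")) {
  order <- match.arg(order)
  assert_cols(data, c("snp_id", "beta_x", "beta_y", "se_y"))
  zero <- data$beta_x == 0
  if (any(zero)) {
    abort(sprintf("Wald ratio undefined (beta_x = 0) for %s",
                  paste(data$snp_id[zero], collapse = ", ")))
  }
  theta <- data$beta_y / data$beta_x
  se <- if (order == "first") {
    data$se_y / abs(data$beta_x)
  } else {
    assert_cols(data, "se_x")
    sqrt(data$se_y^2 / data$beta_x^2 +
           data$beta_y^2 * data$se_x^2 / data$beta_x^4)
  }
  tibble::tibble(snp_id = data$snp_id, theta = theta, se_theta = se,
                 weight = 1 / se^2)
}

new_mr_estimate <- function(method, theta, se, pval, n_snp, data,
                            extra = list()) {
  structure(c(list(method = method, theta = theta, se = se, pval = pval,
                   n_snp = n_snp, data = data), extra),
            class = c(paste0("mr_", sub("_.*", "", method)), "mr_estimate"))
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools the per-SNP Wald ratios with inverse-variance weights
#' `w_j = 1 / se_theta_j^2`. The fixed-effect SE is `(sum w_j)^(-1/2)`;
#' under the multiplicative random-effects model it is inflated by
#' `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's heterogeneity
#' statistic. P-values are two-sided normal. With a single instrument the
#' estimate reduces exactly to its Wald ratio.
#'
#' @inheritParams wald_ratio
#' @param model `"fixed"` (default) or `"random"`.
#' @return An object of class `mr_estimate` with `tidy()`, `glance()` and
#'   `print()` methods.
#' @export
#' @examples
#' dat <- iron_hf_instruments("iron")
#' mr_ivw(dat)
mr_ivw <- function(data, model = c("fixed", "random"),
                   order = c("first", "second")) {
  model <- match.arg(model)
  if (nrow(data) < 1) abort("at least one instrument is required")
  r <- wald_ratio(data, order = order)
  w <- r$weight
  theta <- sum(w * r$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (r$theta - theta)^2)
  if (model == "random" && nrow(r) > 1) {
    se <- se * max(1, sqrt(q / (nrow(r) - 1)))
  }
  new_mr_estimate(paste0("ivw_", model), theta, se, z_pvalue(theta, se),
                  nrow(r), data, extra = list(q = q, ratios = r))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of the SNP-outcome effects on the
#' SNP-exposure effects with an unconstrained intercept and weights
#' `1 / se_y^2`. Instruments are first oriented so every `beta_x` is
#' non-negative (both members of a pair are negated otherwise). The slope
#' estimates the causal effect under the InSIDE assumption; a non-zero
#' intercept indicates average directional pleiotropy. P-values use the t
#' distribution with J - 2 degrees of freedom.
#'
#' @inheritParams wald_ratio
#' @return An object of classes `mr_egger`/`mr_estimate`; `tidy()` returns
#'   one row per term (slope and intercept).
#' @export
mr_egger <- function(data) {
  assert_cols(data, c("snp_id", "beta_x", "beta_y", "se_y"))
  j <- nrow(data)
  if (j < 3) abort("MR-Egger requires at least 3 instruments")
  s <- sign(data$beta_x)
  s[s == 0] <- 1
  bx <- data$beta_x * s
  by <- data$beta_y * s
  fit <- lm(by ~ bx, weights = 1 / data$se_y^2)
  cf <- summary(fit)$coefficients
  df <- j - 2
  est <- new_mr_estimate(
    "egger",
    theta = cf["bx", "Estimate"], se = cf["bx", "Std. Error"],
    pval = 2 * pt(-abs(cf["bx", "t value"]), df),
    n_snp = j, data = data,
    extra = list(
      intercept = cf["(Intercept)", "Estimate"],
      se_intercept = cf["(Intercept)", "Std. Error"],
      p_intercept = 2 * pt(-abs(cf["(Intercept)", "t value"]), df),
      df = df))
  est
}

# weighted-median point estimate on sorted ratio estimates
weighted_median_point <- function(theta, weight) {
  o <- order(theta)
  th <- theta[o]
  p <- weight[o] / sum(weight)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(s)])
  approx(s, th, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios: ratio estimates are
#' sorted, weights normalised, and the estimate is interpolated where the
#' cumulative weight (evaluated at interval midpoints) crosses one half.
#' It is consistent when instruments carrying more than half the total
#' weight are valid, even if the rest are pleiotropic. The standard error
#' is the standard deviation of the estimator over parametric-bootstrap
#' resamples of the summary statistics.
#'
#' @inheritParams wald_ratio
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed RNG seed for the bootstrap (mandatory, for reproducibility).
#' @return An object of class `mr_estimate`.
#' @export
mr_weighted_median <- function(data, n_boot = 5000, seed,
                               order = c("first", "second")) {
  if (nrow(data) < 3) abort("the weighted median requires at least 3 instruments")
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  if (n_boot < 1) abort("`n_boot` must be at least 1")
  order <- match.arg(order)
  r <- wald_ratio(data, order = order)
  theta <- weighted_median_point(r$theta, r$weight)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(data), data$beta_x, data$se_x)
      by <- rnorm(nrow(data), data$beta_y, data$se_y)
      bx[bx == 0] <- .Machine$double.eps
      th <- by / bx
      se <- data$se_y / abs(bx)
      weighted_median_point(th, 1 / se^2)
    }, numeric(1))
  })
  se <- sd(boots)
  new_mr_estimate("weighted_median", theta, se, z_pvalue(theta, se),
                  nrow(data), data,
                  extra = list(n_boot = n_boot, seed = seed, ratios = r))
}

#' Convert a log-scale estimate to an odds ratio with confidence interval
#'
#' @param theta,se Estimate and standard error on the log-odds scale.
#' @param ci_level Coverage of the interval (default 0.95).
#' @return A tibble with columns `or`, `or_low`, `or_high`.
#' @export
#' @examples
#' to_odds_ratio(0.1, 0.05)
to_odds_ratio <- function(theta, se, ci_level = 0.95) {
  assert_scalar_prob(ci_level, "ci_level")
  if (any(se <= 0)) abort("`se` must be positive")
  z <- qnorm(1 - (1 - ci_level) / 2)
  tibble::tibble(or = exp(theta),
                 or_low = exp(theta - z * se),
                 or_high = exp(theta + z * se))
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate: %s, %d SNP%s>\n", x$method, x$n_snp,
              if (x$n_snp == 1) "" else "s"))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn mr_ivw Tidy a fitted MR estimate into a one-row tibble
#'   (two rows, slope and intercept, for MR-Egger) with the effect, its
#'   standard error, p-value and odds-ratio scale confidence interval.
#' @param x A fitted `mr_estimate`.
#' @param ci_level Confidence level for the odds-ratio interval.
#' @param ... Unused.
#' @method tidy mr_estimate
#' @export
tidy.mr_estimate <- function(x, ci_level = 0.95, ...) {
  out <- tibble::tibble(
    method = x$method, term = "effect", n_snp = x$n_snp,
    estimate = x$theta, std.error = x$se, p.value = x$pval)
  dplyr::bind_cols(out, to_odds_ratio(x$theta, x$se, ci_level))
}

#' @method tidy mr_egger
#' @export
tidy.mr_egger <- function(x, ci_level = 0.95, ...) {
  eff <- tibble::tibble(
    method = "egger", term = c("effect", "intercept"), n_snp = x$n_snp,
    estimate = c(x$theta, x$intercept),
    std.error = c(x$se, x$se_intercept),
    p.value = c(x$pval, x$p_intercept))
  ors <- to_odds_ratio(eff$estimate[1], eff$std.error[1], ci_level)
  dplyr::bind_cols(eff, dplyr::bind_rows(ors, tibble::tibble(
    or = NA_real_, or_low = NA_real_, or_high = NA_real_)))
}

#' @method glance mr_estimate
#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(method = x$method, n_snp = x$n_snp,
                 q = x$q %||% NA_real_, pval = x$pval)
}

#' Run the full estimator suite on one instrument set
#'
#' Convenience wrapper producing the per-method forest-plot table for one
#' exposure: fixed- and random-effect IVW, MR-Egger (slope and intercept)
#' and the weighted median. Methods whose preconditions are not met (e.g.
#' fewer than 3 instruments) are silently skipped.
#'
#' @inheritParams wald_ratio
#' @param methods Estimators to run.
#' @param n_boot,seed Weighted-median bootstrap controls.
#' @param ci_level Confidence level for odds-ratio intervals.
#' @return A tibble, one row per method (two for MR-Egger), with an
#'   `exposure` column when `data` carries one.
#' @export
#' @examples
#' mr_estimates(iron_hf_instruments("ferritin"), seed = 1, n_boot = 200)
mr_estimates <- function(data,
                         methods = c("ivw_fixed", "ivw_random", "egger",
                                     "weighted_median"),
                         n_boot = 5000, seed = NULL, ci_level = 0.95) {
  fits <- list()
  if ("ivw_fixed" %in% methods) fits <- c(fits, list(mr_ivw(data, "fixed")))
  if ("ivw_random" %in% methods) fits <- c(fits, list(mr_ivw(data, "random")))
  if ("egger" %in% methods && nrow(data) >= 3) {
    fits <- c(fits, list(mr_egger(data)))
  }
  if ("weighted_median" %in% methods && nrow(data) >= 3) {
    fits <- c(fits, list(mr_weighted_median(data, n_boot = n_boot, seed = seed)))
  }
  out <- purrr::map_dfr(fits, tidy, ci_level = ci_level)
  if ("exposure" %in% names(data) && nrow(data) > 0) {
    out <- dplyr::mutate(out, exposure = data$exposure[1], .before = 1)
  }
  out
}
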
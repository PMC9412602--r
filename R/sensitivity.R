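# Heterogeneity, influence and funnel diagnostics for an instrument set.

#' Cochran's Q heterogeneity test
#'
#' Tests whether the per-SNP Wald ratios are mutually consistent:
#' `Q = sum w_j (theta_j - theta_ivw)^2` with first-order inverse-variance
#' weights and the fixed-effect IVW pooled estimate, referred to a
#' chi-squared distribution with J - 1 degrees of freedom. Excess Q flags
#' heterogeneity, i.e. possible invalid instruments.
#'
#' @inheritParams wald_ratio
#' @return An object of class `mr_heterogeneity`; `glance()` gives the
#'   overall Q, df and p-value, `tidy()` the per-SNP contributions.
#' @export
cochran_q <- function(data) {
  if (nrow(data) < 2) abort("Cochran's Q requires at least 2 instruments")
  r <- wald_ratio(data, order = "first")
  ivw <- mr_ivw(data, "fixed")
  per <- r$weight * (r$theta - ivw$theta)^2
  q <- sum(per)
  df <- nrow(r) - 1
  structure(list(q = q, df = df,
                 pval = pchisq(q, df, lower.tail = FALSE),
                 per_snp = tibble::tibble(snp_id = r$snp_id, q = per),
                 theta_ivw = ivw$theta),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' @method tidy mr_heterogeneity
#' @export
tidy.mr_heterogeneity <- function(x, ...) x$per_snp

#' @method glance mr_heterogeneity
#' @export
glance.mr_heterogeneity <- function(x, ...) {
  tibble::tibble(q = x$q, df = x$df, p.value = x$pval)
}

#' Leave-one-out IVW analysis
#'
#' Refits the fixed-effect IVW estimate J times, each time excluding one
#' instrument, alongside the all-SNP fit, to reveal estimates driven by a
#' single variant.
#'
#' @inheritParams wald_ratio
#' @param model IVW model passed to [mr_ivw()].
#' @return A tibble with J + 1 rows: `excluded_snp` (`"(none)"` for the
#'   full set), `n_snp`, `theta`, `se`, `pval`.
#' @export
leave_one_out <- function(data, model = "fixed") {
  if (nrow(data) < 2) abort("leave-one-out requires at least 2 instruments")
  fit_row <- function(d, label) {
    f <- mr_ivw(d, model)
    tibble::tibble(excluded_snp = label, n_snp = f$n_snp,
                   theta = f$theta, se = f$se, pval = f$pval)
  }
  rows <- purrr::map_dfr(seq_len(nrow(data)), function(i) {
    fit_row(data[-i, , drop = FALSE], data$snp_id[i])
  })
  out <- dplyr::bind_rows(rows, fit_row(data, "(none)"))
  class(out) <- c("mr_loo", class(out))
  out
}

#' Funnel-plot coordinates
#'
#' One point per instrument: its Wald ratio against its precision
#' (1 / SE). Asymmetry about the pooled estimate suggests directional
#' pleiotropy; the assessment is visual, mirroring standard practice.
#'
#' @inheritParams wald_ratio
#' @return A tibble with columns `snp_id`, `theta`, `precision`.
#' @export
funnel_data <- function(data) {
  if (nrow(data) < 1) abort("at least one instrument is required")
  r <- wald_ratio(data, order = "first")
  tibble::tibble(snp_id = r$snp_id, theta = r$theta,
                 precision = 1 / r$se_theta)
}

#' Funnel plot of per-SNP causal estimates
#'
#' @inheritParams wald_ratio
#' @return A ggplot object.
#' @export
plot_funnel <- function(data) {
  pts <- funnel_data(data)
  ivw <- mr_ivw(data, "fixed")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$theta, y = .data$precision)) +
    ggplot2::geom_vline(xintercept = ivw$theta, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "per-SNP causal estimate", y = "precision (1/SE)")
}

#' Leave-one-out forest plot
#'
#' @param loo A tibble from [leave_one_out()].
#' @param ci_level Confidence level for the intervals.
#' @return A ggplot object.
#' @export
plot_leave_one_out <- function(loo, ci_level = 0.95) {
  z <- qnorm(1 - (1 - ci_level) / 2)
  df <- dplyr::mutate(loo,
                      low = .data$theta - z * .data$se,
                      high = .data$theta + z * .data$se,
                      excluded_snp = factor(.data$excluded_snp,
                                            levels = rev(.data$excluded_snp)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$excluded_snp)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$low, xmax = .data$high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate excluding the SNP", y = "excluded SNP")
}

#' Forest plot of the estimator suite
#'
#' @param estimates A tibble from [mr_estimates()] (possibly row-bound
#'   across exposures), with `method`, `or`, `or_low`, `or_high` columns.
#' @return A ggplot object on the odds-ratio scale.
#' @export
plot_forest <- function(estimates) {
  df <- dplyr::filter(estimates, .data$term == "effect")
  df$label <- if ("exposure" %in% names(df)) {
    paste(df$exposure, df$method, sep = ": ")
  } else df$method
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_low,
                                         xmax = .data$or_high), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio per SD (95% CI)", y = NULL)
}
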
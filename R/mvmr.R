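# Multivariable IVW MR: joint direct effects of several exposures.

#' Multivariable inverse-variance-weighted MR
#'
#' Jointly estimates the direct effect of each exposure on the outcome by
#' weighted least squares of the SNP-outcome effects on the matrix of
#' SNP-exposure effects, without intercept and with weights `1/se_y^2`.
#' Standard errors come from the weighted normal equations and p-values
#' from the t distribution with J - K degrees of freedom. With a single
#' exposure the estimate coincides with the univariable fixed-effect IVW
#' estimate.
#'
#' @inheritParams mr_bma
#' @return An object of class `mvmr`: `tidy()` gives one row per exposure
#'   (`exposure`, `n_snp`, `estimate`, `std.error`, `p.value`), where
#'   `n_snp` counts the instruments with a non-zero effect on that
#'   exposure; `glance()` reports the fit dimensions, the condition number
#'   of the weighted design, and the residual heterogeneity.
#' @export
#' @examples
#' fit <- mvmr_ivw(iron_hf_matrix(),
#'                 exposures = c("ferritin", "iron", "transferrin", "ts"))
#' tidy(fit)
mvmr_ivw <- function(data, exposures, beta_y = "beta_y", se_y = "se_y") {
  assert_cols(data, c("snp_id", exposures, beta_y, se_y))
  k <- length(exposures)
  j <- nrow(data)
  if (j <= k) abort("more instruments than exposures are required")
  X <- as.matrix(data[, exposures, drop = FALSE])
  zero_col <- colSums(X != 0) == 0
  if (any(zero_col)) {
    abort(sprintf("exposure column(s) with no non-zero instrument effects: %s",
                  paste(exposures[zero_col], collapse = ", ")))
  }
  w <- 1 / data[[se_y]]^2
  Xw <- X * sqrt(w)
  if (qr(Xw)$rank < k) {
    # name the offending exposures: columns whose removal restores full rank
    offenders <- exposures[vapply(seq_len(k), function(c) {
      qr(Xw[, -c, drop = FALSE])$rank == qr(Xw)$rank
    }, logical(1))]
    abort(sprintf("collinear exposure columns in the MVMR design: %s",
                  paste(offenders, collapse = ", ")))
  }
  y <- data[[beta_y]]
  XtWX <- crossprod(Xw)
  XtWy <- crossprod(X * w, y)
  beta <- drop(solve(XtWX, XtWy))
  resid <- y - drop(X %*% beta)
  s2 <- sum(w * resid^2) / (j - k)
  se <- sqrt(diag(solve(XtWX)) * s2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), j - k)

  coll <- collinearity_check(data, exposures, se_y = se_y)
  structure(list(
    coefficients = tibble::tibble(
      exposure = exposures,
      n_snp = unname(colSums(X != 0)),
      estimate = unname(beta), std.error = unname(se),
      statistic = unname(tval), p.value = unname(pval)),
    condition_number = coll$condition_number,
    vif = coll$vif,
    sigma2 = s2, j = j, k = k, data = data,
    exposures = exposures), class = "mvmr")
}

#' @export
print.mvmr <- function(x, ...) {
  cat(sprintf("<mvmr: %d instruments, %d exposures, condition number %.3g>\n",
              x$j, x$k, x$condition_number))
  print(x$coefficients, ...)
  invisible(x)
}

#' @describeIn mvmr_ivw Per-exposure direct-effect table.
#' @param x A fitted `mvmr` object.
#' @param ... Unused.
#' @method tidy mvmr
#' @export
tidy.mvmr <- function(x, ...) x$coefficients

#' @method glance mvmr
#' @export
glance.mvmr <- function(x, ...) {
  tibble::tibble(n_snp = x$j, n_exposure = x$k,
                 condition_number = x$condition_number,
                 sigma2 = x$sigma2, df.residual = x$j - x$k)
}

#' @describeIn mvmr_ivw Direct effects with confidence intervals.
#' @param object A fitted `mvmr` object.
#' @param ci_level Confidence level for the intervals.
#' @method autoplot mvmr
#' @export
autoplot.mvmr <- function(object, ci_level = 0.95, ...) {
  z <- qnorm(1 - (1 - ci_level) / 2)
  df <- dplyr::mutate(object$coefficients,
                      low = .data$estimate - z * .data$std.error,
                      high = .data$estimate + z * .data$std.error)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$exposure)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$low, xmax = .data$high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "direct effect (per SD)", y = NULL)
}

#' Collinearity diagnostics for a multivariable MR design
#'
#' Reports the condition number (singular-value ratio) of the
#' inverse-variance-weighted design matrix and per-exposure variance
#' inflation factors obtained by regressing each weighted column on the
#' others. A VIF of `Inf` indicates an exactly collinear column.
#'
#' @inheritParams mr_bma
#' @return A list with `condition_number` and a named `vif` vector.
#' @export
collinearity_check <- function(data, exposures, se_y = "se_y") {
  assert_cols(data, c(exposures, se_y))
  X <- as.matrix(data[, exposures, drop = FALSE])
  Xw <- X / data[[se_y]]
  sv <- svd(Xw, nu = 0, nv = 0)$d
  cn <- if (min(sv) == 0) Inf else max(sv) / min(sv)
  vif <- vapply(seq_along(exposures), function(c) {
    if (length(exposures) == 1) return(1)
    others <- Xw[, -c, drop = FALSE]
    fit <- lm.fit(others, Xw[, c])
    r2 <- 1 - sum(fit$residuals^2) / sum(Xw[, c]^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  list(condition_number = cn, vif = setNames(vif, exposures))
}
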
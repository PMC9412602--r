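# Bayesian-model-averaged multivariable MR over subsets of risk factors,
# with per-variant outlier/influence diagnostics and iterative exclusion.

#' Enumerate candidate risk-factor models
#'
#' All non-empty subsets of `k` factors up to `max_size`, in a
#' deterministic order (by size, then lexicographically). The empty model
#' is excluded: only models containing at least one risk factor are
#' ranked.
#'
#' @param k Number of candidate risk factors.
#' @param max_size Largest model size considered (default `k`).
#' @return A list of integer vectors (factor indices).
#' @export
#' @examples
#' length(bma_models(4)) # 15
bma_models <- function(k, max_size = k) {
  if (k < 1) abort("`k` must be at least 1")
  if (max_size < 1 || max_size > k) abort("`max_size` must be in [1, k]")
  unlist(lapply(seq_len(max_size), function(s) {
    combn(k, s, simplify = FALSE)
  }), recursive = FALSE)
}

# Closed-form log marginal likelihood of y ~ N(0, I + sigma^2 X Xt) using
# the determinant lemma and Woodbury identity (p x p algebra only), plus
# the ridge posterior mean of the causal effects.
bma_model_fit <- function(X, y, sigma) {
  p <- ncol(X)
  j <- length(y)
  A <- crossprod(X) + diag(1 / sigma^2, p)          # (XtX + sigma^-2 I)
  if (qr(X)$rank < p) {
    abort(sprintf("collinear risk-factor columns: %s",
                  paste(colnames(X), collapse = ", ")))
  }
  Ai <- solve(A)
  xty <- crossprod(X, y)
  logdet <- as.numeric(determinant(diag(p) + sigma^2 * crossprod(X))$modulus)
  quad <- sum(y^2) - as.numeric(crossprod(xty, Ai %*% xty))
  list(log_ml = -0.5 * (j * log(2 * pi) + logdet + quad),
       theta = drop(Ai %*% xty),
       hat = rowSums((X %*% Ai) * X))               # leverages
}

#' Bayesian-model-averaged multivariable MR
#'
#' Averages multivariable MR over every non-empty subset of candidate risk
#' factors. Per instrument, the SNP-outcome effect and the SNP-exposure
#' effects are divided by the outcome standard error (the
#' inverse-variance-weighted scale); for a subset S the weighted outcome
#' vector is modelled as multivariate normal with mean zero and covariance
#' `I + sigma^2 X_S X_S'`, giving a closed-form marginal likelihood. Model
#' posteriors combine this likelihood with an independent-inclusion prior
#' (`prior_prob` per factor); the marginal inclusion probability (MIP) of
#' a factor is the summed posterior probability of all models containing
#' it, and its model-averaged causal effect (MACE) is the posterior-
#' weighted mean of its conditional (ridge) estimates.
#'
#' @param data A wide tibble: one row per instrument with `snp_id`, the
#'   SNP-outcome effect and SE, and one column of SNP-exposure effects per
#'   risk factor. Instruments not associated with a factor carry a zero
#'   entry. See [iron_hf_matrix()] and [bma_input()].
#' @param exposures Character vector naming the risk-factor columns.
#' @param beta_y,se_y Names of the outcome effect/SE columns.
#' @param prior_prob Prior inclusion probability of each factor
#'   (default 0.1).
#' @param sigma Prior scale of causal effects on the weighted scale
#'   (default 0.5).
#' @param pp_threshold Posterior-probability threshold above which a model
#'   counts as a "best model" for reporting and diagnostics (default 0.02).
#' @param max_size Largest model size enumerated.
#' @return An object of class `mr_bma` with elements `models` (one row per
#'   enumerated model: factors, log marginal likelihood, posterior
#'   probability, conditional estimates), `factors` (per-factor MIP, MACE,
#'   ranks, best-model PP and estimate) and the weighted design kept for
#'   diagnostics. `tidy()` returns the per-factor table; `glance()` the
#'   model-space summary.
#' @export
#' @examples
#' fit <- mr_bma(iron_hf_matrix(),
#'               exposures = c("ferritin", "iron", "transferrin", "ts"))
#' tidy(fit)
mr_bma <- function(data, exposures, beta_y = "beta_y", se_y = "se_y",
                   prior_prob = 0.1, sigma = 0.5, pp_threshold = 0.02,
                   max_size = length(exposures)) {
  assert_cols(data, c("snp_id", exposures, beta_y, se_y))
  assert_scalar_prob(prior_prob, "prior_prob")
  assert_scalar_prob(pp_threshold, "pp_threshold", open_left = FALSE)
  if (sigma <= 0) abort("`sigma` must be positive")
  if (any(data[[se_y]] <= 0)) abort("outcome standard errors must be positive")
  k <- length(exposures)
  j <- nrow(data)
  if (j < k) abort("at least as many instruments as risk factors are required")

  Xt <- as.matrix(data[, exposures, drop = FALSE]) / data[[se_y]]
  yt <- data[[beta_y]] / data[[se_y]]
  subsets <- bma_models(k, max_size)

  fits <- lapply(subsets, function(S) {
    bma_model_fit(Xt[, S, drop = FALSE], yt, sigma)
  })
  log_ml <- vapply(fits, `[[`, numeric(1), "log_ml")
  log_prior <- vapply(subsets, function(S) {
    length(S) * log(prior_prob) + (k - length(S)) * log(1 - prior_prob)
  }, numeric(1))
  lp <- log_ml + log_prior
  pp <- exp(lp - max(lp))
  pp <- pp / sum(pp)

  models <- tibble::tibble(
    model = vapply(subsets, function(S) paste(exposures[S], collapse = "+"),
                   character(1)),
    size = lengths(subsets),
    factors = lapply(subsets, function(S) exposures[S]),
    log_ml = log_ml,
    pp = pp,
    theta = lapply(seq_along(subsets), function(i) {
      setNames(fits[[i]]$theta, exposures[subsets[[i]]])
    }))
  models <- models[order(-models$pp), ]

  mip <- vapply(seq_len(k), function(f) {
    sum(pp[vapply(subsets, function(S) f %in% S, logical(1))])
  }, numeric(1))
  mace <- vapply(seq_len(k), function(f) {
    sum(vapply(seq_along(subsets), function(i) {
      if (f %in% subsets[[i]]) {
        pp[i] * fits[[i]]$theta[which(subsets[[i]] == f)]
      } else 0
    }, numeric(1)))
  }, numeric(1))
  pp_best <- vapply(seq_len(k), function(f) {
    in_f <- vapply(subsets, function(S) f %in% S, logical(1))
    max(pp[in_f])
  }, numeric(1))
  theta_best <- vapply(seq_len(k), function(f) {
    in_f <- which(vapply(subsets, function(S) f %in% S, logical(1)))
    i <- in_f[which.max(pp[in_f])]
    fits[[i]]$theta[which(subsets[[i]] == f)]
  }, numeric(1))

  factors <- tibble::tibble(
    factor = exposures,
    mip = mip,
    mace = mace,
    rank_by_mip = rank(-mip, ties.method = "first"),
    pp_best = pp_best,
    theta_best = theta_best,
    rank_by_pp = rank(-pp_best, ties.method = "first"))

  structure(list(models = models, factors = factors,
                 subsets = subsets, pp = pp, fits = fits,
                 snp_id = data$snp_id, Xt = Xt, yt = yt,
                 exposures = exposures, data = data,
                 beta_y = beta_y, se_y = se_y,
                 prior_prob = prior_prob, sigma = sigma,
                 pp_threshold = pp_threshold, j = j, k = k),
            class = "mr_bma")
}

#' @export
print.mr_bma <- function(x, ...) {
  cat(sprintf("<mr_bma: %d instruments, %d risk factors, %d models>\n",
              x$j, x$k, nrow(x$models)))
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn mr_bma Per-factor summary table: MIP, MACE, ranks, PP and
#'   conditional estimate of the best model containing the factor.
#' @param x A fitted `mr_bma` object.
#' @param ... Unused.
#' @method tidy mr_bma
#' @export
tidy.mr_bma <- function(x, ...) x$factors

#' @method glance mr_bma
#' @export
glance.mr_bma <- function(x, ...) {
  tibble::tibble(n_snp = x$j, n_factor = x$k, n_model = nrow(x$models),
                 best_model = x$models$model[1], pp_best = x$models$pp[1],
                 prior_prob = x$prior_prob, sigma = x$sigma)
}

#' @describeIn mr_bma Marginal inclusion probabilities as a bar chart.
#' @param object A fitted `mr_bma` object.
#' @method autoplot mr_bma
#' @export
autoplot.mr_bma <- function(object, ...) {
  df <- object$factors
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$factor, -.data$mip), y = .data$mip)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$pp_threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = "marginal inclusion probability")
}

# indices (into the enumerated model list) of the credible "best" models
best_model_indices <- function(fit) {
  idx <- which(fit$pp >= fit$pp_threshold)
  if (length(idx) == 0) idx <- which.max(fit$pp)
  idx[order(-fit$pp[idx])]
}

#' Per-variant outlier and influence diagnostics
#'
#' For every credible model (posterior probability at or above the fit's
#' `pp_threshold`) the instruments' squared residuals on the weighted
#' scale (the per-variant Q statistic) and Cook's distances are computed;
#' each variant is summarised by its worst value across those models. A
#' variant is influence-flagged when its Cook's distance exceeds the
#' model-specific reference threshold, by default the median of the
#' F(p, J - p) distribution.
#'
#' @param fit A fitted [mr_bma()] object.
#' @param cook_threshold Optional fixed Cook's-distance threshold; the
#'   default is the per-model median-F rule.
#' @return A tibble with columns `snp_id`, `q_stat`, `q_model`, `cooks_d`,
#'   `cooks_model`, `cooks_threshold`, `cooks_flag`, carrying the
#'   per-model detail in attribute `"per_model"`.
#' @export
variant_diagnostics <- function(fit, cook_threshold = NULL) {
  idx <- best_model_indices(fit)
  per_model <- purrr::map_dfr(idx, function(i) {
    S <- fit$subsets[[i]]
    p <- length(S)
    f <- fit$fits[[i]]
    res <- fit$yt - fit$Xt[, S, drop = FALSE] %*% f$theta
    h <- f$hat
    s2 <- sum(res^2) / (fit$j - p)
    thr <- cook_threshold %||% qf(0.5, p, fit$j - p)
    tibble::tibble(
      snp_id = fit$snp_id,
      model_label = paste(fit$exposures[S], collapse = "+"),
      pp = fit$pp[i],
      q_stat = drop(res)^2,
      cooks_d = drop(res)^2 / (s2 * p) * h / (1 - h)^2,
      cooks_threshold = thr)
  })
  worst_q <- per_model |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::slice_max(.data$q_stat, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("snp_id", "q_stat", q_model = "model_label")
  worst_cd <- per_model |>
    dplyr::mutate(excess = .data$cooks_d / .data$cooks_threshold) |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::slice_max(.data$excess, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::mutate(cooks_flag = .data$excess > 1) |>
    dplyr::select("snp_id", "cooks_d", cooks_model = "model_label",
                  "cooks_threshold", "cooks_flag")
  out <- dplyr::left_join(worst_q, worst_cd, by = "snp_id")
  out <- out[match(fit$snp_id, out$snp_id), ]
  attr(out, "per_model") <- per_model
  out
}

#' MR-BMA with iterative instrument exclusion
#'
#' Reproduces the staged analysis workflow: fit on the full instrument
#' set, then (i) repeatedly remove the worst outlier — the variant whose
#' per-variant Q statistic across credible models exceeds `q_max` —
#' refitting after each removal until none remains; then (ii) remove
#' influential variants flagged by Cook's distance. Influence flags are
#' taken from the full-set fit's diagnostics (influence is a property of
#' the full design a practitioner inspects in the diagnostic plots), and
#' flagged variants are removed worst-first, one per stage. A refitted
#' model-averaging panel is emitted after every removal.
#'
#' @inheritParams mr_bma
#' @param q_max Outlier cut-off on the per-variant Q statistic
#'   (default 10).
#' @param cook_threshold Optional fixed Cook's-distance threshold
#'   (default: per-model median-F rule).
#' @param max_steps Safety bound on the number of exclusions.
#' @return An object of class `mr_bma_trail`: `stages` (list of `mr_bma`
#'   fits, first = full set), `excluded` (tibble of removed variants with
#'   rule, statistic and stage), `diagnostics` (per-stage diagnostic
#'   tables). `tidy()` stacks the per-factor tables with a `stage` column.
#' @export
mr_bma_exclude <- function(data, exposures, beta_y = "beta_y",
                           se_y = "se_y", prior_prob = 0.1, sigma = 0.5,
                           pp_threshold = 0.02, q_max = 10,
                           cook_threshold = NULL, max_steps = nrow(data)) {
  refit <- function(d) {
    mr_bma(d, exposures, beta_y = beta_y, se_y = se_y,
           prior_prob = prior_prob, sigma = sigma,
           pp_threshold = pp_threshold)
  }
  k <- length(exposures)
  current <- data
  fit <- refit(current)
  stages <- list(fit)
  diagnostics <- list(variant_diagnostics(fit, cook_threshold))
  excluded <- tibble::tibble(snp_id = character(), rule = character(),
                             statistic = numeric(), stage = integer())
  steps <- 0

  # outlier phase: re-assess after each removal
  repeat {
    d <- diagnostics[[length(diagnostics)]]
    worst <- which.max(d$q_stat)
    if (d$q_stat[worst] <= q_max || steps >= max_steps) break
    if (nrow(current) - 1 < k + 1) {
      warn("stopping exclusions: too few instruments would remain")
      break
    }
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      snp_id = d$snp_id[worst], rule = "q_statistic",
      statistic = d$q_stat[worst], stage = length(stages)))
    current <- current[current$snp_id != d$snp_id[worst], , drop = FALSE]
    fit <- refit(current)
    stages <- c(stages, list(fit))
    diagnostics <- c(diagnostics, list(variant_diagnostics(fit, cook_threshold)))
    steps <- steps + 1
  }

  # influence phase: flags from the full-set fit, removed worst-first
  d0 <- diagnostics[[1]]
  flagged <- d0[d0$cooks_flag & !(d0$snp_id %in% excluded$snp_id), ]
  flagged <- flagged[order(-flagged$cooks_d / flagged$cooks_threshold), ]
  for (i in seq_len(nrow(flagged))) {
    if (!(flagged$snp_id[i] %in% current$snp_id)) next
    if (nrow(current) - 1 < k + 1) {
      warn("stopping exclusions: too few instruments would remain")
      break
    }
    if (steps >= max_steps) break
    excluded <- dplyr::bind_rows(excluded, tibble::tibble(
      snp_id = flagged$snp_id[i], rule = "cooks_distance",
      statistic = flagged$cooks_d[i], stage = length(stages)))
    current <- current[current$snp_id != flagged$snp_id[i], , drop = FALSE]
    fit <- refit(current)
    stages <- c(stages, list(fit))
    diagnostics <- c(diagnostics, list(variant_diagnostics(fit, cook_threshold)))
    steps <- steps + 1
  }

  structure(list(stages = stages, excluded = excluded,
                 diagnostics = diagnostics, q_max = q_max,
                 exposures = exposures),
            class = "mr_bma_trail")
}

#' @export
print.mr_bma_trail <- function(x, ...) {
  cat(sprintf("<mr_bma_trail: %d stage%s>\n", length(x$stages),
              if (length(x$stages) == 1) "" else "s"))
  if (nrow(x$excluded) > 0) {
    cat("excluded:\n")
    print(x$excluded)
  } else {
    cat("no instruments excluded\n")
  }
  invisible(x)
}

#' @method tidy mr_bma_trail
#' @export
tidy.mr_bma_trail <- function(x, ...) {
  purrr::map_dfr(seq_along(x$stages), function(i) {
    dplyr::mutate(tidy(x$stages[[i]]),
                  stage = i, n_snp = x$stages[[i]]$j, .before = 1)
  })
}

#' @method glance mr_bma_trail
#' @export
glance.mr_bma_trail <- function(x, ...) {
  tibble::tibble(n_stage = length(x$stages),
                 n_excluded = nrow(x$excluded),
                 n_snp_final = x$stages[[length(x$stages)]]$j)
}

#' Permutation p-values for marginal inclusion probabilities
#'
#' Permutes the weighted outcome vector across instruments and recomputes
#' each factor's MIP; the empirical p-value is the add-one-smoothed
#' proportion of permutations whose MIP reaches the observed one, so
#' p-values lie in `[1/(n_perm + 1), 1]`.
#'
#' @param fit A fitted [mr_bma()] object.
#' @param n_perm Number of permutations (at least 100; default 1000).
#' @param seed RNG seed (mandatory).
#' @return A tibble with columns `factor`, `mip`, `perm_p`.
#' @export
bma_permutation_p <- function(fit, n_perm = 1000, seed) {
  if (n_perm < 100) abort("`n_perm` must be at least 100")
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  obs <- fit$factors$mip
  k <- fit$k
  log_prior <- vapply(fit$subsets, function(S) {
    length(S) * log(fit$prior_prob) + (k - length(S)) * log(1 - fit$prior_prob)
  }, numeric(1))
  counts <- withr::with_seed(seed, {
    cnt <- numeric(k)
    for (b in seq_len(n_perm)) {
      yp <- fit$yt[sample.int(fit$j)]
      lml <- vapply(fit$subsets, function(S) {
        bma_model_fit(fit$Xt[, S, drop = FALSE], yp, fit$sigma)$log_ml
      }, numeric(1))
      lp <- lml + log_prior
      pp <- exp(lp - max(lp))
      pp <- pp / sum(pp)
      mip <- vapply(seq_len(k), function(f) {
        sum(pp[vapply(fit$subsets, function(S) f %in% S, logical(1))])
      }, numeric(1))
      cnt <- cnt + (mip >= obs)
    }
    cnt
  })
  tibble::tibble(factor = fit$exposures, mip = obs,
                 perm_p = (1 + counts) / (1 + n_perm))
}

#' Assemble a wide MR-BMA input table from harmonised instrument sets
#'
#' Builds the instruments-by-risk-factors matrix used by [mr_bma()] and
#' [mvmr_ivw()] from per-exposure harmonised tibbles: the SNP union forms
#' the rows, each exposure contributes a column of SNP-exposure effects
#' (zero where the SNP is not an instrument for that exposure), and the
#' shared SNP-outcome effect and SE are carried over.
#'
#' @param sets Named list of harmonised instrument tibbles
#'   (see [harmonise()]); names become the risk-factor columns.
#' @return A wide tibble: `snp_id`, one column per exposure, `beta_y`,
#'   `se_y`.
#' @export
bma_input <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of harmonised instrument tibbles")
  }
  snps <- unique(unlist(lapply(sets, `[[`, "snp_id")))
  out <- tibble::tibble(snp_id = snps)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    out[[nm]] <- s$beta_x[match(snps, s$snp_id)]
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  all_sets <- dplyr::bind_rows(lapply(sets, function(s) {
    s[, c("snp_id", "beta_y", "se_y")]
  }))
  first <- all_sets[match(snps, all_sets$snp_id), ]
  out$beta_y <- first$beta_y
  out$se_y <- first$se_y
  out
}
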
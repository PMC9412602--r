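exposure_cols <- c("ferritin", "iron", "transferrin", "ts")

# small random multivariable instance with known shape
random_bma_data <- function(j, k, seed, theta = rep(0, k)) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(j * k, 0, 0.2), j, k)
    se_y <- runif(j, 5e-4, 2e-3)
    beta_y <- drop(X %*% theta) + rnorm(j, 0, se_y)
    out <- tibble::as_tibble(as.data.frame(X))
    names(out) <- paste0("f", seq_len(k))
    dplyr::bind_cols(tibble::tibble(snp_id = sprintf("s%03d", seq_len(j))),
                     out, tibble::tibble(beta_y = beta_y, se_y = se_y))
  })
}

test_that("model enumeration covers all non-empty subsets deterministically", {
  expect_length(bma_models(4), 15)
  expect_length(bma_models(1), 1)
  expect_length(bma_models(4, max_size = 2), 10)
  m <- bma_models(3)
  expect_equal(m[1:3], list(1L, 2L, 3L))
  expect_equal(m[[4]], c(1L, 2L))
  expect_equal(m[[7]], c(1L, 2L, 3L))
})

test_that("posterior probabilities match a dense multivariate-normal oracle", {
  d <- random_bma_data(4, 2, seed = 11, theta = c(0.3, 0))
  fit <- mr_bma(d, c("f1", "f2"), prior_prob = 0.1, sigma = 0.5)
  Xt <- as.matrix(d[, c("f1", "f2")]) / d$se_y
  yt <- d$beta_y / d$se_y
  subsets <- list(1L, 2L, c(1L, 2L))
  log_ml <- vapply(subsets, function(S) {
    dense_log_marginal(Xt[, S, drop = FALSE], yt, 0.5)
  }, numeric(1))
  log_prior <- vapply(subsets, function(S) {
    length(S) * log(0.1) + (2 - length(S)) * log(0.9)
  }, numeric(1))
  pp <- exp(log_ml + log_prior - max(log_ml + log_prior))
  pp <- pp / sum(pp)
  got <- fit$models[match(c("f1", "f2", "f1+f2"), fit$models$model), ]
  expect_equal(got$pp, pp, tolerance = 1e-10)
  expect_equal(sum(fit$models$pp), 1, tolerance = 1e-10)
})

test_that("closed-form marginal likelihood equals the dense oracle to 1e-8", {
  for (seed in 1:6) {
    j <- sample(3:8, 1)
    k <- sample(1:3, 1)
    d <- random_bma_data(j, k, seed = 300 + seed)
    cols <- paste0("f", seq_len(k))
    fit <- mr_bma(d, cols, sigma = 0.7)
    Xt <- as.matrix(d[, cols]) / d$se_y
    yt <- d$beta_y / d$se_y
    for (i in seq_along(fit$subsets)) {
      dense <- dense_log_marginal(Xt[, fit$subsets[[i]], drop = FALSE], yt, 0.7)
      expect_equal(fit$fits[[i]]$log_ml, dense, tolerance = 1e-8)
    }
  }
})

test_that("conditional estimates are ridge posterior means; null data give zero", {
  d <- tibble::tibble(snp_id = c("a", "b"), f1 = c(0.2, -0.3),
                      beta_y = c(0, 0), se_y = c(1e-3, 1e-3))
  fit <- mr_bma(d, "f1")
  expect_equal(fit$factors$mace, 0)
  expect_equal(fit$models$theta[[1]][["f1"]], 0)

  # exactly collinear factor columns are refused by name
  d2 <- random_bma_data(6, 2, seed = 2)
  d2$f2 <- 2 * d2$f1
  expect_error(mr_bma(d2, c("f1", "f2")), "collinear")
})

test_that("the printed 12-instrument panel ranks ferritin first", {
  fit <- mr_bma(iron_hf_matrix(), exposure_cols)
  td <- tidy(fit)
  expect_equal(td$factor[td$rank_by_mip == 1], "ferritin")
  expect_equal(td$factor[td$rank_by_pp == 1], "ferritin")
  expect_equal(td$mip[td$factor == "ferritin"], 0.771, tolerance = 0.02)
  expect_lt(max(td$mip[td$factor != "ferritin"]), 0.15)
  # MACE and conditional estimates are protective (negative) for ferritin
  expect_lt(td$mace[td$factor == "ferritin"], 0)
  expect_equal(glance(fit)$best_model, "ferritin")
  # sum of model posteriors is 1; MIPs live in [0, 1]
  expect_equal(sum(fit$models$pp), 1, tolerance = 1e-10)
  expect_true(all(td$mip >= 0 & td$mip <= 1))
})

test_that("variant diagnostics flag outliers and influential instruments", {
  # an instrument with zero signal everywhere has zero residual and leverage
  d <- random_bma_data(6, 1, seed = 7, theta = 0.2)
  d$f1[6] <- 0
  d$beta_y[6] <- 0
  fit <- mr_bma(d, "f1")
  diag6 <- variant_diagnostics(fit)
  expect_equal(diag6$q_stat[6], 0)
  expect_equal(diag6$cooks_d[6], 0)

  # the printed instrument table: the ABO locus is the worst outlier in
  # every credible model, and the HFE C282Y locus is the most influential
  fit12 <- mr_bma(iron_hf_matrix(), exposure_cols)
  d12 <- variant_diagnostics(fit12)
  expect_equal(d12$snp_id[which.max(d12$q_stat)], "rs651007")
  expect_gt(max(d12$q_stat), 10)
  expect_equal(d12$snp_id[which.max(d12$cooks_d)], "rs1800562")
  expect_true(d12$cooks_flag[d12$snp_id == "rs1800562"])
  expect_equal(sum(d12$cooks_flag), 1)
})

test_that("iterative exclusion reproduces the staged instrument removals", {
  trail <- mr_bma_exclude(iron_hf_matrix(), exposure_cols)
  expect_equal(trail$excluded$snp_id, c("rs651007", "rs1800562"))
  expect_equal(trail$excluded$rule, c("q_statistic", "cooks_distance"))
  expect_length(trail$stages, 3)
  expect_equal(vapply(trail$stages, function(s) s$j, numeric(1)), c(12, 11, 10))
  # ferritin stays the top-ranked factor at every stage
  panels <- tidy(trail)
  top <- panels[panels$rank_by_mip == 1, ]
  expect_equal(unique(top$factor), "ferritin")
})

test_that("a planted gross outlier is removed, a clean instance untouched", {
  clean <- random_bma_data(20, 2, seed = 32, theta = c(0.2, 0))
  t0 <- mr_bma_exclude(clean, c("f1", "f2"))
  expect_equal(nrow(t0$excluded), 0)
  expect_length(t0$stages, 1)
  expect_equal(tidy(t0$stages[[1]]), tidy(mr_bma(clean, c("f1", "f2"))))

  spiked <- clean
  spiked$beta_y[5] <- spiked$beta_y[5] + 30 * spiked$se_y[5]
  t1 <- mr_bma_exclude(spiked, c("f1", "f2"))
  expect_equal(t1$excluded$snp_id[t1$excluded$rule == "q_statistic"], "s005")
})

test_that("permutation p-values are bounded and uniform-ish under the null", {
  d <- random_bma_data(20, 2, seed = 17)      # pure noise factors
  fit <- mr_bma(d, c("f1", "f2"))
  p <- bma_permutation_p(fit, n_perm = 100, seed = 9)
  expect_true(all(p$perm_p >= 1 / 101 & p$perm_p <= 1))
  expect_identical(p$perm_p,
                   bma_permutation_p(fit, n_perm = 100, seed = 9)$perm_p)

  # across seeds, null permutation p-values centre near 0.5
  ps <- unlist(lapply(1:6, function(s) {
    f <- mr_bma(random_bma_data(15, 2, seed = 700 + s), c("f1", "f2"))
    bma_permutation_p(f, n_perm = 100, seed = s)$perm_p
  }))
  mc_se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - 0.5), 3 * mc_se + 0.1)
  expect_error(bma_permutation_p(fit, n_perm = 10, seed = 1), "at least 100")
})

test_that("bma_input assembles the zero-filled wide matrix", {
  wide <- iron_hf_matrix()
  expect_equal(nrow(wide), 12)
  expect_named(wide, c("snp_id", exposure_cols, "beta_y", "se_y"))
  # a SNP instrumenting only ferritin carries zeros elsewhere
  row <- wide[wide$snp_id == "rs411988", ]
  expect_equal(row$ferritin, -0.044)
  expect_equal(c(row$iron, row$transferrin, row$ts), c(0, 0, 0))
  # the three shared loci are non-zero in all four columns
  shared <- wide[wide$snp_id %in% c("rs1800562", "rs1799945", "rs855791"), ]
  expect_true(all(as.matrix(shared[, exposure_cols]) != 0))
})
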
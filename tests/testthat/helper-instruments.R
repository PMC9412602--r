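# Shared helpers: small instrument tables built in code.

# a minimal harmonised instrument tibble
make_instruments <- function(beta_x, beta_y, se_y, se_x = rep(0.01, length(beta_x)),
                             snp_id = sprintf("rs%03d", seq_along(beta_x))) {
  tibble::tibble(snp_id = snp_id, beta_x = beta_x, se_x = se_x,
                 pval_x = 2 * stats::pnorm(-abs(beta_x / se_x)),
                 beta_y = beta_y, se_y = se_y,
                 pval_y = 2 * stats::pnorm(-abs(beta_y / se_y)),
                 eaf_x = 0.3, eaf_y = 0.3,
                 f_stat = (beta_x / se_x)^2, proxy_of = "",
                 exposure = "test")
}

# a minimal GWAS summary tibble
make_gwas <- function(snp_id, beta, se, pval = NULL,
                      ea = rep("A", length(snp_id)),
                      oa = rep("G", length(snp_id)),
                      eaf = rep(0.3, length(snp_id))) {
  tibble::tibble(snp_id = snp_id,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = beta, se = se,
                 pval = pval %||% (2 * stats::pnorm(-abs(beta / se))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

biomarkers <- c("ferritin", "iron", "transferrin", "ts")

write_gwas_tsv <- function(data, path = withr::local_tempfile(fileext = ".tsv",
                                                              .local_envir = parent.frame())) {
  readr::write_tsv(data, path)
  path
}

# dense-covariance log-density oracle for the model-averaging likelihood:
# evaluates the multivariate normal N(0, I + sigma^2 X X') directly in J
# dimensions (determinant + solve), independent of the low-rank identities
# used by the implementation.
dense_log_marginal <- function(X, y, sigma) {
  j <- length(y)
  Sig <- diag(j) + sigma^2 * X %*% t(X)
  -0.5 * (j * log(2 * pi) +
            as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
            drop(t(y) %*% solve(Sig, y)))
}
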
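test_that("reading the packaged tables recovers the printed instruments", {
  iron <- iron_hf_exposure("iron")
  expect_equal(nrow(iron), 5)
  rs <- iron[iron$snp_id == "rs1800562", ]
  expect_equal(rs$beta, 0.328)
  expect_equal(rs$se, 0.016)
  expect_true(all(iron$effect_allele %in% c("A", "C", "G", "T")))
  expect_equal(nrow(iron_hf_exposure("ferritin")), 6)
  expect_equal(nrow(iron_hf_exposure("transferrin")), 9)
  expect_equal(nrow(iron_hf_outcome()), 12)
})

test_that("the reader validates structure and rejects bad rows", {
  d <- make_gwas(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.3),
                 se = c(0.01, 0, 0.02))
  path <- write_gwas_tsv(d)
  got <- read_summary_table(path)
  expect_equal(got$snp_id, c("rs1", "rs3"))
  log <- selection_log(got)
  expect_equal(log$snp_id, "rs2")
  expect_equal(log$rule, "non_positive_se")

  # header-only file is vacuous, not an error
  empty <- write_gwas_tsv(d[0, ])
  expect_equal(nrow(read_summary_table(empty)), 0)

  # missing mandatory column is named in the error
  bad <- d[, setdiff(names(d), "eaf")]
  expect_error(read_summary_table(write_gwas_tsv(bad)), "eaf")

  # unparsable numerics carry the row number
  txt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\teffect_allele\tother_allele\teaf\tbeta\tse\tpval",
               "rs1\tA\tG\t0.3\tnot_a_number\t0.01\t0.5"), txt)
  expect_error(read_summary_table(txt), "row 1")

  # alleles are uppercased
  txt2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\teffect_allele\tother_allele\teaf\tbeta\tse\tpval",
               "rs1\ta\tg\t0.3\t0.1\t0.01\t0.5"), txt2)
  expect_equal(read_summary_table(txt2)$effect_allele, "A")
})

test_that("column dialects map foreign headers onto the canonical schema", {
  d <- make_gwas("rs1", 0.1, 0.01)
  names(d)[names(d) == "snp_id"] <- "rsid"
  names(d)[names(d) == "pval"] <- "P"
  path <- write_gwas_tsv(d)
  got <- read_summary_table(path, dialect = gwas_dialect(snp_id = "rsid",
                                                         pval = "P"))
  expect_equal(got$snp_id, "rs1")
  expect_error(read_summary_table(path, dialect = gwas_dialect(snp_id = "nope")),
               "nope")
})

test_that("significance selection is strict and order-preserving", {
  all12 <- dplyr::bind_rows(lapply(biomarkers,
                                   function(b) iron_hf_exposure(b)))
  all12 <- all12[!duplicated(all12$snp_id), ]
  expect_equal(nrow(select_instruments(all12, 5e-8)), 12)

  d <- make_gwas(c("a", "b", "c"), beta = c(1, 1, 1), se = c(0.1, 0.1, 0.1),
                 pval = c(5e-8, 4.9e-8, 0.2))
  sel <- select_instruments(d, 5e-8)
  expect_equal(sel$snp_id, "b")           # boundary value removed
  expect_equal(selection_log(sel)$rule, rep("p_threshold", 2))
  expect_equal(select_instruments(d, 1)$snp_id, d$snp_id)  # no-op threshold
})

test_that("greedy LD pruning keeps independent SNPs and is maximal", {
  d <- make_gwas(c("rs1800562", "rs1799945"), beta = c(0.33, -0.19),
                 se = c(0.016, 0.01), pval = c(2.7e-97, 1.1e-81))
  m <- matrix(c(1, 0.005, 0.005, 1), 2, 2,
              dimnames = list(d$snp_id, d$snp_id))
  expect_equal(nrow(ld_prune(d, m, 0.01)), 2)

  m[1, 2] <- m[2, 1] <- 1
  pruned <- ld_prune(d, m, 0.01)
  expect_equal(pruned$snp_id, "rs1800562")  # weaker p-value dropped

  expect_equal(nrow(ld_prune(d[1, ], m[1, 1, drop = FALSE], 0.01)), 1)

  m_bad <- m; m_bad[1, 2] <- 0.3
  expect_error(ld_prune(d, m_bad, 0.01), "symmetric")

  # property: no dropped SNP is unlinked to every kept SNP
  for (seed in 1:5) {
    n <- 8
    r <- withr::with_seed(seed, {
      a <- matrix(runif(n * n), n)
      a <- (a + t(a)) / 2; diag(a) <- 1; a
    })
    ids <- sprintf("s%02d", 1:n)
    dimnames(r) <- list(ids, ids)
    dd <- make_gwas(ids, beta = rep(1, n), se = rep(0.1, n),
                    pval = withr::with_seed(seed + 100, runif(n)))
    kept <- ld_prune(dd, r, 0.3)$snp_id
    dropped <- setdiff(ids, kept)
    for (s in dropped) {
      expect_true(any(r[s, kept] >= 0.3))
    }
  }
})

test_that("proxy lookup respects the r2 bound and the tie-break rules", {
  out <- make_gwas(c("rsA", "rsB"), beta = c(0.1, 0.2), se = c(0.01, 0.01),
                   pval = c(0.01, 0.001))
  m <- matrix(0, 3, 3, dimnames = list(c("rsT", "rsA", "rsB"),
                                       c("rsT", "rsA", "rsB")))
  diag(m) <- 1
  m["rsT", "rsA"] <- m["rsA", "rsT"] <- 0.95
  hit <- find_proxy("rsT", out, m, r2_min = 0.8)
  expect_equal(hit$snp_id, "rsA")
  expect_equal(hit$r2, 0.95)

  m["rsT", "rsA"] <- m["rsA", "rsT"] <- 0.7
  expect_null(find_proxy("rsT", out, m, r2_min = 0.8))

  # equal r2: smaller p-value wins, in either row order
  m["rsT", "rsA"] <- m["rsA", "rsT"] <- 0.9
  m["rsT", "rsB"] <- m["rsB", "rsT"] <- 0.9
  expect_equal(find_proxy("rsT", out, m)$snp_id, "rsB")
  expect_equal(find_proxy("rsT", out[2:1, ], m)$snp_id, "rsB")
})

test_that("palindrome detection follows the complementary-allele rule", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("AT", "A"))  # indel, never palindromic
  expect_equal(is_palindromic(c("a", "g"), c("t", "c")), c(TRUE, TRUE))
})

test_that("harmonisation aligns, flips, strand-corrects and drops correctly", {
  ex <- make_gwas("rs1", 0.2, 0.01, ea = "A", oa = "G", eaf = 0.2)
  aligned <- make_gwas("rs1", -1.7e-4, 1e-4, ea = "A", oa = "G", eaf = 0.2)
  h <- harmonise(ex, aligned)
  expect_equal(h$beta_y, -1.7e-4)
  expect_equal(h$eaf_y, 0.2)

  swapped <- make_gwas("rs1", -1.7e-4, 1e-4, ea = "G", oa = "A", eaf = 0.8)
  h2 <- harmonise(ex, swapped)
  expect_equal(h2$beta_y, 1.7e-4)
  expect_equal(h2$eaf_y, 0.2)

  # opposite strand, same orientation: T/C complements to A/G
  strand <- make_gwas("rs1", -1.7e-4, 1e-4, ea = "T", oa = "C", eaf = 0.2)
  expect_equal(harmonise(ex, strand)$beta_y, -1.7e-4)
  # opposite strand and swapped
  strand_sw <- make_gwas("rs1", -1.7e-4, 1e-4, ea = "C", oa = "T", eaf = 0.8)
  expect_equal(harmonise(ex, strand_sw)$beta_y, 1.7e-4)

  pal <- make_gwas("rs1", 0.2, 0.01, ea = "A", oa = "T")
  hp <- harmonise(pal, aligned)
  expect_equal(nrow(hp), 0)
  expect_equal(selection_log(hp)$rule, "palindromic")
  expect_equal(nrow(harmonise(pal, make_gwas("rs1", 1e-4, 1e-4, ea = "A", oa = "T"),
                              drop_palindromic = FALSE)), 1)

  bad <- make_gwas("rs1", -1.7e-4, 1e-4, ea = "A", oa = "C")
  hb <- harmonise(ex, bad)
  expect_equal(nrow(hb), 0)
  expect_equal(selection_log(hb)$rule, "incompatible_alleles")
})

test_that("harmonisation is an involution under allele swaps", {
  ex <- make_gwas(c("rs1", "rs2"), c(0.2, -0.1), c(0.01, 0.02),
                  ea = c("A", "T"), oa = c("G", "C"), eaf = c(0.2, 0.6))
  out <- make_gwas(c("rs1", "rs2"), c(-1.7e-4, 2e-4), c(1e-4, 2e-4),
                   ea = c("A", "T"), oa = c("G", "C"), eaf = c(0.2, 0.6))
  h0 <- harmonise(ex, out)
  swapped <- dplyr::mutate(out,
                           tmp = effect_allele,
                           effect_allele = other_allele,
                           other_allele = tmp,
                           beta = -beta, eaf = 1 - eaf)
  h1 <- harmonise(ex, swapped[, names(out)])
  expect_equal(as.data.frame(h1), as.data.frame(h0))
})

test_that("proxy substitution records provenance during harmonisation", {
  ex <- make_gwas("rsT", 0.2, 0.01)
  out <- make_gwas("rsP", -1e-4, 1e-4)
  m <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
              dimnames = list(c("rsT", "rsP"), c("rsT", "rsP")))
  h <- harmonise(ex, out, r2_matrix = m)
  expect_equal(h$snp_id, "rsP")
  expect_equal(h$proxy_of, "rsT")
  expect_true("proxy_substituted" %in% selection_log(h)$rule)
  # without a matrix the instrument is dropped and logged
  h2 <- harmonise(ex, out)
  expect_equal(nrow(h2), 0)
  expect_equal(selection_log(h2)$rule, "no_outcome_record")
})

test_that("the F statistic matches direct arithmetic and is scale-invariant", {
  expect_equal(f_statistic(-0.055, 0.007), (0.055 / 0.007)^2)
  expect_equal(f_statistic(-0.055, 0.007), 61.7346938776, tolerance = 1e-10)
  expect_equal(f_statistic(0.42, 0.42), 1)
  for (k in c(0.1, 3, 100)) {
    expect_equal(f_statistic(0.2 * k, 0.05 * k), f_statistic(0.2, 0.05))
  }
  # r2-based alternative: small R2 limit approaches beta^2 * 2p(1-p) * n
  f <- f_statistic(0.1, 0.01, eaf = 0.5, n = 10000, method = "r2")
  r2 <- 2 * 0.5 * 0.5 * 0.1^2
  expect_equal(f, r2 * 9998 / (1 - r2))
  expect_error(f_statistic(0.1, 0.01, method = "r2"), "eaf")
})

test_that("the weak-instrument filter drops below-threshold SNPs only", {
  d <- make_instruments(beta_x = c(0.3, 0.1), beta_y = c(1e-4, 1e-4),
                        se_y = c(1e-4, 1e-4))
  d$f_stat <- c(10, 9.99)
  kept <- filter_weak(d, 10)
  expect_equal(kept$snp_id, "rs001")      # boundary F removed
  expect_equal(selection_log(kept)$rule, "weak_instrument")
  expect_equal(nrow(filter_weak(d, 0)), 2)
  expect_warning(filter_weak(d, 1e6), "no instruments")
})
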
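make_test_data <- function(n = 200, p = 5, family = "binary", seed = 42,
                           gxe = 0) {
  spec <- scenario_spec("scenario1", n = n, p = max(p, 5), family = family,
                        alpha_gxe = gxe)
  simulate_gxe_data(spec, seed = seed)
}

test_that("single-SNP test reduces to the per-SNP Wald p at p = 1 and
           Bonferroni-corrects otherwise", {
  dat <- make_test_data(n = 300)
  g1 <- dat$geno[, c("sample_id", "SNP1")]
  res <- gxe_test_single_snp(g1, dat$pheno)
  w <- wald_pvalue(fit_glm(build_design(geno_matrix(g1)[, 1], dat$pheno)))
  expect_equal(res$p_value, w$p_value)

  res_all <- gxe_test_single_snp(dat$geno, dat$pheno)
  per <- res_all$diagnostics$snp_pvalues
  expect_equal(res_all$p_value, min(1, nrow(per) * min(per$p_value)))
  # 87 SNPs with min per-SNP p 0.125 -> global p exactly 1
  expect_identical(bonferroni_global(c(0.125, runif(86, 0.2, 1))), 1)
})

test_that("SBERIA weights take exactly the three formula values", {
  withr::with_seed(55, {
    n <- 200
    e <- rnorm(n)
    snp_pos <- rbinom(n, 2, plogis(-0.4 + 1.5 * e))   # strong + correlation
    snp_neg <- rbinom(n, 2, plogis(-0.4 - 1.5 * e))   # strong - correlation
    snp_null <- rbinom(n, 2, 0.3)                     # independent of E
  })
  geno <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                         A = snp_pos, B = snp_neg, C = snp_null)
  pheno <- tibble::tibble(sample_id = geno$sample_id,
                          y = rbinom(n, 1, 0.5), e = e)
  attr(pheno, "family") <- "binary"
  wt <- sberia_weights(geno, pheno, screen_on = "E")
  # oracle: recompute each branch from cor.test directly
  for (j in 1:3) {
    ct <- cor.test(geno_matrix(geno)[, j], e)
    expected <- 1e-4 + if (ct$p.value > 0.1) 0 else sign(unname(ct$estimate))
    expect_identical(wt$w[j], expected)
  }
  expect_identical(wt$w[1], 1.0001)
  expect_identical(wt$w[2], -0.9999)
  expect_identical(wt$w[3], 0.0001)
})

test_that("SBERIA test equals the Wald test on the hand-computed weighted
           sum and uses the full sample", {
  dat <- make_test_data(n = 250)
  wt <- sberia_weights(dat$geno, dat$pheno)
  grs_oracle <- as.numeric(geno_matrix(dat$geno) %*% wt$w)
  res <- gxe_test_sberia(dat$geno, dat$pheno)
  w <- wald_pvalue(fit_glm(build_design(grs_oracle, dat$pheno)))
  expect_equal(res$p_value, w$p_value)
  expect_equal(res$diagnostics$n, 250)
})

test_that("interaction Wald p is invariant to affine rescaling of the GRS", {
  dat <- make_test_data(n = 300, family = "continuous", gxe = log(1.05))
  wt <- sberia_weights(dat$geno, dat$pheno)
  grs <- as.numeric(geno_matrix(dat$geno) %*% wt$w)
  p1 <- wald_pvalue(fit_glm(build_design(grs, dat$pheno)))$p_value
  p2 <- wald_pvalue(fit_glm(build_design(7 * grs + 3, dat$pheno)))$p_value
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("degenerate scores give NaN p-values that never count as
           rejections", {
  n <- 100
  geno <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                         SNP1 = rep(1L, n))   # zero-variance SNP
  pheno <- toy_pheno(n)
  pheno$sample_id <- geno$sample_id
  suppressWarnings(
    expect_warning(res <- gxe_test_sberia(geno, pheno), "degenerate"))
  expect_true(is.nan(res$p_value))
  expect_false(res$reject)
})

test_that("split-sample GRS test is deterministic given a seed and tests
           only the held-out half", {
  dat <- make_test_data(n = 200, gxe = log(1.08), seed = 3)
  r1 <- suppressWarnings(gxe_test_split_grs(dat$geno, dat$pheno, seed = 11))
  r2 <- suppressWarnings(gxe_test_split_grs(dat$geno, dat$pheno, seed = 11))
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$diagnostics$n, 100)
  expect_equal(r1$diagnostics$n_train, 100)
  expect_error(gxe_test_split_grs(dat$geno[1:30, ], dat$pheno[1:30, ]),
               "N >= 40")
})

test_that("bagged test consumes every observation in both stages and
           reports OOB diagnostics", {
  dat <- make_test_data(n = 120, seed = 8)
  res <- suppressWarnings(
    gxe_test_bagged(dat$geno, dat$pheno, base = "random_forest", b = 60,
                    seed = 4))
  expect_equal(res$diagnostics$n, 120)
  expect_true(res$diagnostics$mean_oob_coverage > 0.2)
  expect_true(res$p_value >= 0 && res$p_value <= 1)

  # B = 1 edge case: most observations need the fallback, result is still
  # returned with the fallback count recorded
  res1 <- suppressWarnings(
    gxe_test_bagged(dat$geno, dat$pheno, base = "elastic_net", b = 1,
                    seed = 4))
  expect_gte(res1$diagnostics$n_fallback, 1)
})

test_that("bagged tests are reproducible from the master seed", {
  dat <- make_test_data(n = 100, seed = 12)
  r1 <- suppressWarnings(gxe_test_bagged(dat$geno, dat$pheno,
                                         base = "random_forest", b = 50,
                                         seed = 99))
  r2 <- suppressWarnings(gxe_test_bagged(dat$geno, dat$pheno,
                                         base = "random_forest", b = 50,
                                         seed = 99))
  expect_identical(r1$p_value, r2$p_value)
})

test_that("gxe_test dispatches by method name", {
  dat <- make_test_data(n = 150, seed = 21)
  for (m in c("single_snp", "sberia")) {
    res <- gxe_test(dat$geno, dat$pheno, method = m)
    expect_s3_class(res, "gxe_result")
    expect_equal(res$method, m)
    td <- tidy(res)
    expect_equal(nrow(td), 1)
    expect_true(is.finite(td$p_value))
  }
})
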
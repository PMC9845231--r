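test_that("elastic net at lambda=0 equals unpenalized least squares", {
  withr::with_seed(11, {
    n <- 100; p <- 5
    x <- matrix(rnorm(n * p), n, p)
    y <- x %*% c(1, -0.5, 0, 0.3, 0) + rnorm(n)
  })
  m <- fit_elastic_net(x, y, family = "continuous", xi = 0.5, lambda = 0)
  ols <- coef(lm(y ~ x))
  expect_equal(m$alpha0, unname(ols[1]), tolerance = 1e-4)
  expect_equal(m$weights, unname(ols[-1]), tolerance = 1e-4)
})

test_that("a huge penalty shrinks all weights to zero and leaves the
           link-scale mean as intercept", {
  withr::with_seed(12, {
    x <- matrix(rnorm(200 * 4), 200, 4)
    y <- rbinom(200, 1, 0.3)
  })
  m <- fit_elastic_net(x, y, family = "binary", lambda = 1e6)
  expect_equal(m$weights, rep(0, 4))
  expect_equal(m$alpha0, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("pure ridge assigns equal weights to duplicated predictors", {
  withr::with_seed(13, {
    n <- 150
    z <- rnorm(n)
    x <- cbind(z, z, rnorm(n))
    y <- 2 * z + rnorm(n)
  })
  m <- fit_elastic_net(x, y, family = "continuous", xi = 0, lambda = 0.1)
  expect_lt(abs(m$weights[1] - m$weights[2]), 1e-4)
  # and the cross-validated ridge keeps them close too
  mcv <- fit_elastic_net(x, y, family = "continuous", xi = 0, seed = 4)
  expect_lt(abs(mcv$weights[1] - mcv$weights[2]),
            0.05 * max(abs(mcv$weights)))
})

test_that("resampling draws have the stated sizes and are seed-determined", {
  expect_identical(draw_resample(1, "bootstrap", seed = 5), 1L)
  sub <- draw_resample(1000, "subsample", seed = 5)
  expect_length(sub, 632)
  expect_identical(sub, unique(sub))
  expect_identical(draw_resample(50, "bootstrap", seed = 8),
                   draw_resample(50, "bootstrap", seed = 8))
  expect_error(draw_resample(0), ">= 1")
  boot <- draw_resample(100, "bootstrap", seed = 3)
  expect_length(boot, 100)
  expect_true(all(boot %in% 1:100))
})

test_that("bagged ensembles store full-size in-bag multisets and b=1
           reduces to the single base model", {
  withr::with_seed(14, {
    x <- matrix(rnorm(60 * 4), 60, 4)
    y <- x[, 1] + rnorm(60)
  })
  ens <- fit_bagged(x, y, family = "continuous", base_kind = "tree",
                    b = 5, seed = 9)
  expect_length(ens$inbag, 5)
  expect_true(all(lengths(ens$inbag) == 60))
  one <- fit_bagged(x, y, family = "continuous", base_kind = "tree",
                    b = 1, seed = 9)
  single_pred <- gxebag:::predict_base_model(one$models[[1]], x)
  oob <- suppressWarnings(oob_predict(one))
  in_bag <- unique(one$inbag[[1]])
  expect_equal(oob$grs[in_bag], single_pred[in_bag])

  # constant response: every base model and the ensemble predict it
  ens_c <- fit_bagged(x, rep(3, 60), family = "continuous",
                      base_kind = "tree", b = 4, seed = 2)
  oob_c <- suppressWarnings(oob_predict(ens_c))
  expect_true(all(abs(oob_c$grs - 3) < 1e-12))
})

test_that("OOB predictions equal brute-force enumeration on fixed masks", {
  # three observations, four hand-fixed linear models and in-bag multisets
  x <- matrix(c(1, 0, 2,
                0, 1, 1), nrow = 3)
  models <- list(linear_base(0, c(1, 0)), linear_base(1, c(0, 1)),
                 linear_base(-1, c(2, 1)), linear_base(0.5, c(1, 1)))
  inbag <- list(c(1L, 1L, 2L), c(2L, 3L, 3L), c(1L, 2L, 3L), c(2L, 2L, 2L))
  ens <- manual_ensemble(models, inbag, n = 3, x = x)
  oob <- suppressWarnings(oob_predict(ens))
  oracle <- oob_brute_force(models, inbag, x)
  expect_equal(oob$grs, oracle$grs)
  expect_equal(oob$n_oob_models, oracle$n_oob)
  # observation 3 is absent from resamples 1 and 4 only
  expect_equal(oob$n_oob_models[3], 2L)
  f1 <- models[[1]]$alpha0 + sum(models[[1]]$weights * x[3, ])
  f4 <- models[[4]]$alpha0 + sum(models[[4]]$weights * x[3, ])
  expect_equal(oob$grs[3], (f1 + f4) / 2)
})

test_that("observations in-bag everywhere fall back to the full ensemble
           average with a flag", {
  x <- matrix(rnorm(4), 2, 2)
  models <- list(linear_base(1, c(0, 0)), linear_base(3, c(0, 0)))
  inbag <- list(c(1L, 2L), c(1L, 1L))  # obs 1 in-bag for every model
  ens <- manual_ensemble(models, inbag, n = 2, x = x)
  expect_warning(oob <- oob_predict(ens), "fallback")
  expect_true(oob$fallback_used[1])
  expect_equal(oob$grs[1], 2)        # full-ensemble average
  expect_equal(oob$grs[2], 3)        # only model 2 excludes obs 2
  expect_equal(oob$n_oob_models, c(0L, 1L))
})

test_that("all-constant base models give a constant OOB GRS", {
  x <- matrix(rnorm(20), 10, 2)
  models <- list(linear_base(7, c(0, 0)), linear_base(7, c(0, 0)),
                 linear_base(7, c(0, 0)))
  inbag <- replicate(3, sample(1:10, 10, replace = TRUE), simplify = FALSE)
  ens <- manual_ensemble(models, lapply(inbag, as.integer), n = 10, x = x)
  oob <- suppressWarnings(oob_predict(ens))
  expect_true(all(oob$grs == 7))
})

test_that("random forest applies the mtry and node-size rules", {
  withr::with_seed(15, {
    x <- matrix(rbinom(200 * 50, 2, 0.3), 200, 50)
    y <- rnorm(200)
  })
  rf <- fit_random_forest(x, y, family = "continuous", num_trees = 20,
                          seed = 3)
  expect_equal(rf$mtry, 16)          # floor(50/3)
  expect_equal(rf$min_node, 10)      # floor(0.05 * 200)
  sub <- fit_random_forest(x, y, family = "continuous", num_trees = 20,
                           sampling = "subsample", seed = 3)
  expect_equal(sub$min_node, floor(0.05 * floor(0.632 * 200)))

  withr::with_seed(16, {
    xs <- matrix(rbinom(30 * 5, 2, 0.3), 30, 5)
    ys <- rnorm(30)
  })
  # floor(0.05 * floor(0.632*30)) = 0: node-size floor is raised to 1
  expect_warning(tiny <- fit_random_forest(xs, ys, family = "continuous",
                                           num_trees = 5, seed = 1,
                                           sampling = "subsample"),
                 "raising")
  expect_equal(tiny$min_node, 1L)
})

test_that("package OOB averaging agrees with ranger's native OOB
           predictions", {
  withr::with_seed(17, {
    x <- matrix(rbinom(150 * 10, 2, 0.3), 150, 10)
    y <- x[, 1] * 0.5 + rnorm(150)
  })
  rf <- fit_random_forest(x, y, family = "continuous", num_trees = 100,
                          seed = 6)
  oob <- oob_predict(rf)
  native <- rf$rf$predictions
  ok <- oob$n_oob_models > 0 & is.finite(native)
  expect_true(all(ok))
  expect_equal(oob$grs[ok], native[ok], tolerance = 1e-10)
})

test_that("random-forest OOB scores are uncorrelated with pure-noise
           outcomes", {
  withr::with_seed(18, {
    n <- 500
    x <- matrix(rbinom(n * 20, 2, 0.3), n, 20)
    y <- rnorm(n)
  })
  rf <- fit_random_forest(x, y, family = "continuous", num_trees = 200,
                          seed = 10)
  oob <- oob_predict(rf)
  expect_lt(abs(cor(oob$grs, y)), 0.1)
})

test_that("structural OOB guarantee holds on a fitted ensemble", {
  withr::with_seed(19, {
    x <- matrix(rbinom(80 * 6, 2, 0.3), 80, 6)
    y <- rnorm(80)
  })
  ens <- fit_bagged(x, y, family = "continuous", base_kind = "tree",
                    b = 30, seed = 2)
  st <- oob_structure(ens)
  expect_equal(st$violations, 0)
  # every contributing model excludes the observation, from stored multisets
  oob <- oob_predict(ens)
  for (i in seq_len(10)) {
    excl <- vapply(ens$inbag, function(ix) !(i %in% ix), logical(1))
    expect_equal(oob$n_oob_models[i], sum(excl))
  }
})

test_that("bagged prediction variance is non-increasing in ensemble size", {
  withr::with_seed(20, {
    n <- 120
    x <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
    y <- x[, 1] - x[, 2] + rnorm(n)
  })
  var_at_b <- vapply(c(5, 30, 120), function(b) {
    preds <- vapply(1:8, function(s) {
      ens <- fit_bagged(x, y, family = "continuous", base_kind = "tree",
                        b = b, seed = s)
      suppressWarnings(oob_predict(ens))$grs
    }, numeric(n))
    mean(apply(preds, 1, var))
  }, numeric(1))
  expect_true(var_at_b[2] <= var_at_b[1] + 1e-8)
  expect_true(var_at_b[3] <= var_at_b[2] + 1e-8)
})
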
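new_gxe_result <- function(method, p_value, beta3, se, statistic, alpha,
                           diagnostics = list()) {
  reject <- is.finite(p_value) && p_value <= alpha
  structure(list(method = method, p_value = p_value, beta3 = beta3,
                 se = se, statistic = statistic, alpha = alpha,
                 reject = reject, diagnostics = diagnostics),
            class = "gxe_result")
}

#' @export
print.gxe_result <- function(x, ...) {
  cat("GxE interaction test (", x$method, ")\n", sep = "")
  cat(sprintf("  beta3 = %.6g  se = %.6g  p = %.6g  [alpha = %g, %s]\n",
              x$beta3, x$se, x$p_value, x$alpha,
              if (x$reject) "reject H0" else "do not reject H0"))
  invisible(x)
}

#' Tidy and glance methods for GxE test results and experiments
#'
#' `tidy()` on a test result returns the interaction-coefficient row;
#' `glance()` adds the test decision. On an experiment, `tidy()` returns
#' the per-method rejection-rate table and `glance()` a one-row summary.
#'
#' @param x A `gxe_result` or `gxe_experiment`.
#' @param ... Unused.
#' @name gxe-tidiers
NULL

#' @rdname gxe-tidiers
#' @method tidy gxe_result
#' @export
tidy.gxe_result <- function(x, ...) {
  tibble(method = x$method, estimate = x$beta3, se = x$se,
         statistic = x$statistic, p_value = x$p_value)
}

#' @rdname gxe-tidiers
#' @method glance gxe_result
#' @export
glance.gxe_result <- function(x, ...) {
  tibble(method = x$method, p_value = x$p_value, alpha = x$alpha,
         reject = x$reject,
         n = x$diagnostics$n %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fits the interaction GLM on a generic genetic score and Wald-tests the
# score-by-environment coefficient. Degenerate scores or fits give NaN.
score_interaction_test <- function(score, pheno, alpha, method,
                                   diagnostics = list()) {
  diagnostics$n <- nrow(pheno)
  if (!all(is.finite(score)) || sd(score) < 1e-12) {
    warn(paste0(method, ": genetic score is degenerate; NaN p-value"))
    return(new_gxe_result(method, NaN, NaN, NaN, NaN, alpha, diagnostics))
  }
  res <- tryCatch({
    fit <- fit_glm(build_design(score, pheno))
    w <- suppressWarnings(wald_pvalue(fit))
    if (!fit$converged && is.finite(w$p_value)) {
      warn(paste0(method, ": GLM did not converge"))
      diagnostics$converged <- FALSE
    }
    w
  }, error = function(e) {
    warn(paste0(method, ": interaction GLM failed (", conditionMessage(e),
                "); NaN p-value"))
    NULL
  })
  if (is.null(res)) {
    return(new_gxe_result(method, NaN, NaN, NaN, NaN, alpha, diagnostics))
  }
  new_gxe_result(method, res$p_value, res$estimate, res$se, res$statistic,
                 alpha, diagnostics)
}

#' Single-SNP GxE interaction test with Bonferroni correction
#'
#' Tests every SNP independently for an interaction with the exposure by
#' fitting, per SNP j,
#' \eqn{g(E[Y]) = \beta_0 + \beta_1 SNP_j + \beta_2 E + \beta_3 SNP_j \times E
#'   + \sum \gamma_i C_i}
#' (additive 0/1/2 coding) and Wald-testing \eqn{\beta_3}. The global
#' region-level p-value is the Bonferroni combination of the per-SNP
#' p-values. A SNP whose fit fails contributes p = 1 (conservative).
#'
#' @param geno Genotype tibble.
#' @param pheno Phenotype tibble (row-aligned by sample ID).
#' @param alpha Significance level; default 0.05.
#' @return A `gxe_result`; `diagnostics$snp_pvalues` holds the per-SNP
#'   tibble, and `beta3`/`se` refer to the smallest-p SNP.
#' @export
gxe_test_single_snp <- function(geno, pheno, alpha = 0.05) {
  al <- align_samples(geno, pheno)
  g <- geno_matrix(al$geno)
  pheno <- al$pheno
  per_snp <- purrr::map_dfr(seq_len(ncol(g)), function(j) {
    res <- tryCatch({
      fit <- fit_glm(build_design(g[, j], pheno))
      suppressWarnings(wald_pvalue(fit))
    }, error = function(e) NULL)
    if (is.null(res) || !is.finite(res$p_value)) {
      warn(paste0("single_snp: fit failed for SNP ", colnames(g)[j],
                  "; p set to 1"))
      return(tibble(snp = colnames(g)[j], estimate = NaN, se = NaN,
                    p_value = 1))
    }
    tibble(snp = colnames(g)[j], estimate = res$estimate, se = res$se,
           p_value = res$p_value)
  })
  global_p <- bonferroni_global(per_snp$p_value)
  best <- per_snp[which.min(per_snp$p_value), ]
  new_gxe_result("single_snp", global_p, best$estimate, best$se,
                 best$estimate / best$se, alpha,
                 diagnostics = list(n = nrow(pheno), n_snps = ncol(g),
                                    min_p = min(per_snp$p_value),
                                    snp_pvalues = per_snp))
}

#' Split-sample GRS GxE interaction test
#'
#' The classical internal-GRS test: the sample is split at random
#' (unstratified) into training and test halves; a cross-validated elastic
#' net (balance `xi`, 10-fold CV) learns GRS weights on the training half;
#' the linear GRS is predicted on the test half; and the interaction GLM is
#' fitted and Wald-tested on the test half only. Simulation evidence in the
#' GRS literature favors the 50:50 split used by default.
#'
#' @inheritParams gxe_test_single_snp
#' @param split_fraction Fraction of samples used for training; default 0.5.
#' @param xi,nfolds Elastic-net balance and CV folds.
#' @param seed Optional seed controlling the split and CV folds.
#' @return A `gxe_result` (test-half sample size in `diagnostics$n`).
#' @export
gxe_test_split_grs <- function(geno, pheno, alpha = 0.05,
                               split_fraction = 0.5, xi = 0.5, nfolds = 10,
                               seed = NULL) {
  al <- align_samples(geno, pheno)
  g <- geno_matrix(al$geno)
  pheno <- al$pheno
  n <- nrow(g)
  if (n < 40) abort("split-sample GRS test needs N >= 40")
  seeds <- child_seeds(seed, 2)
  train <- with_seed_if(seeds[[1]],
                        sample.int(n, floor(split_fraction * n)))
  test <- setdiff(seq_len(n), train)
  fam <- pheno_family(pheno)
  y_tr <- pheno$y[train]
  diag <- list(n = length(test), n_train = length(train))
  if (fam == "binary" && length(unique(y_tr)) < 2) {
    warn("split_grs: training half has a single outcome class; NaN p-value")
    return(new_gxe_result("split_grs", NaN, NaN, NaN, NaN, alpha, diag))
  }
  enet <- fit_elastic_net(g[train, , drop = FALSE], y_tr, family = fam,
                          xi = xi, nfolds = nfolds, seed = seeds[[2]])
  grs <- predict(enet, g[test, , drop = FALSE])
  pheno_test <- pheno[test, , drop = FALSE]
  attr(pheno_test, "family") <- fam
  diag$n_selected <- sum(enet$weights != 0)
  diag$lambda <- enet$lambda
  score_interaction_test(grs, pheno_test, alpha, "split_grs", diag)
}

#' SBERIA screening weights
#'
#' Per SNP j, computes the Pearson correlation of the (additive-coded) SNP
#' with the screening variable (exposure E by default, or outcome Y) and
#' its two-sided test p-value, then assigns
#' `w_j = eps` if p > theta, `w_j = eps - 1` if p <= theta with negative
#' correlation, and `w_j = eps + 1` if p <= theta with positive
#' correlation. A zero-variance SNP gets `w_j = eps` with a warning.
#'
#' @inheritParams gxe_test_single_snp
#' @param eps Offset for non-significant SNPs; default 0.0001.
#' @param theta Screening p-value threshold; default 0.1.
#' @param screen_on `"E"` (default) or `"Y"`.
#' @return Tibble with columns `snp`, `correlation`, `p_value`, `w`.
#' @export
sberia_weights <- function(geno, pheno, eps = 1e-4, theta = 0.1,
                           screen_on = c("E", "Y")) {
  screen_on <- match.arg(screen_on)
  al <- align_samples(geno, pheno)
  g <- geno_matrix(al$geno)
  v <- if (screen_on == "E") al$pheno$e else as.numeric(al$pheno$y)
  purrr::map_dfr(seq_len(ncol(g)), function(j) {
    snp <- g[, j]
    if (sd(snp) < 1e-12 || sd(v) < 1e-12) {
      warn(paste0("sberia: SNP ", colnames(g)[j],
                  " has zero variance; weight set to eps"))
      return(tibble(snp = colnames(g)[j], correlation = NA_real_,
                    p_value = NA_real_, w = eps))
    }
    ct <- cor.test(snp, v, method = "pearson")
    w <- eps + if (ct$p.value > theta) 0
         else if (unname(ct$estimate) < 0) -1 else 1
    tibble(snp = colnames(g)[j], correlation = unname(ct$estimate),
           p_value = ct$p.value, w = w)
  })
}

#' SBERIA set-based GxE interaction test
#'
#' Builds the screened weighted SNP sum
#' \eqn{GRS = \sum_j w_j SNP_j} with weights from [sberia_weights()]
#' (no intercept, additive coding) on the full sample, then fits the
#' interaction GLM and Wald-tests the GRS-by-exposure coefficient on the
#' full sample. The limited weighting avoids overfitting, so no data split
#' is needed.
#'
#' @inheritParams sberia_weights
#' @param alpha Significance level; default 0.05.
#' @return A `gxe_result` (`diagnostics$n_selected` counts screened-in SNPs).
#' @export
gxe_test_sberia <- function(geno, pheno, alpha = 0.05, eps = 1e-4,
                            theta = 0.1, screen_on = c("E", "Y")) {
  screen_on <- match.arg(screen_on)
  al <- align_samples(geno, pheno)
  g <- geno_matrix(al$geno)
  pheno <- al$pheno
  wt <- sberia_weights(al$geno, pheno, eps = eps, theta = theta,
                       screen_on = screen_on)
  grs <- as.numeric(g %*% wt$w)
  diag <- list(n = nrow(pheno), n_selected = sum(abs(wt$w) > 0.5),
               screen_on = screen_on)
  score_interaction_test(grs, pheno, alpha, "sberia", diag)
}

#' Bagged OOB GxE interaction test
#'
#' The proposed full-sample procedure: a bagged ensemble (elastic-net base
#' learners or a random forest) is fitted to the SNPs of *all* samples;
#' each sample's GRS is its out-of-bag prediction — the average over only
#' those ensemble members that never saw it; and the interaction GLM is
#' fitted and Wald-tested on *all* samples. Both the GRS construction and
#' the test therefore use the full sample, with the OOB mechanism standing
#' in for the train/test split.
#'
#' @inheritParams gxe_test_single_snp
#' @param base `"random_forest"` (default) or `"elastic_net"`.
#' @param b Ensemble size (bagging iterations or trees); default 500.
#' @param sampling `"bootstrap"` or `"subsample"` (without replacement,
#'   `floor(0.632 N)` per resample).
#' @param xi,nfolds Elastic-net balance and CV folds (elastic-net base only).
#' @param seed Optional master seed.
#' @return A `gxe_result`; diagnostics carry the fallback count and the
#'   mean OOB coverage fraction.
#' @export
gxe_test_bagged <- function(geno, pheno, alpha = 0.05,
                            base = c("random_forest", "elastic_net"),
                            b = 500, sampling = c("bootstrap", "subsample"),
                            xi = 0.5, nfolds = 10, seed = NULL) {
  base <- match.arg(base)
  sampling <- match.arg(sampling)
  al <- align_samples(geno, pheno)
  g <- geno_matrix(al$geno)
  pheno <- al$pheno
  if (nrow(g) < 40) abort("bagged GxE test needs N >= 40")
  fam <- pheno_family(pheno)
  ens <- if (base == "random_forest") {
    fit_random_forest(g, pheno$y, family = fam, num_trees = b,
                      sampling = sampling, seed = seed)
  } else {
    fit_bagged(g, pheno$y, family = fam, base_kind = "elastic_net", b = b,
               sampling = sampling, xi = xi, nfolds = nfolds, seed = seed)
  }
  oob <- oob_predict(ens)
  method <- if (base == "random_forest") "bagged_rf" else "bagged_en"
  diag <- list(n = nrow(pheno), b = b, sampling = sampling,
               n_fallback = sum(oob$fallback_used),
               mean_oob_coverage = mean(oob$n_oob_models) / b)
  stopifnot(length(oob$grs) == nrow(pheno))  # both stages use all N samples
  score_interaction_test(oob$grs, pheno, alpha, method, diag)
}

#' Run one GxE interaction test by name
#'
#' Thin dispatcher used by the experiment runner and the command-line
#' interface.
#'
#' @inheritParams gxe_test_single_snp
#' @param method One of `"single_snp"`, `"split_grs"`, `"sberia"`,
#'   `"bagged_en"`, `"bagged_rf"`.
#' @param seed Optional seed for stochastic methods.
#' @param b Ensemble size for the bagged methods; default 500.
#' @param sampling Resampling mode for the bagged methods.
#' @param ... Further arguments passed to the specific test.
#' @return A `gxe_result`.
#' @export
gxe_test <- function(geno, pheno,
                     method = c("single_snp", "split_grs", "sberia",
                                "bagged_en", "bagged_rf"),
                     alpha = 0.05, seed = NULL, b = 500,
                     sampling = "bootstrap", ...) {
  method <- match.arg(method)
  switch(method,
    single_snp = gxe_test_single_snp(geno, pheno, alpha = alpha, ...),
    split_grs = gxe_test_split_grs(geno, pheno, alpha = alpha, seed = seed,
                                   ...),
    sberia = gxe_test_sberia(geno, pheno, alpha = alpha, ...),
    bagged_en = gxe_test_bagged(geno, pheno, alpha = alpha,
                                base = "elastic_net", b = b,
                                sampling = sampling, seed = seed, ...),
    bagged_rf = gxe_test_bagged(geno, pheno, alpha = alpha,
                                base = "random_forest", b = b,
                                sampling = sampling, seed = seed, ...))
}
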
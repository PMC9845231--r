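#' Fit the interaction GLM
#'
#' Fits the generalized linear model
#' \deqn{g(E[Y]) = \beta_0 + \beta_1 score + \beta_2 E + \beta_3 score \times E
#'   + \sum_i \gamma_i C_i}
#' by maximum likelihood: logistic regression (logit link) for a binary
#' outcome, ordinary least squares (identity link) for a continuous one.
#'
#' Rank-deficient designs are tolerated: aliased columns receive `NA`
#' coefficients (downstream Wald tests on them yield `NaN` p-values).
#'
#' @param design A `gxe_design` from [build_design()].
#' @return Object of class `gxe_glm`: the underlying [stats::glm] fit plus
#'   `family` and `converged`.
#' @export
fit_glm <- function(design) {
  stopifnot(inherits(design, "gxe_design"))
  dat <- design$data
  dat$.y <- design$y
  fam <- if (design$family == "binary") binomial() else gaussian()
  if (design$family == "binary" && length(unique(design$y)) < 2) {
    abort("binary outcome is degenerate (single class)")
  }
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = fam,
        control = list(epsilon = 1e-8, maxit = 100))
  )
  structure(list(fit = fit, family = design$family,
                 converged = isTRUE(fit$converged),
                 interaction_term = design$interaction_term),
            class = "gxe_glm")
}

#' Wald test of a fitted coefficient
#'
#' Two-sided Wald test of `H0: beta = 0` for one model term. Logistic fits
#' use the asymptotic standard-normal reference; linear fits use the t
#' reference with residual degrees of freedom. A missing (aliased) or
#' zero-standard-error coefficient yields `NaN` estimate/p-value — treated
#' by callers as a non-rejection.
#'
#' @param model A `gxe_glm` from [fit_glm()].
#' @param term Character name of the coefficient to test; defaults to the
#'   interaction term.
#' @return A one-row tibble: `term`, `estimate`, `se`, `statistic`,
#'   `p_value`, `df`.
#' @export
wald_pvalue <- function(model, term = NULL) {
  stopifnot(inherits(model, "gxe_glm"))
  if (is.null(term)) term <- model$interaction_term
  cf <- coef(model$fit)
  if (!term %in% names(cf)) abort(paste0("unknown model term: ", term))
  est <- unname(cf[term])
  bad <- function(df) tibble(term = term, estimate = NaN, se = NaN,
                             statistic = NaN, p_value = NaN, df = df)
  df <- if (model$family == "binary") Inf else model$fit$df.residual
  if (is.na(est)) {
    warn(paste0("coefficient '", term, "' is aliased; returning NaN p-value"))
    return(bad(df))
  }
  vc <- vcov(model$fit)
  se <- sqrt(vc[term, term])
  if (!is.finite(se) || se <= 0) {
    warn(paste0("standard error for '", term, "' is degenerate; NaN p-value"))
    return(bad(df))
  }
  stat <- est / se
  p <- if (model$family == "binary") {
    2 * pnorm(-abs(stat))
  } else {
    2 * pt(-abs(stat), df = df)
  }
  tibble(term = term, estimate = est, se = se, statistic = stat,
         p_value = p, df = df)
}

#' Bonferroni-corrected global p-value
#'
#' Combines per-SNP interaction p-values into a single gene/region-level
#' p-value: `min(1, m * min(p))` for `m` tests. The global null of no GxE
#' interaction anywhere in the set is rejected when this value falls below
#' the significance level.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (`NaN` entries are
#'   treated as 1, i.e. non-rejections).
#' @return Single numeric global p-value.
#' @export
bonferroni_global <- function(pvals) {
  if (length(pvals) < 1) abort("empty p-value vector")
  pvals[is.nan(pvals)] <- 1
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must lie in [0,1]")
  min(1, length(pvals) * min(pvals))
}
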
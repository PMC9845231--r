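#' Fit a cross-validated elastic net
#'
#' Fits the penalized GLM
#' \deqn{\min_{\alpha_0,\alpha} \{-\ell(\alpha_0,\alpha)/N +
#'   \lambda [\,(1-\xi)\|\alpha\|_2^2/2 + \xi\|\alpha\|_1\,]\}}
#' with the penalty strength \eqn{\lambda} selected by k-fold
#' cross-validation (minimum mean deviance) over a descending grid of 100
#' log-spaced values from the data-derived \eqn{\lambda_{max}} down to
#' \eqn{10^{-4}\lambda_{max}}. Predictors are standardized internally;
#' reported weights are on the original scale. Fitting is delegated to
#' \pkg{glmnet}, whose `alpha` is exactly the balance \eqn{\xi} between the
#' lasso and ridge penalties.
#'
#' @param x Numeric N x p predictor matrix (SNP allele counts).
#' @param y Outcome vector (0/1 for binary, numeric for continuous).
#' @param family `"binary"` or `"continuous"`.
#' @param xi Penalty balance in \[0,1\] (1 = lasso, 0 = ridge); default 0.5.
#' @param nfolds CV folds; default 10.
#' @param lambda Optional fixed penalty (scalar, skips CV); `lambda = 0`
#'   gives the unpenalized fit.
#' @param seed Optional seed controlling CV fold assignment.
#' @return Object of class `enet_model` with `alpha0` (intercept), `weights`
#'   (length p, original scale), `xi`, `lambda`, `family`.
#' @export
fit_elastic_net <- function(x, y, family = c("binary", "continuous"),
                            xi = 0.5, nfolds = 10, lambda = NULL,
                            seed = NULL) {
  family <- match.arg(family)
  x <- as.matrix(x)
  if (var(as.numeric(y)) == 0) abort("outcome is constant; cannot fit elastic net")
  fam <- if (family == "binary") "binomial" else "gaussian"
  p <- ncol(x)
  # glmnet requires >= 2 predictor columns; pad with a constant (weight 0)
  padded <- p < 2
  if (padded) x <- cbind(x, `.pad` = 0)

  if (is.null(lambda)) {
    if (nrow(x) < nfolds) abort("fewer observations than CV folds")
    foldid <- with_seed_if(seed,
      sample(rep_len(seq_len(nfolds), nrow(x))))
    cvfit <- glmnet::cv.glmnet(x, y, family = fam, alpha = xi,
                               foldid = foldid, nlambda = 100,
                               lambda.min.ratio = 1e-4,
                               type.measure = "deviance",
                               standardize = TRUE)
    sel <- cvfit$lambda.min
    cf <- as.numeric(coef(cvfit, s = "lambda.min"))
    fit <- cvfit$glmnet.fit
  } else {
    stopifnot(length(lambda) == 1, lambda >= 0)
    base <- glmnet::glmnet(x, y, family = fam, alpha = xi,
                           nlambda = 30, lambda.min.ratio = 1e-4,
                           standardize = TRUE)
    lmax <- max(base$lambda)
    path <- sort(unique(c(
      exp(seq(log(max(lmax, lambda * 1.001, 1e-8)),
              log(max(lmax * 1e-4, 1e-10)), length.out = 50)),
      lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = fam, alpha = xi, lambda = path,
                          standardize = TRUE, thresh = 1e-12)
    sel <- lambda
    cf <- as.numeric(predict(fit, type = "coefficients", s = lambda,
                             exact = TRUE, x = x, y = y))
  }
  w <- cf[-1]
  if (padded) w <- w[1]
  structure(list(alpha0 = cf[1], weights = w, xi = xi, lambda = sel,
                 family = family, snp_ids = colnames(x)[seq_len(p)]),
            class = "enet_model")
}

#' Predict the linear GRS from an elastic-net model
#'
#' Returns the linear predictor \eqn{\hat\alpha_0 + x\hat\alpha} — the
#' link-scale genetic risk score for both outcome families.
#'
#' @param object An `enet_model`.
#' @param newdata Numeric matrix with the same columns as training.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.enet_model <- function(object, newdata, ...) {
  as.numeric(object$alpha0 + as.matrix(newdata) %*% object$weights)
}
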
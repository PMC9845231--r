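#' Draw a resample of observation indices
#'
#' Bootstrap sampling draws N observations with replacement; subsampling
#' draws `floor(0.632 * N)` distinct observations without replacement —
#' 0.632 being the asymptotic fraction of unique observations in a
#' bootstrap sample.
#'
#' @param n Number of observations (>= 1).
#' @param sampling `"bootstrap"` or `"subsample"`.
#' @param seed Optional seed; the draw is fully determined by it.
#' @return Integer vector of indices (a multiset for bootstrap).
#' @export
draw_resample <- function(n, sampling = c("bootstrap", "subsample"),
                          seed = NULL) {
  sampling <- match.arg(sampling)
  if (n < 1) abort("n must be >= 1")
  with_seed_if(seed, {
    if (sampling == "bootstrap") sample.int(n, n, replace = TRUE)
    else sample.int(n, floor(0.632 * n), replace = FALSE)
  })
}

fit_base_model <- function(kind, x, y, family, xi, nfolds, min_node, seed) {
  if (kind == "elastic_net") {
    fit_elastic_net(x, y, family = family, xi = xi, nfolds = nfolds,
                    seed = seed)
  } else {
    dat <- as.data.frame(x)
    dat$.y <- as.numeric(y)
    # regression tree for both families: leaves hold risk estimates for 0/1 y
    rpart::rpart(.y ~ ., data = dat, method = "anova",
                 control = rpart::rpart.control(
                   minbucket = max(1L, min_node), cp = 0, xval = 0,
                   maxsurrogate = 0, maxcompete = 0))
  }
}

predict_base_model <- function(model, x) {
  if (inherits(model, "enet_model")) predict(model, x)
  else as.numeric(predict(model, newdata = as.data.frame(x)))
}

#' Fit a bagged ensemble of GRS base learners
#'
#' Trains `b` base models, each on its own resample of the data, and stores
#' the in-bag index multisets so that out-of-bag predictions can later be
#' formed by [oob_predict()]. Base learners are cross-validated elastic
#' nets (link-scale scores) or regression trees (risk-scale scores).
#' Per-model seeds are derived deterministically from `seed`; a base model
#' that fails on its resample is retried once with a fresh derived seed and
#' then recorded as missing (excluded from all predictions) with a warning.
#'
#' @param x Numeric N x p SNP matrix (allele counts 0/1/2).
#' @param y Outcome vector.
#' @param family `"binary"` or `"continuous"`.
#' @param base_kind `"elastic_net"` or `"tree"`.
#' @param b Number of bagging iterations; default 500.
#' @param sampling `"bootstrap"` (default) or `"subsample"`.
#' @param xi,nfolds Elastic-net balance and CV folds (base learners).
#' @param seed Optional master seed.
#' @return Object of class `bagged_ensemble`: `models`, `inbag` (list of
#'   index multisets), `sampling`, `base_kind`, `n`, `x` (training matrix).
#' @export
fit_bagged <- function(x, y, family = c("binary", "continuous"),
                       base_kind = c("elastic_net", "tree"), b = 500,
                       sampling = c("bootstrap", "subsample"),
                       xi = 0.5, nfolds = 10, seed = NULL) {
  family <- match.arg(family)
  base_kind <- match.arg(base_kind)
  sampling <- match.arg(sampling)
  if (b < 1) abort("b must be >= 1")
  x <- as.matrix(x)
  n <- nrow(x)
  n_tree <- if (sampling == "bootstrap") n else floor(0.632 * n)
  min_node <- floor(0.05 * n_tree)
  seeds <- child_seeds(seed, 2L * b)
  models <- vector("list", b)
  inbag <- vector("list", b)
  n_failed <- 0L
  for (j in seq_len(b)) {
    s1 <- seeds[[j]]
    idx <- draw_resample(n, sampling, seed = s1)
    m <- tryCatch(
      fit_base_model(base_kind, x[idx, , drop = FALSE], y[idx], family,
                     xi, nfolds, min_node, seed = s1),
      error = function(e) NULL)
    if (is.null(m)) {  # one retry with the alternate derived seed
      s2 <- seeds[[b + j]]
      idx <- draw_resample(n, sampling, seed = s2)
      m <- tryCatch(
        fit_base_model(base_kind, x[idx, , drop = FALSE], y[idx], family,
                       xi, nfolds, min_node, seed = s2),
        error = function(e) NULL)
    }
    if (is.null(m)) n_failed <- n_failed + 1L
    models[[j]] <- m
    inbag[[j]] <- idx
  }
  if (n_failed > 0) {
    warn(paste0(n_failed, " base model(s) failed after retry and are ",
                "excluded from predictions"))
  }
  structure(list(models = models, inbag = inbag, sampling = sampling,
                 base_kind = base_kind, b = b, n = n, family = family,
                 x = x, n_failed = n_failed),
            class = "bagged_ensemble")
}

#' Out-of-bag prediction of the genetic risk score
#'
#' For each training observation i, averages the predictions of exactly
#' those ensemble members whose in-bag multiset excludes i — so every
#' observation's GRS comes from models that never saw it, mimicking
#' test-set prediction on the full sample. If an observation appears in
#' every resample (vanishingly rare at B = 500), its GRS falls back to the
#' full-ensemble average and is flagged.
#'
#' @param ensemble A `bagged_ensemble` or `rf_ensemble`.
#' @param x Optional matrix row-aligned with the training data (defaults to
#'   the stored training matrix).
#' @return Object of class `oob_prediction`: `grs` (length N),
#'   `n_oob_models` (models contributing per observation), `fallback_used`.
#' @export
oob_predict <- function(ensemble, x = NULL) {
  UseMethod("oob_predict")
}

#' @export
oob_predict.bagged_ensemble <- function(ensemble, x = NULL) {
  if (is.null(x)) x <- ensemble$x
  x <- as.matrix(x)
  n <- nrow(x)
  if (n != ensemble$n) abort("x must be row-aligned with the training data")
  keep <- !vapply(ensemble$models, is.null, logical(1))
  if (!any(keep)) abort("no usable base models in the ensemble")
  preds <- vapply(ensemble$models[keep],
                  function(m) predict_base_model(m, x), numeric(n))
  preds <- matrix(preds, nrow = n)
  inbag_counts <- vapply(ensemble$inbag[keep],
                         function(ix) tabulate(ix, nbins = n), integer(n))
  inbag_counts <- matrix(inbag_counts, nrow = n)
  finish_oob(preds, oob_mask = inbag_counts == 0)
}

#' @export
oob_predict.rf_ensemble <- function(ensemble, x = NULL) {
  if (is.null(x)) x <- ensemble$x
  x <- as.matrix(x)
  if (nrow(x) != ensemble$n) abort("x must be row-aligned with the training data")
  preds <- predict(ensemble$rf, data = as.data.frame(x),
                   predict.all = TRUE, num.threads = 1)$predictions
  inbag_counts <- do.call(cbind, ensemble$rf$inbag.counts)
  finish_oob(preds, oob_mask = inbag_counts == 0)
}

finish_oob <- function(preds, oob_mask) {
  n_oob <- rowSums(oob_mask)
  grs <- ifelse(n_oob > 0,
                rowSums(preds * oob_mask) / pmax(n_oob, 1),
                rowMeans(preds))
  fallback <- n_oob == 0
  if (any(fallback)) {
    warn(paste0(sum(fallback), " observation(s) were in-bag for every ",
                "model; full-ensemble fallback used"))
  }
  structure(list(grs = as.numeric(grs), n_oob_models = as.integer(n_oob),
                 fallback_used = fallback),
            class = "oob_prediction")
}

#' Fit a random forest for GRS construction
#'
#' Random forests extend bagging with randomized trees: at every split only
#' a random subset of `mtry` SNPs is considered. Defaults follow the
#' package's standard configuration for GxE testing: `mtry = floor(p/3)`,
#' 500 trees, and minimum terminal-node size `floor(0.05 * n_tree)` where
#' `n_tree` is the per-tree training size (N for bootstrap,
#' `floor(0.632 N)` for subsampling) — shallow probability-estimation trees
#' whose leaves hold stable risk estimates. A binary outcome is treated as
#' 0/1 regression so tree predictions are risks. Fitting is delegated to
#' \pkg{ranger} with in-bag bookkeeping retained; OOB scores come from
#' [oob_predict()].
#'
#' @param x Numeric N x p SNP matrix.
#' @param y Outcome vector.
#' @param family `"binary"` or `"continuous"`.
#' @param num_trees Number of trees; default 500.
#' @param sampling `"bootstrap"` or `"subsample"`.
#' @param mtry,min_node Optional overrides of the default rules.
#' @param seed Optional seed.
#' @return Object of class `rf_ensemble` wrapping the ranger fit, with
#'   `mtry`, `min_node`, `sampling`, `n`, `x`.
#' @export
fit_random_forest <- function(x, y, family = c("binary", "continuous"),
                              num_trees = 500,
                              sampling = c("bootstrap", "subsample"),
                              mtry = NULL, min_node = NULL, seed = NULL) {
  family <- match.arg(family)
  sampling <- match.arg(sampling)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  n_tree <- if (sampling == "bootstrap") n else floor(0.632 * n)
  if (is.null(min_node)) {
    min_node <- floor(0.05 * n_tree)
    if (min_node < 1) {
      warn("floor(0.05 * n_tree) is 0; raising minimum node size to 1")
      min_node <- 1L
    }
  }
  if (min_node >= n) abort("minimum node size must be smaller than N")
  dat <- as.data.frame(x)
  dat$.y <- as.numeric(y)
  rf_seed <- if (is.null(seed)) sample.int(2147483646L, 1) else as.integer(seed)
  rf <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node,
    replace = sampling == "bootstrap",
    sample.fraction = if (sampling == "bootstrap") 1 else 0.632,
    keep.inbag = TRUE, num.threads = 1, seed = rf_seed)
  structure(list(rf = rf, n = n, x = x, base_kind = "tree",
                 sampling = sampling, b = num_trees, family = family,
                 mtry = mtry, min_node = min_node),
            class = "rf_ensemble")
}

#' Inspect the structural out-of-bag guarantee
#'
#' Re-derives, from the stored in-bag records, how often an observation
#' would be predicted by a model whose training resample contained it —
#' which [oob_predict()] must never do — and the per-observation OOB
#' coverage.
#'
#' @param ensemble A `bagged_ensemble` or `rf_ensemble`.
#' @return List with `violations` (count of contributing in-bag pairs,
#'   expected 0) and `coverage` (mean fraction of models out-of-bag per
#'   observation; about exp(-1) = 0.368 for bootstrap sampling).
#' @export
oob_structure <- function(ensemble) {
  if (inherits(ensemble, "rf_ensemble")) {
    counts <- do.call(cbind, ensemble$rf$inbag.counts)
  } else {
    counts <- vapply(ensemble$inbag,
                     function(ix) tabulate(ix, nbins = ensemble$n),
                     integer(ensemble$n))
  }
  mask <- counts == 0  # models contributing to each observation's OOB score
  violations <- sum(mask & counts > 0)
  list(violations = violations, coverage = mean(rowMeans(mask)))
}
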
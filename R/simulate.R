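#' Define a simulation scenario
#'
#' Bundles the generative model and all its parameters. Three scenarios are
#' supported, matching the package's type-I-error and power studies:
#'
#' * `"null"`: marginal SNP effects, one gene-gene interaction, a marginal
#'   exposure effect, and *no* GxE interaction — used to estimate type I
#'   error. Defaults: \eqn{\alpha_1=\ldots=\alpha_4=\log 1.5},
#'   \eqn{\alpha_{GxG}=\log 2.25}, \eqn{\alpha_E=\log 1.02}, log-normal
#'   exposure.
#' * `"scenario1"`: two marginal SNP effects plus three GxE terms — two
#'   plain (\eqn{\alpha_{GxE}}) and one involving a gene-gene interaction
#'   at doubled strength (\eqn{2\alpha_{GxE}}). Defaults:
#'   \eqn{\alpha_1=\alpha_2=\log 1.5}, \eqn{\alpha_E=\log 1.01},
#'   log-normal exposure.
#' * `"scenario2"`: K SNPs with (possibly zero) main effects and K
#'   interacting SNPs `j = K/2+1 .. 1.5K`, coefficients drawn per replicate
#'   by [sample_scenario2_coeffs()]; binary exposure with P(E=1) = 0.5.
#'
#' All genetic effects act on dominant-coded SNPs; the tests always receive
#' the raw 0/1/2 matrix. For binary outcomes the intercept is calibrated
#' per data set so that the expected case fraction equals
#' `target_prevalence`.
#'
#' @param scenario `"null"`, `"scenario1"` or `"scenario2"`.
#' @param n Sample size.
#' @param p Number of simulated SNPs; default 50.
#' @param family `"binary"` or `"continuous"`.
#' @param alpha_gxe GxE effect size for scenario 1 (e.g. `log(1.05)`).
#' @param setting Scenario-2 effect-size setting 1-4.
#' @param k Scenario-2 number of main-effect/interacting SNPs; default 10.
#' @param maf_range Minor-allele-frequency range; default `c(0.15, 0.45)`.
#' @param env_median,env_sdlog Log-normal exposure median (default 23.91,
#'   an NO2-like exposure level) and log-scale SD (default 0.25).
#' @param target_prevalence Case fraction targeted by intercept calibration
#'   (binary outcomes); default 0.5.
#' @param coefficients Optional named list overriding default coefficients
#'   (`alpha1..alpha4`, `alpha_gxg`, `alpha_e`).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("null", "scenario1", "scenario2"),
                          n, p = 50, family = c("binary", "continuous"),
                          alpha_gxe = log(1.05), setting = 1, k = 10,
                          maf_range = c(0.15, 0.45),
                          env_median = 23.91, env_sdlog = 0.25,
                          target_prevalence = 0.5, coefficients = list()) {
  scenario <- match.arg(scenario)
  family <- match.arg(family)
  if (n < 1 || p < 1) abort("n and p must be >= 1")
  if (scenario == "scenario1" && p < 5) abort("scenario1 requires p >= 5")
  if (scenario == "scenario2" && p < 1.5 * k) {
    abort("scenario2 requires p >= 1.5 * k")
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("target_prevalence must lie in (0,1)")
  }
  defaults <- list(alpha1 = log(1.5), alpha2 = log(1.5), alpha3 = log(1.5),
                   alpha4 = log(1.5), alpha_gxg = log(2.25),
                   alpha_e = if (scenario == "null") log(1.02) else log(1.01))
  unknown <- setdiff(names(coefficients), names(defaults))
  if (length(unknown)) abort(paste0("unknown coefficient(s): ",
                                    paste(unknown, collapse = ", ")))
  co <- utils::modifyList(defaults, coefficients)
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 family = family, alpha_gxe = alpha_gxe,
                 setting = as.integer(setting), k = as.integer(k),
                 maf_range = maf_range, env_median = env_median,
                 env_sdlog = env_sdlog,
                 env_kind = if (scenario == "scenario2") "bernoulli"
                            else "lognormal",
                 target_prevalence = target_prevalence, coefficients = co),
            class = "scenario_spec")
}

#' Simulate independent SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, a minor allele frequency q is drawn uniformly from `maf_range`
#' and genotypes are sampled as Binomial(2, q) — i.e. Hardy-Weinberg
#' probabilities \eqn{(1-q)^2, 2q(1-q), q^2}. SNPs are independent,
#' resembling LD-pruned variants.
#'
#' @param n,p Samples and SNPs.
#' @param maf_range MAF interval within (0, 0.5]; default `c(0.15, 0.45)`.
#' @param seed Optional seed.
#' @return Genotype tibble with attribute `maf` (the drawn frequencies).
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.15, 0.45),
                               seed = NULL) {
  if (n < 1 || p < 1) abort("n and p must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be an interval within (0, 0.5]")
  }
  with_seed_if(seed, {
    maf <- runif(p, maf_range[1], maf_range[2])
    g <- vapply(maf, function(q) rbinom(n, 2L, q), integer(n))
    g <- matrix(g, nrow = n)
    new_genotypes(g,
                  sample_ids = sprintf("S%04d", seq_len(n)),
                  snp_ids = paste0("SNP", seq_len(p)),
                  maf = maf)
  })
}

#' Simulate the environmental exposure
#'
#' `"lognormal"` mimics a continuous air-pollution-like exposure: values
#' are drawn from a log-normal with log-location `log(median)` (so the
#' distribution's median equals `median`) and log-scale SD `sdlog`.
#' `"bernoulli"` is a fair binary exposure.
#'
#' @param n Number of samples.
#' @param kind `"lognormal"` or `"bernoulli"`.
#' @param median Median of the log-normal exposure; default 23.91.
#' @param sdlog Log-scale SD (>= 0); default 0.25.
#' @param prob Success probability of the Bernoulli exposure; default 0.5.
#' @param seed Optional seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_environment <- function(n, kind = c("lognormal", "bernoulli"),
                                 median = 23.91, sdlog = 0.25, prob = 0.5,
                                 seed = NULL) {
  kind <- match.arg(kind)
  if (n < 1) abort("n must be >= 1")
  if (kind == "lognormal" && sdlog < 0) abort("sdlog must be >= 0")
  with_seed_if(seed, {
    if (kind == "lognormal") rlnorm(n, meanlog = log(median), sdlog = sdlog)
    else as.numeric(rbinom(n, 1L, prob))
  })
}

#' Draw scenario-2 effect coefficients
#'
#' Effect magnitudes are drawn uniformly from setting- and family-specific
#' ranges, with independent random signs; settings 1-2 have no main
#' effects:
#'
#' | setting | main effects | GxE effects (binary) | GxE effects (continuous) |
#' |---|---|---|---|
#' | 1 | 0 | \[log 1.2, log 1.4\] | \[0.13, 0.17\] |
#' | 2 | 0 | \[log 1.4, log 1.6\] | \[0.18, 0.22\] |
#' | 3 | as GxE | \[log 1.2, log 1.4\] | \[0.13, 0.17\] |
#' | 4 | as GxE | \[log 1.4, log 1.6\] | \[0.18, 0.22\] |
#'
#' @param setting Integer 1-4.
#' @param family `"binary"` or `"continuous"`.
#' @param k Number of main-effect and of interacting SNPs; default 10.
#' @param seed Optional seed.
#' @return List with `main` (length k, SNPs 1..k) and `gxe` (length k,
#'   SNPs k/2+1..1.5k).
#' @export
sample_scenario2_coeffs <- function(setting, family = c("binary", "continuous"),
                                    k = 10, seed = NULL) {
  family <- match.arg(family)
  if (!setting %in% 1:4) abort("setting must be 1, 2, 3, or 4")
  rng <- if (family == "binary") {
    if (setting %in% c(1, 3)) c(log(1.2), log(1.4)) else c(log(1.4), log(1.6))
  } else {
    if (setting %in% c(1, 3)) c(0.13, 0.17) else c(0.18, 0.22)
  }
  with_seed_if(seed, {
    draw <- function() runif(k, rng[1], rng[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    gxe <- draw()
    main <- if (setting %in% c(1, 2)) rep(0, k) else draw()
    list(main = main, gxe = gxe)
  })
}

#' Evaluate a scenario's linear predictor (without intercept)
#'
#' Applies the scenario's generative model to dominant-coded SNPs
#' \eqn{S_j = 1(SNP_j > 0)}:
#'
#' * null: \eqn{\alpha_1 S_1 + \alpha_2 S_2 + \alpha_3 S_3 + \alpha_4 S_4 +
#'   \alpha_{GxG} S_1 S_5 + \alpha_E E}
#' * scenario1: \eqn{\alpha_1 S_1 + \alpha_2 S_2 + \alpha_E E +
#'   \alpha_{GxE}(S_3 + S_4) E + 2\alpha_{GxE} S_1 S_5 E}
#' * scenario2: \eqn{\sum_{j=1}^K \alpha_j S_j +
#'   \sum_{j=K/2+1}^{1.5K} \alpha_{GxE_j} S_j E}
#'
#' @param spec A `scenario_spec`.
#' @param g_dom Dominant-coded 0/1 matrix (columns are SNP_1..SNP_p).
#' @param e Exposure vector.
#' @param coeffs Scenario-2 coefficients from [sample_scenario2_coeffs()];
#'   ignored otherwise.
#' @return Numeric vector of linear-predictor values (no intercept).
#' @export
linear_predictor <- function(spec, g_dom, e, coeffs = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  g_dom <- as.matrix(g_dom)
  co <- spec$coefficients
  need_p <- switch(spec$scenario, null = 5, scenario1 = 5,
                   scenario2 = ceiling(1.5 * spec$k))
  if (ncol(g_dom) < need_p) {
    abort(paste0("scenario references SNP indices up to ", need_p,
                 " but only ", ncol(g_dom), " SNPs supplied"))
  }
  if (nrow(g_dom) != length(e)) abort("g_dom and e have mismatched lengths")
  switch(spec$scenario,
    null = co$alpha1 * g_dom[, 1] + co$alpha2 * g_dom[, 2] +
      co$alpha3 * g_dom[, 3] + co$alpha4 * g_dom[, 4] +
      co$alpha_gxg * g_dom[, 1] * g_dom[, 5] + co$alpha_e * e,
    scenario1 = co$alpha1 * g_dom[, 1] + co$alpha2 * g_dom[, 2] +
      co$alpha_e * e +
      spec$alpha_gxe * g_dom[, 3] * e + spec$alpha_gxe * g_dom[, 4] * e +
      2 * spec$alpha_gxe * g_dom[, 1] * g_dom[, 5] * e,
    scenario2 = {
      if (is.null(coeffs)) abort("scenario2 requires drawn coefficients")
      k <- spec$k
      main_idx <- seq_len(k)
      gxe_idx <- seq(k / 2 + 1, 1.5 * k)
      as.numeric(g_dom[, main_idx, drop = FALSE] %*% coeffs$main +
                 (g_dom[, gxe_idx, drop = FALSE] %*% coeffs$gxe) * e)
    })
}

#' Calibrate the intercept to a target prevalence
#'
#' Solves \eqn{mean_i \, expit(\alpha_0 + lp_i) = target} for
#' \eqn{\alpha_0} by bisection on \[-30, 30\] (tolerance 1e-8 on the mean),
#' so simulated binary data sets are balanced case-control samples.
#'
#' @param lp Linear predictor without intercept (finite).
#' @param target_prevalence Target case fraction in (0,1); default 0.5.
#' @return The intercept \eqn{\alpha_0}.
#' @export
calibrate_intercept <- function(lp, target_prevalence = 0.5) {
  if (!all(is.finite(lp))) abort("linear predictor must be finite")
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("target_prevalence must lie in (0,1)")
  }
  f <- function(a0) mean(plogis(a0 + lp)) - target_prevalence
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) abort("bisection bracket does not contain root")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < 1e-8) break
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  mid
}

#' Simulate outcomes from a linear predictor
#'
#' Binary: \eqn{Y_i \sim Bernoulli(expit(lp_i))}. Continuous:
#' \eqn{Y_i = lp_i + N(0,1)} standard-normal noise.
#'
#' @param lp Linear predictor *including* any intercept.
#' @param family `"binary"` or `"continuous"`.
#' @param seed Optional seed.
#' @return Numeric outcome vector.
#' @export
simulate_outcome <- function(lp, family = c("binary", "continuous"),
                             seed = NULL) {
  family <- match.arg(family)
  with_seed_if(seed, {
    if (family == "binary") rbinom(length(lp), 1L, plogis(lp))
    else lp + rnorm(length(lp))
  })
}

#' Simulate one complete GxE data set
#'
#' Draws genotypes, exposure, (for scenario 2) per-replicate coefficients,
#' calibrates the intercept for binary outcomes, and samples the outcome.
#' All randomness derives deterministically from `seed`.
#'
#' @param spec A `scenario_spec`.
#' @param seed Optional master seed for this data set.
#' @return List with `geno` (genotype tibble), `pheno` (phenotype tibble
#'   with `family` attribute), `intercept`, and `coeffs` (scenario 2 only).
#' @export
simulate_gxe_data <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  seeds <- child_seeds(seed, 4)
  geno <- simulate_genotypes(spec$n, spec$p, spec$maf_range,
                             seed = seeds[[1]])
  e <- if (spec$env_kind == "lognormal") {
    simulate_environment(spec$n, "lognormal", median = spec$env_median,
                         sdlog = spec$env_sdlog, seed = seeds[[2]])
  } else {
    simulate_environment(spec$n, "bernoulli", seed = seeds[[2]])
  }
  coeffs <- NULL
  if (spec$scenario == "scenario2") {
    coeffs <- sample_scenario2_coeffs(spec$setting, spec$family, spec$k,
                                      seed = seeds[[3]])
  }
  g_dom <- dominant_encode(geno_matrix(geno))
  lp <- linear_predictor(spec, g_dom, e, coeffs = coeffs)
  a0 <- if (spec$family == "binary") {
    calibrate_intercept(lp, spec$target_prevalence)
  } else 0
  y <- simulate_outcome(a0 + lp, spec$family, seed = seeds[[4]])
  pheno <- tibble(sample_id = geno$sample_id, y = y, e = e)
  attr(pheno, "family") <- spec$family
  list(geno = geno, pheno = pheno, intercept = a0, coeffs = coeffs)
}
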
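CANONICAL_METHODS <- c("single_snp", "split_grs", "sberia", "bagged_en",
                       "bagged_rf")

#' Run a Monte-Carlo GxE testing experiment
#'
#' Repeats, `reps` times: simulate a fresh data set from `spec`, apply
#' every requested test to the *same* replicate data, and record whether
#' each test rejects (a finite p-value at or below `alpha`; `NaN`
#' p-values and method failures count as non-rejections and are logged).
#' Under the null scenario the per-method rejection rate estimates the
#' type I error; under the power scenarios it estimates statistical power.
#'
#' Replicate seeds are derived from `seed` by position, and method seeds
#' from each replicate seed by the method's fixed canonical index, so
#' adding or removing methods never perturbs data generation or the other
#' methods' draws. The whole experiment is a pure function of
#' `(spec, methods, reps, alpha, seed)`.
#'
#' @param spec A [scenario_spec()].
#' @param methods Character vector from `"single_snp"`, `"split_grs"`,
#'   `"sberia"`, `"bagged_en"`, `"bagged_rf"`.
#' @param reps Number of independent replicates.
#' @param alpha Significance level; default 0.05.
#' @param seed Master seed.
#' @param b Ensemble size for the bagged methods; default 500.
#' @param sampling Resampling mode for the bagged methods.
#' @param method_args Named list of per-method argument lists, e.g.
#'   `list(bagged_en = list(b = 50))` — overrides the shared defaults.
#' @return Object of class `gxe_experiment`; `tidy()` gives the per-method
#'   tibble with rejection rates and exact binomial 95% CIs.
#' @export
run_experiment <- function(spec, methods, reps, alpha = 0.05, seed = NULL,
                           b = 500, sampling = "bootstrap",
                           method_args = list()) {
  stopifnot(inherits(spec, "scenario_spec"))
  methods <- match.arg(methods, CANONICAL_METHODS, several.ok = TRUE)
  if (reps < 1) abort("reps must be >= 1")
  rep_seeds <- child_seeds(seed, reps)
  counters <- stats::setNames(
    replicate(length(methods), list(reject = 0L, nan = 0L, fail = 0L,
                                    fallback = 0L), simplify = FALSE),
    methods)
  t0 <- Sys.time()
  for (r in seq_len(reps)) {
    rs <- rep_seeds[[r]]
    dat <- simulate_gxe_data(spec, seed = rs)
    mseeds <- child_seeds(rs, 10L + length(CANONICAL_METHODS))
    for (m in methods) {
      midx <- 10L + match(m, CANONICAL_METHODS)
      args <- utils::modifyList(
        list(geno = dat$geno, pheno = dat$pheno, method = m, alpha = alpha,
             seed = mseeds[[midx]], b = b, sampling = sampling),
        method_args[[m]] %||% list())
      res <- tryCatch(suppressWarnings(do.call(gxe_test, args)),
                      error = function(e) e)
      if (inherits(res, "error")) {
        counters[[m]]$fail <- counters[[m]]$fail + 1L
        next
      }
      if (!is.finite(res$p_value)) counters[[m]]$nan <- counters[[m]]$nan + 1L
      if (isTRUE(res$reject)) counters[[m]]$reject <- counters[[m]]$reject + 1L
      fb <- res$diagnostics$n_fallback
      if (!is.null(fb)) counters[[m]]$fallback <- counters[[m]]$fallback + fb
    }
  }
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  results <- purrr::map_dfr(methods, function(m) {
    k <- counters[[m]]$reject
    ci <- binom.test(k, reps)$conf.int
    tibble(method = m, scenario = spec$scenario, n = spec$n, p = spec$p,
           family = spec$family, reps = reps, rejections = k,
           rejection_rate = k / reps, ci_low = ci[1], ci_high = ci[2],
           n_nan = counters[[m]]$nan, n_failed = counters[[m]]$fail,
           n_fallback = counters[[m]]$fallback)
  })
  structure(list(results = results, spec = spec, methods = methods,
                 reps = reps, alpha = alpha, seed = seed,
                 elapsed_secs = elapsed),
            class = "gxe_experiment")
}

#' @export
print.gxe_experiment <- function(x, ...) {
  cat("GxE Monte-Carlo experiment:", x$spec$scenario,
      sprintf("(N = %d, p = %d, %s outcome, %d replicates, alpha = %g)\n",
              x$spec$n, x$spec$p, x$spec$family, x$reps, x$alpha))
  print(x$results, ...)
  invisible(x)
}

#' @rdname gxe-tidiers
#' @method tidy gxe_experiment
#' @export
tidy.gxe_experiment <- function(x, ...) x$results

#' @rdname gxe-tidiers
#' @method glance gxe_experiment
#' @export
glance.gxe_experiment <- function(x, ...) {
  tibble(scenario = x$spec$scenario, n = x$spec$n, p = x$spec$p,
         family = x$spec$family, reps = x$reps, alpha = x$alpha,
         n_methods = length(x$methods), elapsed_secs = x$elapsed_secs)
}

#' Plot rejection rates of a Monte-Carlo experiment
#'
#' Bar chart of per-method rejection rates with exact binomial 95%
#' confidence intervals and the nominal level as a dashed reference line.
#'
#' @param object A `gxe_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gxe_experiment
#' @export
autoplot.gxe_experiment <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method,
                                  y = .data$rejection_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = NULL, y = "Rejection rate",
                  title = sprintf("%s scenario (N = %d, %s outcome, %d reps)",
                                  object$spec$scenario, object$spec$n,
                                  object$spec$family, object$reps)) +
    ggplot2::theme_minimal()
}
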
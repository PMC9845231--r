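# Small in-code fixtures shared across test files.

# Deterministic toy genotype tibble (values exercise all of {0,1,2}).
toy_geno <- function(n = 6, p = 3, seed = 101) {
  withr::with_seed(seed, {
    g <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    out <- tibble::as_tibble(as.data.frame(g))
    names(out) <- paste0("SNP", seq_len(p))
    dplyr::bind_cols(tibble::tibble(sample_id = sprintf("S%02d", 1:n)), out)
  })
}

toy_pheno <- function(n = 6, family = "binary", seed = 202) {
  withr::with_seed(seed, {
    y <- if (family == "binary") rep_len(c(0, 1), n) else rnorm(n)
    out <- tibble::tibble(sample_id = sprintf("S%02d", 1:n),
                          y = y, e = runif(n, 10, 40))
    attr(out, "family") <- family
    out
  })
}

# Hand-constructed linear base models (enet_model objects) for OOB oracles.
linear_base <- function(alpha0, weights) {
  structure(list(alpha0 = alpha0, weights = weights, xi = 0.5, lambda = 0,
                 family = "continuous", snp_ids = NULL),
            class = "enet_model")
}

# Assemble a bagged_ensemble by hand from models + in-bag index lists.
manual_ensemble <- function(models, inbag, n, x) {
  structure(list(models = models, inbag = inbag, sampling = "bootstrap",
                 base_kind = "elastic_net", b = length(models), n = n,
                 family = "continuous", x = x, n_failed = 0L),
            class = "bagged_ensemble")
}

# Brute-force OOB oracle: for each observation, enumerate the models whose
# in-bag multiset excludes it and average their predictions directly.
oob_brute_force <- function(models, inbag, x) {
  n <- nrow(x)
  grs <- numeric(n)
  n_oob <- integer(n)
  for (i in seq_len(n)) {
    f_set <- which(vapply(inbag, function(ix) !(i %in% ix), logical(1)))
    n_oob[i] <- length(f_set)
    preds <- vapply(f_set, function(j) {
      m <- models[[j]]
      m$alpha0 + sum(m$weights * x[i, ])
    }, numeric(1))
    grs[i] <- if (length(f_set) > 0) mean(preds) else {
      mean(vapply(models, function(m) m$alpha0 + sum(m$weights * x[i, ]),
                  numeric(1)))
    }
  }
  list(grs = grs, n_oob = n_oob)
}

# Exact binomial acceptance region for a Monte-Carlo rejection count at
# nominal level `p0`: the central 95% probability interval of Binom(n, p0).
binom_region <- function(n, p0 = 0.05) {
  c(qbinom(0.025, n, p0), qbinom(0.975, n, p0))
}
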
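# Deterministic seed splitting: one master seed per run, child seeds derived
# by position so adding consumers never perturbs earlier draws.

#' Derive child seeds from a master seed
#'
#' @param seed Integer master seed (or `NULL` for none).
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds, or `NULL` seeds if `seed` is `NULL`.
#' @export
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(withr::with_seed(as.integer(seed),
                           sample.int(2147483646L, n, replace = FALSE)))
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
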
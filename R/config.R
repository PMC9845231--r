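# Run configuration and tabular result writers backing the `gxe` CLI.

CONFIG_DEFAULTS <- list(
  method = NULL, methods = NULL, scenario = NULL,
  n = NULL, p = 50L, family = "binary", alpha = 0.05,
  b = 500L, trees = 500L, xi = 0.5, folds = 10L, sampling = "bootstrap",
  alpha_gxe = log(1.05), setting = 1L, k = 10L,
  env_median = 23.91, env_sdlog = 0.25, target_prevalence = 0.5,
  reps = 100L, seed = NULL,
  genotypes = NULL, phenotypes = NULL, out = NULL, out_prefix = NULL)

#' Parse and validate a run configuration
#'
#' Merges a YAML configuration file and/or a named list of overrides onto
#' the package defaults (B = 500, trees = 500, xi = 0.5, 10 CV folds,
#' alpha = 0.05), rejecting unknown keys and out-of-range values.
#'
#' @param path Optional path to a YAML configuration file.
#' @param overrides Optional named list of settings (e.g. parsed CLI flags);
#'   takes precedence over the file.
#' @return A validated named list of class `run_config`.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- CONFIG_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    file_cfg <- yaml::read_yaml(path)
    # YAML 1.1 reads a bare `n:` key as boolean; map it back to `n`
    names(file_cfg)[names(file_cfg) == "FALSE"] <- "n"
    unknown <- setdiff(names(file_cfg), names(CONFIG_DEFAULTS))
    if (length(unknown)) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  unknown <- setdiff(names(overrides), names(CONFIG_DEFAULTS))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, overrides)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) abort("alpha must lie in (0,1)")
  if (cfg$xi < 0 || cfg$xi > 1) abort("xi must lie in [0,1]")
  if (cfg$b < 1 || cfg$trees < 1) abort("b and trees must be >= 1")
  if (cfg$folds < 2) abort("folds must be >= 2")
  if (!cfg$sampling %in% c("bootstrap", "subsample")) {
    abort("sampling must be 'bootstrap' or 'subsample'")
  }
  if (!cfg$family %in% c("binary", "continuous")) {
    abort("family must be 'binary' or 'continuous'")
  }
  structure(cfg, class = "run_config")
}

#' Serialize the effective configuration
#'
#' Writes the fully-resolved configuration (after defaults and overrides)
#' to YAML so a run can be reproduced exactly; `parse_config()` on the
#' emitted file round-trips to an identical configuration.
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(unclass(out), path, precision = 17)
  invisible(path)
}

#' Write test or experiment results as TSV
#'
#' Single-test results become one row (`method`, `p_value`, `beta3`, `se`,
#' `diagnostics` as a JSON string); experiment results one row per method,
#' sorted by method name. Floats are written at 6 significant digits and
#' the column order is fixed.
#'
#' @param result A `gxe_result` or `gxe_experiment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  if (inherits(result, "gxe_result")) {
    diag <- result$diagnostics
    diag$snp_pvalues <- NULL  # keep the JSON blob small
    tbl <- tibble(method = result$method,
                  p_value = signif(result$p_value, 6),
                  beta3 = signif(result$beta3, 6),
                  se = signif(result$se, 6),
                  diagnostics = as.character(jsonlite::toJSON(
                    diag, auto_unbox = TRUE, digits = 6)))
  } else if (inherits(result, "gxe_experiment")) {
    tbl <- result$results |>
      dplyr::arrange(.data$method) |>
      dplyr::mutate(dplyr::across(dplyr::where(is.double),
                                  ~ signif(.x, 6)))
  } else {
    abort("result must be a gxe_result or gxe_experiment")
  }
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}
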
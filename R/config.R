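#' Read a run configuration file
#'
#' YAML or JSON file holding the knobs of a prepare/train run: dedup
#' `tolerance`, CV `size_threshold`, `seed`, `variant`, network controls
#' (`epochs`, `learning_rate`, `patience`), significance `aggregate`,
#' and optional per-predictor overrides of `native_range`,
#' `default_cutoff`. Unknown keys are an error; absent keys keep the
#' package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values merged over defaults.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- list(tolerance = 0.04, size_threshold = 1000L, seed = 1L,
                   variant = "dann", epochs = 300L, learning_rate = 0.05,
                   patience = 50L, aggregate = "euclidean",
                   test_fraction = 0.2, predictors = NULL)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, cfg)
}
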
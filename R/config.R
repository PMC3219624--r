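#' Default pipeline configuration
#'
#' Flat named list of every tunable pipeline parameter with its default.
#' Thresholds mirror the assay's analysis choices: 5x detection over
#' background, 2\% low-start filter, good-insertion window 5--80\%,
#' phenotype alpha 0.001, Bonferroni alpha 0.01, sick/healthy polarity
#' thresholds -2/-1, significant-change gates |fitness| > 1 and |Z| > 2.5,
#' 20 significance bins, 10 CV folds, 500 trees.
#'
#' @return named list of parameters
#' @export
defaultPipelineConfig <- function() {
  list(
    # inputs: when simulate is FALSE, tables are read from input_dir
    simulate = TRUE,
    input_dir = "",
    # synthetic data scale (the default study emulation)
    n_genes = 400L, n_insertions = 900L, n_conditions = 40L, n_controls = 14L,
    probe_sd = 0.3, plate_sd = 0.15, sparsity = 0.05, effect_scale = 3,
    operon_share = 0.8, subrole_effect = 2, with_expression = TRUE,
    # strain fitness
    detect_multiplier = 5, low_start_fraction = 0.02,
    replicon_pass = TRUE, plate_pass = TRUE,
    # gene scoring
    good_window_low = 0.05, good_window_high = 0.80,
    min_stratum = 50L, phenotype_alpha = 0.001, bonferroni_alpha = 0.01,
    change_z_gate = 2.5,
    # compendium
    sick_threshold = -2, healthy_threshold = -1,
    min_experiments = 10L, cofitness_threshold = 0.5, n_bins = 20L,
    # prediction
    k_folds = 10L, n_trees = 500L, feature_source = "fitness",
    n_shuffles = 50L,
    # randomness
    seed = 1L)
}

.configBounds <- list(
  low_start_fraction = c(0, 1 - 1e-9), sparsity = c(0, 1),
  operon_share = c(0, 1), good_window_low = c(0, 1),
  good_window_high = c(0, 1), phenotype_alpha = c(1e-12, 1 - 1e-12),
  bonferroni_alpha = c(1e-12, 1 - 1e-12))

#' Read a pipeline configuration file
#'
#' Parses a flat "key = value" text file (one pair per line; "#" comments
#' allowed). Unknown keys are rejected; values are coerced to the type of
#' the default and bounds-checked.
#'
#' @param path config file, or NULL for pure defaults
#' @param overrides named list applied after the file
#' @return validated config list
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultPipelineConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) validationError("config file not found: %s", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2)
        validationError("config line not of the form key = value: '%s'", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      cfg <- setConfigValue(cfg, key, val)
    }
  }
  for (key in names(overrides))
    cfg <- setConfigValue(cfg, key, overrides[[key]])
  if (cfg$good_window_low >= cfg$good_window_high)
    validationError("good_window_low must be below good_window_high")
  cfg
}

setConfigValue <- function(cfg, key, val) {
  if (!key %in% names(cfg))
    validationError("unknown config key '%s'", key)
  def <- cfg[[key]]
  if (is.logical(def)) {
    v <- as.logical(val)
    if (is.na(v)) validationError("config '%s': not a logical: '%s'", key, val)
  } else if (is.numeric(def)) {
    v <- suppressWarnings(as.numeric(val))
    if (is.na(v)) validationError("config '%s': not numeric: '%s'", key, val)
    if (is.integer(def)) v <- as.integer(v)
    b <- .configBounds[[key]]
    if (!is.null(b) && (v < b[1] || v > b[2]))
      validationError("config '%s' = %s outside [%g, %g]", key, val, b[1], b[2])
  } else v <- as.character(val)
  cfg[[key]] <- v
  cfg
}

# stable hash of a config for provenance stamping
configHash <- function(cfg) {
  txt <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "=", collapse = ";")
  f <- tempfile()
  writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}
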
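read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required for YAML configs", call. = FALSE)
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  config
}

validate_run_config <- function(config) {
  cfg_error <- function(msg) stop(structure(
    class = c("alleloscreen_config_error", "error", "condition"),
    list(message = msg, call = NULL)))
  defaults <- list(alpha = 0.05, control = "CK", seed = 1L,
                   ri_level = "treatment", normalization = "vector",
                   simulate = TRUE, effects = "demo",
                   parameters = germination_parameters())
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    cfg_error("alpha must lie in (0, 1)")
  if (!config$ri_level %in% c("treatment", "dish"))
    cfg_error("ri_level must be 'treatment' or 'dish'")
  if (!config$normalization %in% c("vector", "minmax"))
    cfg_error("normalization must be 'vector' or 'minmax'")
  if (isTRUE(config$simulate)) {
    des <- config$design
    config$design_obj <- do.call(allelo_design, c(
      des[intersect(names(des),
                    c("treatments", "control", "seeds_per_dish",
                      "dishes_per_treatment", "physio_bio_reps",
                      "physio_tech_reps"))],
      list(seed = as.integer(config$seed))))
    if (!identical(config$design_obj$control, config$control))
      cfg_error("design control label differs from config control")
  } else {
    for (nm in c("germination_csv", "seedlings_csv"))
      if (is.null(config[[nm]]) || !file.exists(config[[nm]]))
        cfg_error(paste("input file missing for", nm))
  }
  config
}

resolve_effects <- function(config) {
  eff <- config$effects
  if (identical(eff, "demo")) return(demo_effects(config$design_obj))
  if (is.list(eff) && all(vapply(eff, is.list, logical(1)))) {
    return(lapply(eff, function(e) do.call(treatment_effect, e)))
  }
  stop(structure(class = c("alleloscreen_config_error", "error", "condition"),
                 list(message = "effects must be \"demo\" or a named list of effect specs",
                      call = NULL)))
}

#' Run the full screening pipeline from a configuration
#'
#' Config-driven end-to-end run: simulate a bioassay (or read the
#' germination/seedling/physiology CSVs named in the config), compute
#' germination metrics, allelopathy scores, the TOPSIS ranking, the
#' comparison layer, and write every stage's CSV plus a JSON run manifest
#' to `outdir`. Failure modes carry distinct condition classes
#' (`alleloscreen_config_error`, `alleloscreen_missing_control`,
#' `alleloscreen_degenerate_weights`); no partial outputs are left behind
#' on error.
#'
#' @param config A list, or path to a JSON/YAML file, with fields:
#'   `simulate` (logical), `design` (list of [allelo_design()] arguments),
#'   `effects` (`"demo"` or named list of [treatment_effect()] argument
#'   lists), or `germination_csv` / `seedlings_csv` / `physiology_csv`
#'   paths; plus `control`, `alpha`, `seed`, `parameters`, `ri_level`,
#'   `normalization`.
#' @param outdir Output directory.
#' @return Invisibly, the run manifest (also written to `manifest.json`):
#'   config hash, package version, seed, per-output row counts, warnings.
#' @export
run_pipeline <- function(config, outdir) {
  config <- validate_run_config(read_run_config(config))
  warnings_seen <- character(0)
  withCallingHandlers({
    if (isTRUE(config$simulate)) {
      effects <- resolve_effects(config)
      sim <- simulate_germination(config$design_obj, effects)
      germ <- sim$dishes; seedl <- sim$seedlings
      physio <- simulate_physiology(config$design_obj, effects)
    } else {
      germ <- utils::read.csv(config$germination_csv)
      seedl <- utils::read.csv(config$seedlings_csv)
      physio <- if (!is.null(config$physiology_csv))
        utils::read.csv(config$physiology_csv) else
        data.frame(treatment = character(0), bio_rep = integer(0),
                   tech_rep = integer(0), indicator = character(0),
                   value = numeric(0))
    }
    scr <- allelo_screen(germ, seedl,
                         physiology = if (nrow(physio)) physio else NULL,
                         control = config$control, alpha = config$alpha,
                         parameters = config$parameters,
                         ri_level = config$ri_level,
                         normalization = config$normalization,
                         seed = config$seed)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  staging <- tempfile("allelo_run_")
  dir.create(staging, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(staging, name), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    nrow(df)
  }
  counts <- c(
    germination = wr(germ, "germination.csv"),
    seedlings = wr(seedl, "seedlings.csv"),
    metrics = wr(scr$metrics$treatment, "metrics.csv"),
    metrics_dish = wr(scr$metrics$dish, "metrics_dish.csv"),
    allelopathy = wr(scr$allelopathy$ri, "allelopathy.csv"),
    se = wr(scr$allelopathy$se, "se.csv"),
    topsis = wr(data.frame(alternative = scr$topsis$alternatives,
                           d_plus = scr$topsis$d_plus,
                           d_minus = scr$topsis$d_minus,
                           closeness = scr$topsis$closeness,
                           rank = scr$topsis$rank), "topsis.csv"),
    weights = wr(data.frame(criterion = names(scr$topsis$weights),
                            entropy = NA_real_,
                            weight = scr$topsis$weights), "weights.csv"),
    anova = wr(do.call(rbind, lapply(names(scr$comparisons), function(p) {
      cmp <- scr$comparisons[[p]]
      if (!inherits(cmp, "duncan_mrt"))
        return(data.frame(parameter = p, treatment = NA, mean = NA,
                          F_stat = NA, p_value = NA, letters = NA))
      data.frame(parameter = p, treatment = names(cmp$means),
                 mean = unname(cmp$means), F_stat = cmp$anova$F_stat,
                 p_value = cmp$anova$p_value, letters = unname(cmp$letters),
                 stringsAsFactors = FALSE)
    })), "anova.csv"))
  if (nrow(physio)) {
    counts <- c(counts, physiology = wr(physio, "physiology.csv"),
                pca_scores = wr(scr$pca$scores, "pca_scores.csv"),
                pca_loadings = wr(data.frame(
                  indicator = rownames(scr$pca$loadings),
                  scr$pca$loadings), "pca_loadings.csv"),
                radar = wr(scr$radar, "radar.csv"))
  }
  if (!is.null(scr$importance))
    counts <- c(counts,
                importance = wr(as.data.frame(scr$importance), "importance.csv"))

  cfg_for_hash <- config[setdiff(names(config), "design_obj")]
  cfg_file <- file.path(staging, "config.json")
  jsonlite::write_json(cfg_for_hash, cfg_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("alleloscreen")),
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    rows = as.list(counts),
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # outputs land in outdir only after every stage has succeeded
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  for (f in list.files(staging))
    file.copy(file.path(staging, f), file.path(outdir, f), overwrite = TRUE)
  unlink(staging, recursive = TRUE)
  invisible(manifest)
}
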
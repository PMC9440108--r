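# Orchestration: a configurable end-to-end run from (synthetic or
# on-disk) assemblage tables to ordination screening, model comparison,
# reconstruction, assessment and seasonal attribution, with per-stage
# output manifests. All randomness flows from the config seed through
# derive_seed(); deterministic stages re-run bit-identically.

#' Build a pipeline configuration
#'
#' Returns the default configuration, optionally overridden by a nested
#' list (only supplied keys are replaced). The configuration round-trips
#' losslessly through YAML via \code{\link{read_pipeline_config}} /
#' \code{\link{write_pipeline_config}}.
#'
#' @param ... named overrides, e.g. \code{seed = 7},
#'   \code{simulate = list(n_sites = 100)}.
#' @return a \code{pipeline_config} nested list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 42,
    outdir = "paleoseason_out",
    inputs = list(modern_taxa = NULL, modern_env = NULL, fossil_taxa = NULL),
    simulate = list(n_sites = 382, n_species = 40, count_depth = 500,
                    correlation = 0.8, resolution = 250),
    ordination = list(n_perm = 199, vif_threshold = 20, alpha = 0.05,
                      metric = "bray"),
    calibration = list(methods = c("WA", "WAPLS", "MAT", "LW-WA", "LW-WAPLS"),
                       n_components = 2, compare_targets = "MAT",
                       n_boot = 100, metric = "sqchord"),
    reconstruction = list(method = "LW-WAPLS", n_components = 2,
                          targets = c(SEASONS, "MAT"), with_errors = TRUE,
                          n_boot = 100),
    assessment = list(method = "WAPLS", n_random = 199, metric = "sqchord"),
    attribution = list(dt = 100, window = 1000, step = 100,
                       lowess_span = 0.3, bin_width = 5)
  )
  ov <- list(...)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      if (is.null(over[[nm]])) next # YAML nulls keep the default
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_in(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  structure(merge_in(cfg, ov), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a \code{pipeline_config}.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

pipeline_stages <- c("simulate", "ordinate", "calibrate", "reconstruct",
                     "assess", "attribute")

stage_path <- function(config, name) file.path(config$outdir, name)

require_inputs <- function(stage, files) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop(sprintf("stage '%s' requires missing input file(s): %s", stage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

write_manifest <- function(config, stage, inputs, outputs, seed) {
  manifest <- list(stage = stage, seed = seed,
                   inputs = as.list(tools::md5sum(inputs)),
                   outputs = as.list(tools::md5sum(outputs)),
                   config = unclass(config[[stage]] %||% list()))
  jsonlite::write_json(manifest,
                       stage_path(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

# Resolve the modern/fossil tables for a stage: explicit input paths win,
# otherwise the simulate stage's outputs in outdir are used.
resolve_data <- function(config, stage, need_fossil = TRUE) {
  taxa_p <- config$inputs$modern_taxa %||% stage_path(config, "modern_taxa.csv")
  env_p <- config$inputs$modern_env %||% stage_path(config, "modern_env.csv")
  foss_p <- config$inputs$fossil_taxa %||% stage_path(config, "fossil_taxa.csv")
  require_inputs(stage, c(taxa_p, env_p, if (need_fossil) foss_p))
  list(taxa = read_taxon_csv(taxa_p, kind = "percent"),
       env = read_env_csv(env_p),
       fossil = if (need_fossil) read_taxon_csv(foss_p, kind = "percent"),
       paths = c(taxa_p, env_p, if (need_fossil) foss_p))
}

#' Run a single pipeline stage
#'
#' Stages: \code{simulate} (synthetic calibration set, temperature
#' history and fossil sequence), \code{ordinate} (DCA gradient length,
#' PCoA, CCA after VIF filtering, per-variable permutation tests),
#' \code{calibrate} (bootstrap model-comparison table), \code{reconstruct}
#' (per-season + MAT reconstructions, both the direct MAT and the
#' four-season mean), \code{assess} (analogue classes and significance
#' tests), \code{attribute} (100-yr interpolation, sliding seasonal
#' contributions, histograms, smoothed trends). Every stage writes CSV
#' outputs plus a JSON manifest (input/output checksums, stage config,
#' seed) into \code{config$outdir}.
#'
#' @param stage stage name.
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a character vector of output paths.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, pipeline_stages)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- derive_seed(config$seed, stage)
  out <- switch(stage,
    simulate = stage_simulate(config, seed),
    ordinate = stage_ordinate(config, seed),
    calibrate = stage_calibrate(config, seed),
    reconstruct = stage_reconstruct(config, seed),
    assess = stage_assess(config, seed),
    attribute = stage_attribute(config, seed)
  )
  write_manifest(config, stage, out$inputs, out$outputs, seed)
  invisible(out$outputs)
}

#' Run the full pipeline
#'
#' Executes the stages in order. The simulate stage is skipped when all
#' three input paths are supplied in \code{config$inputs}. A stage
#' failure halts the run; manifests of completed stages remain.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a named list of output paths per stage.
#' @export
run_pipeline <- function(config) {
  stages <- pipeline_stages
  have_inputs <- !vapply(config$inputs, is.null, logical(1))
  if (all(have_inputs)) stages <- setdiff(stages, "simulate")
  res <- list()
  for (st in stages) {
    message("stage: ", st)
    res[[st]] <- run_stage(st, config)
  }
  invisible(res)
}

stage_simulate <- function(config, seed) {
  sc <- config$simulate
  cfg <- sim_config(n_sites = sc$n_sites, n_species = sc$n_species,
                    count_depth = sc$count_depth, correlation = sc$correlation,
                    resolution = sc$resolution, seed = seed)
  train <- simulate_training_set(cfg)
  history <- simulate_temperature_history(history_params(), seed = seed)
  fossil <- simulate_fossil_sequence(history, train$responses,
                                     resolution = cfg$resolution,
                                     count_depth = cfg$count_depth, seed = seed)
  p <- function(f) stage_path(config, f)
  write_taxon_csv(train$taxa, p("modern_taxa.csv"))
  write_env_csv(train$env, p("modern_env.csv"))
  write_taxon_csv(fossil$taxa, p("fossil_taxa.csv"))
  utils::write.csv(fossil$truth, p("truth.csv"), row.names = FALSE)
  list(inputs = character(0),
       outputs = p(c("modern_taxa.csv", "modern_env.csv", "fossil_taxa.csv",
                     "truth.csv")))
}

stage_ordinate <- function(config, seed) {
  oc <- config$ordination
  dat <- resolve_data(config, "ordinate", need_fossil = FALSE)
  sq <- sqrt_transform(dat$taxa)
  dca_len <- dca_gradient_length(dat$taxa$values)
  pc <- pcoa(dissimilarity_matrix(dat$taxa, oc$metric), n_axes = 2)
  keep <- vif_filter(dat$env, threshold = oc$vif_threshold)
  cc <- cca_fit(sq, dat$env, keep)
  tests <- do.call(rbind, lapply(keep, function(v) {
    pt <- permutation_test(sq, dat$env$values[, v], n_perm = oc$n_perm,
                           seed = derive_seed(seed, paste0("perm:", v)),
                           variable = v)
    data.frame(variable = v, statistic = pt$statistic, n_perm = pt$n_perm,
               p_value = pt$p_value)
  }))
  p <- function(f) stage_path(config, f)
  utils::write.csv(data.frame(dca_gradient_length_sd = dca_len,
                              cca_explained_fraction = cc$explained,
                              n_variables = length(keep),
                              pcoa_eig1 = pc$eigenvalues[1],
                              pcoa_eig2 = pc$eigenvalues[2]),
                   p("ordination_summary.csv"), row.names = FALSE)
  utils::write.csv(tests, p("permutation_tests.csv"), row.names = FALSE)
  utils::write.csv(data.frame(site = rownames(cc$site_scores), cc$site_scores),
                   p("cca_site_scores.csv"), row.names = FALSE)
  list(inputs = dat$paths,
       outputs = p(c("ordination_summary.csv", "permutation_tests.csv",
                     "cca_site_scores.csv")))
}

stage_calibrate <- function(config, seed) {
  cc <- config$calibration
  dat <- resolve_data(config, "calibrate", need_fossil = FALSE)
  rows <- list()
  for (tg in cc$compare_targets) {
    specs <- lapply(cc$methods, function(m) {
      method_spec(m, n_components = cc$n_components, metric = cc$metric)
    })
    tab <- compare_models(specs, dat$taxa, dat$env$values[, tg],
                          n_boot = cc$n_boot,
                          seed = derive_seed(seed, paste0("cmp:", tg)))
    tab$target <- tg
    rows[[tg]] <- tab
  }
  out <- do.call(rbind, rows)
  p <- stage_path(config, "model_comparison.csv")
  utils::write.csv(out, p, row.names = FALSE)
  list(inputs = dat$paths, outputs = p)
}

stage_reconstruct <- function(config, seed) {
  rc <- config$reconstruction
  dat <- resolve_data(config, "reconstruct")
  spec <- method_spec(rc$method, n_components = rc$n_components)
  recon <- reconstruct(spec, dat$taxa, dat$env, dat$fossil, rc$targets,
                       with_errors = isTRUE(rc$with_errors),
                       n_boot = rc$n_boot, seed = seed)
  if (all(SEASONS %in% rc$targets)) {
    recon$MAT_from_seasons <- mat_from_seasons(recon)
  }
  p <- stage_path(config, "reconstruction.csv")
  write_reconstruction_csv(recon, p)
  list(inputs = dat$paths, outputs = c(p, paste0(p, ".model.json")))
}

stage_assess <- function(config, seed) {
  ac <- config$assessment
  dat <- resolve_data(config, "assess")
  cls <- classify_analogues(dat$fossil, dat$taxa, metric = ac$metric)
  spec <- method_spec(ac$method)
  sig <- do.call(rbind, lapply(config$reconstruction$targets, function(tg) {
    st <- significance_test(dat$taxa, dat$env, tg, dat$fossil, spec = spec,
                            n_random = ac$n_random,
                            seed = derive_seed(seed, paste0("sig:", tg)))
    data.frame(target = tg, observed_fraction = st$observed,
               p_value = st$p_value,
               proportion_exceeded = st$proportion_exceeded,
               n_random = st$n_random, seed = st$seed)
  }))
  p <- function(f) stage_path(config, f)
  utils::write.csv(as.data.frame(cls), p("analogue_classes.csv"), row.names = FALSE)
  utils::write.csv(sig, p("significance_tests.csv"), row.names = FALSE)
  list(inputs = dat$paths,
       outputs = p(c("analogue_classes.csv", "significance_tests.csv")))
}

stage_attribute <- function(config, seed) {
  at <- config$attribution
  rp <- stage_path(config, "reconstruction.csv")
  require_inputs("attribute", rp)
  rec <- utils::read.csv(rp)
  if (!all(SEASONS %in% names(rec))) {
    stop("stage 'attribute' needs the four season columns in ", rp)
  }
  s <- seasonal_series(rec$age_calBP, rec$T_spring, rec$T_summer,
                       rec$T_autumn, rec$T_winter,
                       MAT = mat_from_seasons(rec))
  grid <- interpolate_uniform(s, dt = at$dt)
  contrib <- sliding_contributions(grid, step = at$step, window = at$window)
  hist_tab <- contribution_histogram(contrib, bin_width = at$bin_width)
  trends <- contrib[, c("center", paste0(SEASONS, "_pct"), "defined")]
  ok <- trends$defined
  for (season in SEASONS) {
    cn <- paste0(season, "_pct")
    sm <- rep(NA_real_, nrow(trends))
    sm[ok] <- lowess_smooth(trends$center[ok], trends[[cn]][ok],
                            span = at$lowess_span)
    trends[[paste0(season, "_trend")]] <- sm
  }
  p <- function(f) stage_path(config, f)
  utils::write.csv(as.data.frame(grid), p("gridded_series.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(contrib), p("contributions.csv"), row.names = FALSE)
  utils::write.csv(hist_tab, p("contribution_histogram.csv"), row.names = FALSE)
  utils::write.csv(trends, p("contribution_trends.csv"), row.names = FALSE)
  list(inputs = rp,
       outputs = p(c("gridded_series.csv", "contributions.csv",
                     "contribution_histogram.csv", "contribution_trends.csv")))
}
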
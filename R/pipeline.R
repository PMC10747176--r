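#' Assemble a full monitoring-run configuration
#'
#' Bundles every stage's parameters into one structured config, the unit the
#' end-to-end pipeline consumes and the YAML config files serialise.
#'
#' @param scenario `"lab"` or `"pilot"` (ignored when `sim` is given).
#' @param sim Optional explicit [simulation_config()] replacing the scenario
#'   default.
#' @param seed Integer seed overriding the simulation config's.
#' @param preprocess A [preprocess_params()].
#' @param reference_day QC similarity reference day.
#' @param pool_sessions Pool sessions within a calendar day for QC.
#' @param quantities Band/ratio labels for kinetic series.
#' @param pca_components Number of PCA components.
#' @param kw_alpha Family-wise level for the post-hoc comparisons.
#' @param kw_pairs `"adjacent"` or `"all"`.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario = "pilot", sim = NULL, seed = 1L,
                       preprocess = preprocess_params(),
                       reference_day = 0, pool_sessions = TRUE,
                       quantities = c("1524", "1157", "1660", "1750",
                                      "unsaturation_index", "carotenoid_ratio"),
                       pca_components = 3, kw_alpha = 0.05,
                       kw_pairs = "adjacent", out_dir = "results") {
  if (is.null(sim)) sim <- default_config(scenario, seed = seed)
  else { sim$seed <- as.integer(seed); validate_config(sim) }
  structure(list(sim = sim, seed = as.integer(seed), preprocess = preprocess,
                 reference_day = reference_day, pool_sessions = pool_sessions,
                 quantities = quantities, pca_components = pca_components,
                 kw_alpha = kw_alpha, kw_pairs = kw_pairs, out_dir = out_dir),
            class = "run_config")
}

# Deterministic 32-bit FNV-1a hash of a string, hex-encoded. Kept in
# doubles (split multiply) since the state exceeds R's integer range.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- ((((h %/% 65536) * m) %% 65536) * 65536 + (h %% 65536) * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Hash of the scientific configuration only: the output destination does not
# affect the numbers, so it is excluded and reruns into different directories
# stay byte-identical.
config_hash <- function(config) {
  cfg <- unclass_deep(config)
  cfg$out_dir <- NULL
  fnv1a(paste(utils::capture.output(utils::str(cfg)), collapse = "\n"))
}

write_result_table <- function(df, path, prov) {
  writeLines(paste0("# ", prov), path)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Run the full monitoring pipeline
#'
#' Executes simulate (or read) -> preprocess -> QC -> band kinetics -> PCA ->
#' Kruskal-Wallis with post-hoc comparisons, writes every result family as a
#' tab-separated table under `config$out_dir` (each with a provenance header
#' line carrying the config hash and seed), plus a YAML run manifest.
#' Identical config and seed give identical numeric outputs.
#'
#' @param config A [run_config()].
#' @param set Optional `spectra_set` to analyse instead of simulating.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, set = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- sprintf("provenance: config_hash=%s seed=%d ramalgae=%s",
                  config_hash(config), config$seed,
                  as.character(utils::packageVersion("ramalgae")))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  if (is.null(set)) set <- simulate_spectra(config$sim)
  tick("simulate")

  prep <- preprocess(set, config$preprocess)
  tick("preprocess")

  rep_tab <- repeatability(prep, config$pool_sessions)
  sim_tab <- similarity_to_reference(prep, config$reference_day)
  cmap <- correlation_map(prep)
  qc_summary <- data.frame(statistic = c("overall_mean", "overall_sd"),
                           value = unname(cmap$overall))
  write_result_table(rep_tab, file.path(config$out_dir, "qc_repeatability.tsv"), prov)
  write_result_table(sim_tab, file.path(config$out_dir, "qc_similarity.tsv"), prov)
  write_result_table(qc_summary, file.path(config$out_dir, "qc_correlation_summary.tsv"), prov)
  tick("qc")

  kin <- lapply(config$quantities, function(q) kinetic_series(prep, q))
  names(kin) <- config$quantities
  for (q in config$quantities)
    write_result_table(kin[[q]],
                       file.path(config$out_dir, sprintf("kinetics_%s.tsv", q)), prov)
  tick("bands")

  pc <- pca(prep, config$pca_components)
  scores_tab <- data.frame(prep$meta, pc$scores, check.names = FALSE)
  var_tab <- data.frame(component = paste0("PC", seq_along(pc$explained_fraction)),
                        explained_fraction = pc$explained_fraction)
  load_tab <- data.frame(wavenumber = prep$axis, t(pc$loadings), check.names = FALSE)
  write_result_table(scores_tab, file.path(config$out_dir, "pca_scores.tsv"), prov)
  write_result_table(var_tab, file.path(config$out_dir, "pca_variance.tsv"), prov)
  write_result_table(load_tab, file.path(config$out_dir, "pca_loadings.tsv"), prov)
  tick("pca")

  kw <- kruskal_wallis(pc$scores[, 1], prep$meta$day)
  ph <- pairwise_rank_comparison(kw, config$kw_alpha, config$kw_pairs)
  kw_tab <- data.frame(kw$group_stats, H = kw$H, df = kw$df, p_value = kw$p_value)
  write_result_table(kw_tab, file.path(config$out_dir, "kw_groups.tsv"), prov)
  write_result_table(ph, file.path(config$out_dir, "kw_pairwise.tsv"), prov)
  tick("kw")

  manifest <- list(config = unclass_deep(config), config_hash = config_hash(config),
                   seed = config$seed, n_spectra = n_spectra(set),
                   points_retained = length(prep$axis),
                   stage_timings_s = as.list(timings),
                   ramalgae_version = as.character(utils::packageVersion("ramalgae")))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))

  invisible(list(set = set, preprocessed = prep, repeatability = rep_tab,
                 similarity = sim_tab, correlation = cmap, kinetics = kin,
                 pca = pc, kw = kw, pairwise = ph, manifest = manifest))
}
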
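#' Run the full connectome analysis pipeline
#'
#' Composes the whole analysis end to end: (optionally) simulate a
#' cohort, compute graph metrics and tract scores, build the demographics
#' comparison, run the univariate screen and per-metric multivariate
#' models for each outcome domain, and perform the edge-wise permutation
#' comparison. All tables are written as CSV under `out_dir` together
#' with a JSON run manifest (configuration snapshot, seeds, per-stage
#' timings, output file list with MD5 hashes). Identical config + seed
#' yields identical outputs.
#'
#' @param config A `simulation_config`, a YAML file path with fields
#'   overriding [default_scenario()], or NULL for the defaults.
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Output directory.
#' @param n_perm Permutations for the edge-wise stage (default 5000).
#' @param n_null Null networks for small-worldness (default 100).
#' @param write_connectomes Also write per-subject connectome CSVs.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, seed = 20110101, out_dir = "results",
                         n_perm = 5000, n_null = 100,
                         write_connectomes = FALSE) {
  config <- resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- load_atlas()
  manifest <- list(config = config[setdiff(names(config), "planted_edges")],
                   seed = as.integer(seed), n_perm = n_perm, n_null = n_null,
                   tool_version = as.character(utils::packageVersion("neonconn")),
                   timings = list(), outputs = character(0))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "; completed outputs: ", paste(manifest$outputs, collapse = ", "),
           call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, file)
    path
  }

  sim <- stage("simulate", simulate_cohort(config, seed = seed, atlas = atlas))
  emit(sim$subjects, "subjects.csv")
  emit(sim$outcomes, "outcomes.csv")
  if (write_connectomes) {
    stage("write_connectomes", write_cohort_csv(sim, file.path(out_dir, "cohort")))
  }

  metrics <- stage("metrics", metric_table(sim$connectomes, n_null = n_null,
                                           seed = seed))
  emit(metrics, "graph_metrics.csv")

  tracts <- stage("tracts", tract_score_table(sim$connectomes, atlas = atlas))
  emit(tracts, "tract_scores.csv")

  subj <- sim$subjects
  subj$male <- subj$sex == "male"
  demo <- stage("demographics", demographics_table(subj))
  emit(demo, "demographics.csv")

  ## outcome analysis at each timepoint
  analysis_data <- merge(merge(sim$subjects, metrics, by = "subject_id"),
                         tracts, by = "subject_id")
  screen_rows <- list()
  multi_rows <- list()
  for (tp in c("12-18 months", "30 months")) {
    oc <- sim$outcomes[sim$outcomes$timepoint == tp, ]
    d <- merge(analysis_data, oc, by = "subject_id")
    tag <- if (tp == "12-18 months") "12_18" else "30"
    preds <- c("cohort", "sex", "injury_on_mri", "maternal_education", "race",
               "snappe", "ga_mri", "ga_birth", "birth_weight",
               "log_global_efficiency", "log_transitivity", "log_modularity",
               "log_small_worldness")
    for (dom in c("cognitive", "language", "motor")) {
      sc <- stage(paste0("screen_", dom, "_", tag),
                  univariate_screen(d, dom, preds))
      sc$outcome <- paste0(dom, "_", tag)
      screen_rows[[paste(dom, tag)]] <- sc
      metric_sel <- intersect(attr(sc, "selected"),
                              grep("^log_", preds, value = TRUE))
      clin_sel <- setdiff(attr(sc, "selected"),
                          c(metric_sel, "ga_mri", "ga_birth"))
      for (m in metric_sel) {
        mm <- stage(paste0("model_", dom, "_", tag, "_", m),
                    suppressMessages(multivariate_metric_model(
                      d, dom, m, covariates = clin_sel)))
        mm$outcome <- paste0(dom, "_", tag)
        mm$metric <- m
        mm$model_p <- attr(mm, "model_p")
        mm$n_used <- attr(mm, "n_used")
        multi_rows[[paste(dom, tag, m)]] <- mm
      }
    }
  }
  screen_tab <- do.call(rbind, screen_rows)
  rownames(screen_tab) <- NULL
  emit(screen_tab, "univariate_screen.csv")
  if (length(multi_rows) > 0) {
    multi_tab <- do.call(rbind, multi_rows)
    rownames(multi_tab) <- NULL
    emit(multi_tab, "multivariate_models.csv")
  } else {
    emit(data.frame(), "multivariate_models.csv")
  }

  ## tract-outcome grid over the four language outcomes
  oc12 <- sim$outcomes[sim$outcomes$timepoint == "12-18 months",
                       c("subject_id", "language")]
  names(oc12)[2] <- "language_12_18"
  oc30 <- sim$outcomes[sim$outcomes$timepoint == "30 months",
                       c("subject_id", "language", "expressive", "receptive")]
  names(oc30)[2:4] <- c("language_30", "expressive_30", "receptive_30")
  td <- merge(merge(tracts, oc12, by = "subject_id", all.x = TRUE),
              oc30, by = "subject_id", all.x = TRUE)
  tract_tab <- stage("tract_regressions", tract_regressions(td))
  emit(tract_tab, "tract_regressions.csv")

  ## edge-wise permutation comparison, GA at MRI adjusted
  ew <- stage("edgewise", edgewise_compare(
    sim$connectomes, sim$subjects$cohort,
    covariates = sim$subjects[, "ga_mri", drop = FALSE],
    config = edgewise_config(n_perm = n_perm, seed = seed),
    atlas = atlas))
  emit(as.data.frame(ew), "edgewise_edges.csv")
  emit(ew$roi_involvement, "edgewise_involvement.csv")

  manifest$outputs <- unique(manifest$outputs)
  manifest$output_md5 <- as.list(tools::md5sum(file.path(out_dir, manifest$outputs)))
  names(manifest$output_md5) <- manifest$outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

# accept NULL, a simulation_config, or a YAML path overriding defaults
resolve_config <- function(config) {
  if (is.null(config)) return(default_scenario())
  if (inherits(config, "simulation_config")) return(config)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    overrides <- yaml::read_yaml(config)
    base <- default_scenario()
    unknown <- setdiff(names(overrides), names(base))
    if (length(unknown) > 0) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    out <- utils::modifyList(base, overrides)
    class(out) <- "simulation_config"
    return(out)
  }
  if (is.list(config)) {
    base <- default_scenario()
    out <- utils::modifyList(base, config)
    class(out) <- "simulation_config"
    return(out)
  }
  stop("config must be NULL, a simulation_config, a list, or a YAML path",
       call. = FALSE)
}
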
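#' Synthetic neonatal brain-injury cohorts
#'
#' Generates subjects, FA-weighted connectomes and Bayley-III outcomes
#' with the statistical structure the analysis pipeline assumes: two
#' cohorts (HIE and CHD), a shared edge-sparsity template, gestational-age
#' maturation of FA, a planted set of hypoconnected left occipito-temporal
#' edges in the CHD group, outcomes driven by log global efficiency,
#' cohort and sex, and follow-up missingness. Ground truth is emitted for
#' recovery testing. The per-edge Gaussian-with-truncation FA model is a
#' synthetic stand-in: no per-edge FA distributions are available from
#' real data here.
#'
#' @name synthetic_cohort
NULL

#' The planted hypoconnected edge set
#'
#' Eighteen distinct left-hemisphere occipito-temporal region pairs
#' spanning 22 distinct regions (fusiform, lingual, calcarine and
#' occipital cortex, temporal gyri and poles, and adjacent parietal and
#' limbic regions), including the calcarine-to-middle-occipital pathway.
#' These edges receive the configured FA deficit in the CHD cohort.
#'
#' @return A 2-column character matrix of region-name pairs.
#' @export
planted_edge_set <- function() {
  L <- function(x) paste0(x, ", left")
  pairs <- rbind(
    c("fusiform gyrus",            "superior temporal pole"),
    c("fusiform gyrus",            "middle temporal pole"),
    c("fusiform gyrus",            "inferior temporal gyrus"),
    c("fusiform gyrus",            "lingual gyrus"),
    c("calcarine cortex",          "middle occipital gyrus"),
    c("calcarine cortex",          "lingual gyrus"),
    c("middle occipital gyrus",    "middle temporal gyrus"),
    c("inferior occipital gyrus",  "inferior temporal gyrus"),
    c("superior occipital gyrus",  "cuneus"),
    c("cuneus",                    "precuneus"),
    c("superior temporal gyrus",   "heschl gyrus"),
    c("superior temporal gyrus",   "supramarginal gyrus"),
    c("middle temporal gyrus",     "angular gyrus"),
    c("hippocampus",               "parahippocampal gyrus"),
    c("precuneus",                 "posterior cingulate gyrus"),
    c("superior parietal gyrus",   "precuneus"),
    c("inferior parietal lobule",  "angular gyrus"),
    c("thalamus",                  "superior temporal gyrus"))
  matrix(L(pairs), ncol = 2, dimnames = list(NULL, c("roi_i", "roi_j")))
}

#' Default simulation scenario
#'
#' Cohort sizes, sex fractions, gestational-age distributions, follow-up
#' counts and outcome coefficients are calibrated to the published cohort
#' tables; remaining parameters (edge-level FA spread, per-subject FA
#' offset, MRI lag, outcome noise) are realistic choices documented in
#' the methods vignette.
#'
#' @return A list of class `simulation_config`.
#' @export
default_scenario <- function() {
  structure(list(
    n_hie = 60L, n_chd = 35L,
    male_frac_hie = 0.517, male_frac_chd = 0.80,
    ga_birth_mean = c(hie = 39.9, chd = 39.1), ga_birth_sd = 1.0,
    mri_lag_mean_days = c(hie = 5, chd = 3.5), mri_lag_sd_days = 1.5,
    baseline_density = 0.35,
    baseline_fa_mean = 0.25, edge_mean_sd = 0.05,
    fa_sd = 0.03, subject_fa_sd = 0.012,
    maturation_slope = 0.005,
    planted_edges = planted_edge_set(),
    planted_deficit = 0.08,
    outcome_model = list(
      # motor at 30 months carries the log-global-efficiency effect; all
      # intercepts are set so HIE domain means sit near the published
      # HIE medians given a typical log global efficiency of about -1.69
      coef_log_ge_motor_30 = 43.7,
      coef_cohort = c(cognitive_12_18 = -1.7, language_12_18 = -16.1,
                      motor_12_18 = -6.6, cognitive_30 = -21.5,
                      language_30 = -17.9, motor_30 = -14.6),
      coef_sex = c(cognitive_12_18 = 5.0, language_12_18 = 9.1,
                   motor_12_18 = 8.4, cognitive_30 = 12.3,
                   language_30 = 8.9, motor_30 = 8.2),
      target_hie_mean = c(cognitive_12_18 = 103, language_12_18 = 104.5,
                          motor_12_18 = 102, cognitive_30 = 100,
                          language_30 = 98.5, motor_30 = 98.5),
      ref_log_ge = -1.69,
      noise_sd = 12,
      coef_slf2_expressive = -5.2,
      coef_cohort_expressive = -3,
      subscore_noise_sd = 3),
    followup_frac_12_18 = c(hie = 42 / 60, chd = 14 / 35),
    followup_frac_30 = c(hie = 31 / 60, chd = 8 / 35),
    seed = 20110101L
  ), class = "simulation_config")
}

trunc01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Simulate a two-cohort study
#'
#' Fully deterministic given `seed`. Subjects are drawn per cohort with
#' the configured sex fractions and gestational-age distributions; every
#' connectome shares one random sparsity template (edges exist or not
#' population-wide, so edge inclusion masks are well defined), with edge
#' weights = population edge mean + maturation slope x (GA at MRI - 40)
#' + per-subject offset + edge noise, truncated to \[0, 1\]. CHD subjects
#' have the planted deficit subtracted on the planted edges. Outcomes are
#' linear in the log global efficiency computed from each generated
#' connectome, cohort and sex, with Gaussian noise, truncated to
#' \[40, 160\]; expressive language additionally carries the planted SLF2
#' effect. Follow-up missingness is applied per cohort and timepoint.
#'
#' @param config A `simulation_config` (default [default_scenario()]).
#' @param seed Integer RNG seed (defaults to `config$seed`).
#' @param atlas The parcellation (default [load_atlas()]).
#' @return List with `subjects`, `connectomes`, `outcomes`, `truth`
#'   (class `cohort_simulation`).
#' @export
simulate_cohort <- function(config = default_scenario(), seed = config$seed,
                            atlas = load_atlas()) {
  if (config$planted_deficit >= config$baseline_fa_mean) {
    stop("infeasible config: planted deficit >= baseline FA mean", call. = FALSE)
  }
  n <- nrow(atlas)
  nms <- atlas$name
  n_tot <- config$n_hie + config$n_chd
  withr::with_seed(as.integer(seed), {
    ## ---- subjects ----
    cohort <- factor(rep(c("HIE", "CHD"), c(config$n_hie, config$n_chd)),
                     levels = c("HIE", "CHD"))
    id <- sprintf("S%03d", seq_len(n_tot))
    male <- c(stats::rbinom(config$n_hie, 1, config$male_frac_hie),
              stats::rbinom(config$n_chd, 1, config$male_frac_chd)) == 1
    ga_birth <- stats::rnorm(n_tot,
                             mean = ifelse(cohort == "HIE",
                                           config$ga_birth_mean[["hie"]],
                                           config$ga_birth_mean[["chd"]]),
                             sd = config$ga_birth_sd)
    ga_birth <- pmax(ga_birth, 36)  # term cohorts: prematurity excluded
    lag <- stats::rnorm(n_tot,
                        mean = ifelse(cohort == "HIE",
                                      config$mri_lag_mean_days[["hie"]],
                                      config$mri_lag_mean_days[["chd"]]),
                        sd = config$mri_lag_sd_days)
    ga_mri <- ga_birth + pmax(lag, 1) / 7
    subjects <- data.frame(
      subject_id = id,
      cohort = cohort,
      chd_subtype = factor(ifelse(cohort == "CHD",
                                  sample(c("SV", "TGA"), n_tot, TRUE,
                                         prob = c(20, 15) / 35),
                                  "none"),
                           levels = c("none", "SV", "TGA")),
      sex = factor(ifelse(male, "male", "female"),
                   levels = c("male", "female")),
      ga_birth = ga_birth,
      ga_mri = ga_mri,
      birth_weight = stats::rnorm(n_tot, 3.3, 0.35),
      injury_on_mri = stats::rbinom(n_tot, 1,
                                    ifelse(cohort == "HIE", 1 / 3, 13 / 35)) == 1,
      maternal_education = factor(
        sample(c("graduate school", "college graduate", "partial college",
                 "high school graduate", "partial high school"),
               n_tot, TRUE, prob = c(0.25, 0.3, 0.2, 0.17, 0.08)),
        levels = c("graduate school", "college graduate", "partial college",
                   "high school graduate", "partial high school")),
      race = factor(sample(c("white", "asian", "black", "latin-x", "other"),
                           n_tot, TRUE, prob = c(0.45, 0.15, 0.1, 0.2, 0.1)),
                    levels = c("white", "asian", "black", "latin-x", "other")),
      ph = round(ifelse(cohort == "HIE", stats::rnorm(n_tot, 6.98, 0.1),
                        stats::rnorm(n_tot, 7.28, 0.06)), 2),
      base_deficit = round(ifelse(cohort == "HIE", stats::rnorm(n_tot, -16, 4),
                                  stats::rnorm(n_tot, -3, 1.5)), 0),
      apgar1 = pmin(pmax(round(ifelse(cohort == "HIE",
                                      stats::rnorm(n_tot, 2, 1.2),
                                      stats::rnorm(n_tot, 8, 0.8))), 0), 10),
      apgar5 = pmin(pmax(round(ifelse(cohort == "HIE",
                                      stats::rnorm(n_tot, 4.3, 1.6),
                                      stats::rnorm(n_tot, 9, 0.5))), 0), 10),
      snappe = pmax(round(ifelse(cohort == "HIE", stats::rnorm(n_tot, 30, 6),
                                 stats::rnorm(n_tot, 14, 6))), 0),
      stringsAsFactors = FALSE)

    ## ---- shared sparsity template ----
    ut <- which(upper.tri(matrix(0, n, n)))
    pe <- config$planted_edges
    pi_ <- atlas_lookup(atlas, pe[, 1])
    pj <- atlas_lookup(atlas, pe[, 2])
    planted_lin <- (pmax(pi_, pj) - 1L) * n + pmin(pi_, pj)  # column-major upper cell
    tracts <- builtin_tracts(atlas = atlas)
    tract_lin <- unlist(lapply(tracts, function(t) {
      i <- atlas_lookup(atlas, t$pairs[, 1])
      j <- atlas_lookup(atlas, t$pairs[, 2])
      (pmax(i, j) - 1L) * n + pmin(i, j)
    }))
    m_target <- round(config$baseline_density * length(ut))
    # major language pathways and the planted set exist population-wide
    template <- union(sample(ut, m_target), c(planted_lin, tract_lin))
    edge_mean <- trunc01(stats::rnorm(length(template), config$baseline_fa_mean,
                                      config$edge_mean_sd), 0.05, 0.7)
    planted_mask <- template %in% planted_lin

    ## ---- connectomes ----
    connectomes <- vector("list", n_tot)
    log_ge <- numeric(n_tot)
    for (s in seq_len(n_tot)) {
      subj_off <- stats::rnorm(1, 0, config$subject_fa_sd)
      wvals <- edge_mean +
        config$maturation_slope * (ga_mri[s] - 40) +
        subj_off +
        stats::rnorm(length(template), 0, config$fa_sd)
      if (cohort[s] == "CHD") {
        wvals[planted_mask] <- wvals[planted_mask] - config$planted_deficit
      }
      w <- matrix(0, n, n, dimnames = list(nms, nms))
      w[template] <- trunc01(wvals)
      w <- w + t(w)
      connectomes[[s]] <- new_connectome(id[s], w, atlas = atlas)
      log_ge[s] <- log(global_efficiency(w))
    }

    ## ---- outcomes ----
    om <- config$outcome_model
    female <- subjects$sex == "female"
    chd <- cohort == "CHD"
    slf2 <- vapply(connectomes, function(cn) {
      as.numeric(tract_connectivity(cn, tracts$SLF2, atlas = atlas))
    }, numeric(1))
    domain_score <- function(dom, logge_coef = 0) {
      intercept <- om$target_hie_mean[[dom]] -
        logge_coef * om$ref_log_ge - om$coef_sex[[dom]] * 0.48
      trunc01(intercept + logge_coef * log_ge +
                om$coef_cohort[[dom]] * chd + om$coef_sex[[dom]] * female +
                stats::rnorm(n_tot, 0, om$noise_sd), 40, 160)
    }
    scores <- list(
      cognitive_12_18 = domain_score("cognitive_12_18"),
      language_12_18 = domain_score("language_12_18"),
      motor_12_18 = domain_score("motor_12_18"),
      cognitive_30 = domain_score("cognitive_30"),
      language_30 = domain_score("language_30"),
      motor_30 = domain_score("motor_30", logge_coef = om$coef_log_ge_motor_30))
    expressive <- trunc01(10 - om$coef_slf2_expressive * 0.25 +
                            om$coef_slf2_expressive * slf2 +
                            om$coef_cohort_expressive * chd +
                            stats::rnorm(n_tot, 0, om$subscore_noise_sd), 0, 20)
    receptive <- trunc01(10 + stats::rnorm(n_tot, 0, om$subscore_noise_sd), 0, 20)

    seen_12 <- seen_30 <- logical(n_tot)
    for (co in c("hie", "chd")) {
      idx <- which(tolower(as.character(cohort)) == co)
      seen_12[sample(idx, round(config$followup_frac_12_18[[co]] * length(idx)))] <- TRUE
      seen_30[sample(idx, round(config$followup_frac_30[[co]] * length(idx)))] <- TRUE
    }
    n12 <- sum(seen_12)
    n30 <- sum(seen_30)
    outcomes <- rbind(
      data.frame(subject_id = id[seen_12],
                 timepoint = rep("12-18 months", n12),
                 cognitive = scores$cognitive_12_18[seen_12],
                 language = scores$language_12_18[seen_12],
                 motor = scores$motor_12_18[seen_12],
                 expressive = rep(NA_real_, n12),
                 receptive = rep(NA_real_, n12),
                 stringsAsFactors = FALSE),
      data.frame(subject_id = id[seen_30],
                 timepoint = rep("30 months", n30),
                 cognitive = scores$cognitive_30[seen_30],
                 language = scores$language_30[seen_30],
                 motor = scores$motor_30[seen_30],
                 expressive = expressive[seen_30],
                 receptive = receptive[seen_30],
                 stringsAsFactors = FALSE))
    rownames(outcomes) <- NULL

    truth <- list(
      planted_edges = edge_key(pi_, pj, nms),
      coef_log_ge_motor_30 = om$coef_log_ge_motor_30,
      coef_slf2_expressive = om$coef_slf2_expressive,
      planted_deficit = config$planted_deficit,
      log_global_efficiency = stats::setNames(log_ge, id),
      seed = as.integer(seed))
  })
  structure(list(subjects = subjects, connectomes = connectomes,
                 outcomes = outcomes, truth = truth, config = config),
            class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  cat("<cohort_simulation>", sum(x$subjects$cohort == "HIE"), "HIE +",
      sum(x$subjects$cohort == "CHD"), "CHD subjects; seed", x$truth$seed, "\n")
  invisible(x)
}

#' Write a simulated cohort to CSV/JSON files
#'
#' Emits the same formats the rest of the pipeline consumes: one dense
#' connectome CSV per subject, subject and outcome tables, and a
#' ground-truth JSON (planted edges, generative coefficients, seed).
#'
#' @param sim A `cohort_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(sim$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  cdir <- file.path(dir, "connectomes")
  dir.create(cdir, showWarnings = FALSE)
  for (cn in sim$connectomes) {
    write_connectome_csv(cn, file.path(cdir, paste0(cn$subject_id, ".csv")))
  }
  jsonlite::write_json(
    list(planted_edges = sim$truth$planted_edges,
         coef_log_ge_motor_30 = sim$truth$coef_log_ge_motor_30,
         coef_slf2_expressive = sim$truth$coef_slf2_expressive,
         planted_deficit = sim$truth$planted_deficit,
         seed = sim$truth$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
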
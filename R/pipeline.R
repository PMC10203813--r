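#' Configuration for an end-to-end synthetic cohort run
#'
#' Bundles the generative conditions and analysis constants for a full
#' pipeline run: cohort size, sheet size, per-task gains, field geometry and
#' noise, the localiser design, and the thresholds used downstream
#' (z > 2 map threshold, localiser FDR q = 0.01, 3-sigma typicality
#' exclusion).
#'
#' @param seed Root integer seed; all stage randomness derives from it.
#' @param n_participants Cohort size (>= 3).
#' @param n_nodes Nodes in the simulated hand-area sheet.
#' @param n_runs Imaging runs per task.
#' @param gain_active,gain_passive Task-level gains.
#' @param noise_sd Run-to-run beta noise SD.
#' @param localiser_noise_sd BOLD noise SD in the localiser runs.
#' @param widths Field width (SD, axis units) shared by the five digits.
#' @param center_jitter_sd,width_jitter_sd,amp_jitter_sd Between-participant
#'   variability of centers (additive), widths and amplitudes
#'   (log-normal multipliers).
#' @param enslavement_active,enslavement_passive 5x5 input-mixing matrices.
#' @param z_thresh,fdr_q,outlier_sigma Analysis thresholds.
#' @param model_starts Multi-starts for the cortical-model fits.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(seed = 1L, n_participants = 15L, n_nodes = 200L,
                            n_runs = 4L, gain_active = 1.5, gain_passive = 1,
                            noise_sd = 0.2, localiser_noise_sd = 0.5,
                            widths = 0.07, center_jitter_sd = 0.015,
                            width_jitter_sd = 0.1, amp_jitter_sd = 0.1,
                            enslavement_active = diag(5),
                            enslavement_passive = diag(5),
                            z_thresh = 2, fdr_q = 0.01, outlier_sigma = 3,
                            model_starts = 5L) {
  if (n_participants < 3) stop("cohort size must be >= 3", call. = FALSE)
  stopifnot(z_thresh > 0, fdr_q > 0, fdr_q < 1, outlier_sigma > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic per-participant / per-stage seed derived from the root seed
stage_seed <- function(root, participant, stage) {
  as.integer((as.numeric(root) * 7919 + participant * 101 + stage * 13) %%
               2147483647)
}

# participant-specific field spec: shared hand geometry across tasks,
# task-specific gain/enslavement
participant_spec <- function(config, participant, task = c("active", "passive"),
                             gain = NULL, enslavement = NULL,
                             noise_sd = NULL) {
  task <- match.arg(task)
  set.seed(stage_seed(config$seed, participant, 1L))
  centers <- c(0.1, 0.3, 0.5, 0.7, 0.9) +
    stats::rnorm(5, sd = config$center_jitter_sd)
  centers <- sort(pmin(pmax(centers, 0.02), 0.98))
  widths <- rep(config$widths, 5) * exp(stats::rnorm(5, sd = config$width_jitter_sd))
  amps <- exp(stats::rnorm(5, sd = config$amp_jitter_sd))
  if (is.null(gain)) {
    gain <- if (task == "active") config$gain_active else config$gain_passive
  }
  if (is.null(enslavement)) {
    enslavement <- if (task == "active") config$enslavement_active
    else config$enslavement_passive
  }
  digit_field_spec(centers = centers, widths = widths, amplitudes = amps,
                   gain = gain, enslavement = enslavement,
                   noise_sd = if (is.null(noise_sd)) config$noise_sd else noise_sd)
}

#' Simulate a full cohort
#'
#' Generates, per participant: a cortical sheet, forward and backward
#' travelling-wave localiser runs (unit gain, identity enslavement), and
#' active and passive run-level activity sets sharing the participant's hand
#' geometry but differing in task gain (and, if configured, enslavement).
#'
#' @param config A \code{pipeline_config}.
#' @return List of participant lists with elements \code{sheet},
#'   \code{localiser_fwd}, \code{localiser_bwd}, \code{active},
#'   \code{passive}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sheet <- make_sheet(config$n_nodes)
  lapply(seq_len(config$n_participants), function(p) {
    pid <- sprintf("p%02d", p)
    loc_spec <- participant_spec(config, p, "passive", gain = 1,
                                 enslavement = diag(5),
                                 noise_sd = config$localiser_noise_sd)
    list(
      participant_id = pid,
      sheet = sheet,
      localiser_fwd = simulate_localiser(sheet, loc_spec,
                                         direction = "forward",
                                         seed = stage_seed(config$seed, p, 2L)),
      localiser_bwd = simulate_localiser(sheet, loc_spec,
                                         direction = "backward",
                                         seed = stage_seed(config$seed, p, 3L)),
      active = simulate_activity(sheet, participant_spec(config, p, "active"),
                                 n_runs = config$n_runs,
                                 seed = stage_seed(config$seed, p, 4L),
                                 task_label = "active", participant_id = pid),
      passive = simulate_activity(sheet, participant_spec(config, p, "passive"),
                                  n_runs = config$n_runs,
                                  seed = stage_seed(config$seed, p, 5L),
                                  task_label = "passive", participant_id = pid)
    )
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes every stage in order — cohort synthesis, travelling-wave cluster
#' localisation, cross-task Dice overlap, somatotopic-index correlation,
#' within-cluster neighbourhood selectivity, crossnobis RSA, and the
#' cortical-model hypothesis comparison — and returns (optionally writes) a
#' single cohort report. Fully reproducible from the configuration's seed.
#'
#' @param config A \code{pipeline_config}.
#' @param out_dir Optional directory; if given, the report is written to
#'   \code{report.json} there.
#' @return A \code{pipeline_report} list with elements \code{overlap},
#'   \code{somatotopy}, \code{neighbourhood}, \code{rsa}, \code{model} and
#'   \code{config}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- simulate_cohort(config)
  bank <- build_reference_bank(tr = 2, cycles = 5)

  clusters <- lapply(cohort, function(pt) {
    assign_digits(pt$localiser_fwd, pt$localiser_bwd, bank, q = config$fdr_q)
  })

  dice <- lapply(cohort, function(pt) {
    dice_matrix(pt$active$zmaps, pt$passive$zmaps, z_thresh = config$z_thresh)
  })
  overlap <- overlap_summary(dice)

  soma <- lapply(cohort, function(pt) {
    c(active = somatotopy_score(pt$active, pt$sheet)$r_circ,
      passive = somatotopy_score(pt$passive, pt$sheet)$r_circ)
  })
  soma <- do.call(rbind, soma)
  soma_test <- compare_somatotopy(soma[, "active"], soma[, "passive"])

  tables <- mapply(function(pt, cl) {
    extract_cluster_activity(list(active = pt$active, passive = pt$passive), cl)
  }, cohort, clusters, SIMPLIFY = FALSE)
  sel <- lapply(tables, selectivity_ratios)
  neigh <- neighbourhood_inference(sel, tables)

  rdms <- lapply(cohort, function(pt) {
    lapply(list(active = pt$active, passive = pt$passive), function(act) {
      crossnobis(prewhiten(act$betas, act$residuals),
                 task = act$task_label, participant_id = act$participant_id)
    })
  })
  rsa <- rdm_statistics(lapply(rdms, `[[`, "active"),
                        lapply(rdms, `[[`, "passive"),
                        outlier_sigma = config$outlier_sigma)

  # model: group-mean profiles (cluster x digit), passive fit then hypotheses
  mean_profile <- function(task) {
    Reduce(`+`, lapply(tables, function(tb) tb$values[task, , ])) / length(tables)
  }
  passive_fit <- fit_to_profiles(mean_profile("passive"),
                                 free = c("gain", "W"),
                                 n_starts = config$model_starts,
                                 seed = stage_seed(config$seed, 0L, 6L))
  hyp <- compare_hypotheses(passive_fit$params, mean_profile("active"),
                            n_starts = config$model_starts,
                            seed = stage_seed(config$seed, 0L, 7L))

  report <- structure(
    list(schema_version = "1.0",
         overlap = list(means = as.list(overlap$means),
                        p_same_vs_neighbour = overlap$same_vs_neighbour$p.value,
                        p_neighbour_vs_nonneighbour =
                          overlap$neighbour_vs_nonneighbour$p.value),
         somatotopy = list(mean_r_active = mean(soma[, "active"]),
                           mean_r_passive = mean(soma[, "passive"]),
                           p_paired = soma_test$p.value),
         neighbourhood = list(
           anova = as.data.frame(neigh$anova),
           wilcoxon = neigh$wilcoxon,
           hits = lapply(sel, `[[`, "hits"),
           p_overall_activity = neigh$overall_activity$p.value,
           mean_overall_activity = colMeans(
             t(vapply(tables, function(tb) apply(tb$values, 1, mean, na.rm = TRUE),
                      numeric(2))))),
         rsa = list(
           info_mean_active = mean(rsa$info_content$task_a),
           info_mean_passive = mean(rsa$info_content$task_b),
           p_info = rsa$info_test$p.value,
           typicality_means = as.list(colMeans(rsa$typicality, na.rm = TRUE)),
           excluded = rsa$excluded),
         model = list(losses = as.list(hyp$losses),
                      rdm_ratio = as.list(hyp$rdm_ratio),
                      best = hyp$best,
                      passive_loss = passive_fit$loss),
         config = config_to_list(config)),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$enslavement_active <- unclass(out$enslavement_active)
  out$enslavement_passive <- unclass(out$enslavement_passive)
  out
}

unclass_report <- function(report) {
  rapply(unclass(report), unclass, how = "replace")
}
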
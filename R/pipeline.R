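#' Configuration for an end-to-end synthetic run
#'
#' Describes a complete case-versus-controls analysis on simulated data:
#' every control is an independent realization of `schedule_control`, the
#' patient is a realization of `schedule_patient` (typically the same
#' windows with `persistence > 0` and/or a window gain removed), and the
#' downstream stages (RDMs, TGMs and contrasts, model comparisons,
#' behavioral statistics) run with the parameters given here.
#'
#' @param catalog Stimulus catalog shared by all subjects.
#' @param schedule_control,schedule_patient Geometry schedules
#'   ([geometry_schedule()]).
#' @param n_controls Number of control subjects (>= 2).
#' @param n_trials_per_stimulus,n_channels,sampling_rate,epoch_window,repeat_probability
#'   Passed to [sim_config()] for every subject.
#' @param models Named list of `model_rdm` objects to correlate with the
#'   brain RDMs.
#' @param partials Named character vector mapping a model name to the name
#'   of the model to partial out (entries may be `NA` for plain Spearman);
#'   models absent from this vector are correlated without a partial.
#' @param subsets Pair subsets for which TGMs and contrasts are computed.
#' @param folds,repetitions Decoding cross-validation plan.
#' @param decode_time_range,contrast_time_range Decoded window and the
#'   (post-onset) window for TGMs/contrasts, in ms.
#' @param tgm_metric Correlation type for TGMs.
#' @param alpha Significance threshold for all contrasts (uncorrected).
#' @param patient_face_deficit Behavioral effect size for [sim_behavior()].
#' @param seed Master seed; every stage derives its randomness from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(catalog, schedule_control, schedule_patient,
                       n_controls = 5, n_trials_per_stimulus = 40,
                       n_channels = 16, sampling_rate = 64,
                       epoch_window = c(-200, 1100), repeat_probability = 0.1,
                       models = list(), partials = character(),
                       subsets = "all", folds = 5, repetitions = 5,
                       decode_time_range = c(-200, 800),
                       contrast_time_range = c(0, 800),
                       tgm_metric = "pearson", alpha = 0.05,
                       patient_face_deficit = -8, seed = 1L) {
  assert_catalog(catalog)
  if (n_controls < 2) stop("need at least 2 controls")
  if (length(models) && is.null(names(models))) stop("models must be a named list")
  structure(
    list(catalog = catalog, schedule_control = schedule_control,
         schedule_patient = schedule_patient, n_controls = as.integer(n_controls),
         n_trials_per_stimulus = n_trials_per_stimulus, n_channels = n_channels,
         sampling_rate = sampling_rate, epoch_window = epoch_window,
         repeat_probability = repeat_probability, models = models,
         partials = partials, subsets = subsets, folds = folds,
         repetitions = repetitions, decode_time_range = decode_time_range,
         contrast_time_range = contrast_time_range, tgm_metric = tgm_metric,
         alpha = alpha, patient_face_deficit = patient_face_deficit,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

subject_table <- function(config) {
  tibble::tibble(
    subject = c("patient", sprintf("control%02d", seq_len(config$n_controls))),
    is_patient = c(TRUE, rep(FALSE, config$n_controls)),
    sim_seed = config$seed + c(999L, 100L + seq_len(config$n_controls))
  )
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> decode (RDM series) -> temporal generalization
#' (+ subsets, group mean, case contrast) -> model comparisons (+ case
#' contrasts) -> behavioral statistics, and writes every stage's artifacts
#' under `out_dir` as CSV/JSON, together with a `manifest.json` holding the
#' package version, the configuration hash, the master seed and a content
#' hash per artifact. Reruns with the same configuration and seed produce
#' byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips
#'   writing and only returns the in-memory bundle.
#' @return (Invisibly) a `report_bundle` list: `subjects`, `rdms`, `tgms`,
#'   `tgm_group_mean`, `tgm_contrasts`, `model_timecourses`,
#'   `model_contrasts`, `behavior`, `behavior_stats`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  subjects <- subject_table(config)

  # --- simulate + decode ---------------------------------------------------
  rdms <- purrr::map(seq_len(nrow(subjects)), function(k) {
    sched <- if (subjects$is_patient[k]) config$schedule_patient else config$schedule_control
    cfg <- sim_config(
      config$catalog, sched,
      n_trials_per_stimulus = config$n_trials_per_stimulus,
      n_channels = config$n_channels, sampling_rate = config$sampling_rate,
      epoch_window = config$epoch_window,
      repeat_probability = config$repeat_probability,
      seed = subjects$sim_seed[k]
    )
    epochs <- sim_epochs(cfg)
    compute_rdm_series(epochs,
      time_range = config$decode_time_range,
      folds = config$folds, repetitions = config$repetitions,
      seed = config$seed
    )
  })
  names(rdms) <- subjects$subject

  # --- temporal generalization --------------------------------------------
  tgms <- purrr::map(config$subsets, function(ss) {
    purrr::map(rdms, function(r) {
      compute_tgm(subset_pairs(r, ss), metric = config$tgm_metric,
                  time_range = config$contrast_time_range)
    })
  })
  names(tgms) <- config$subsets
  tgm_group_mean <- purrr::map(tgms, function(tt) group_mean_tgm(tt[!subjects$is_patient]))
  tgm_contrasts <- purrr::map(tgms, function(tt) {
    tgm_case_contrast(tt$patient, tt[!subjects$is_patient], alpha = config$alpha)
  })

  # --- model comparisons ---------------------------------------------------
  model_timecourses <- NULL
  model_contrasts <- NULL
  if (length(config$models)) {
    model_timecourses <- purrr::map(names(config$models), function(mn) {
      ctrl_name <- config$partials[mn]
      ctrl <- if (!is.na(ctrl_name) && length(ctrl_name)) config$models[[ctrl_name]]
      purrr::map2(rdms, subjects$subject, function(r, sid) {
        model_timecourse(r, config$models[[mn]], partial_out = ctrl, subject = sid)
      })
    })
    names(model_timecourses) <- names(config$models)
    model_contrasts <- purrr::map(model_timecourses, function(tcs) {
      timecourse_case_contrast(tcs$patient, tcs[!subjects$is_patient],
                               alpha = config$alpha)
    })
  }

  # --- behavioral statistics ----------------------------------------------
  behavior <- sim_behavior(config$n_controls,
                           patient_face_deficit = config$patient_face_deficit,
                           seed = config$seed + 7L)
  fs <- face_specific_score(behavior)
  is_pat <- behavior$group == "patient"
  ch_face <- crawford_howell(fs$scores$pc_score[is_pat], fs$scores$pc_score[!is_pat])
  ch_cfmt <- crawford_howell(behavior$cfmt_score[is_pat], behavior$cfmt_score[!is_pat])
  behavior_stats <- dplyr::bind_rows(
    dplyr::mutate(tidy(ch_face), measure = "face_specific_score"),
    dplyr::mutate(tidy(ch_cfmt), measure = "cfmt_score")
  )
  young <- behavior$group == "control_young"
  matched <- behavior$group == "control_matched"
  if (sum(young) >= 2 && sum(matched) >= 2) {
    sub_t <- two_sample_t(behavior$cfmt_score[young], behavior$cfmt_score[matched])
    behavior_stats <- dplyr::bind_rows(
      behavior_stats,
      tibble::tibble(t = sub_t$t, df = sub_t$df, p = sub_t$p,
                     measure = "cfmt_young_vs_matched")
    )
  }

  bundle <- structure(
    list(subjects = subjects, rdms = rdms, tgms = tgms,
         tgm_group_mean = tgm_group_mean, tgm_contrasts = tgm_contrasts,
         model_timecourses = model_timecourses,
         model_contrasts = model_contrasts, behavior = behavior,
         face_score = fs, behavior_stats = behavior_stats),
    class = "report_bundle"
  )

  if (!is.null(out_dir)) {
    bundle$manifest <- write_report_bundle(bundle, config, out_dir)
  }
  invisible(bundle)
}

write_report_bundle <- function(bundle, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  p <- file.path(out_dir, "catalog.csv")
  readr::write_csv(as.data.frame(config$catalog), p); paths <- c(paths, p)
  p <- file.path(out_dir, "behavior.csv")
  readr::write_csv(bundle$behavior, p); paths <- c(paths, p)
  p <- file.path(out_dir, "face_scores.csv")
  readr::write_csv(bundle$face_score$scores, p); paths <- c(paths, p)
  p <- file.path(out_dir, "behavior_stats.csv")
  readr::write_csv(bundle$behavior_stats, p); paths <- c(paths, p)

  for (sid in names(bundle$rdms)) {
    d <- file.path(out_dir, "rdm", sid)
    write_rdm_series(bundle$rdms[[sid]], d)
    paths <- c(paths, file.path(d, "values.csv"))
  }
  for (ss in names(bundle$tgms)) {
    for (sid in names(bundle$tgms[[ss]])) {
      p <- file.path(out_dir, "tgm", ss, paste0(sid, ".csv"))
      dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
      write_tgm_csv(bundle$tgms[[ss]][[sid]], p); paths <- c(paths, p)
    }
    p <- file.path(out_dir, "tgm", ss, "group_mean.csv")
    write_tgm_csv(bundle$tgm_group_mean[[ss]], p); paths <- c(paths, p)
    ct <- bundle$tgm_contrasts[[ss]]
    p <- file.path(out_dir, "tgm", ss, "contrast_t.csv")
    write_tgm_csv(ct$t_map, p, ct$time_ms); paths <- c(paths, p)
    p <- file.path(out_dir, "tgm", ss, "contrast_p.csv")
    write_tgm_csv(ct$p_map, p, ct$time_ms); paths <- c(paths, p)
  }
  if (!is.null(bundle$model_timecourses)) {
    tc_long <- purrr::map_dfr(bundle$model_timecourses, dplyr::bind_rows)
    p <- file.path(out_dir, "model_timecourses.csv")
    readr::write_csv(tc_long, p); paths <- c(paths, p)
    ct_long <- purrr::map_dfr(names(bundle$model_contrasts), function(mn) {
      dplyr::mutate(tibble::as_tibble(bundle$model_contrasts[[mn]]), model = mn)
    })
    p <- file.path(out_dir, "model_contrasts.csv")
    readr::write_csv(ct_long, p); paths <- c(paths, p)
  }

  manifest <- list(
    package = "casersa",
    version = as.character(utils::packageVersion("casersa")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    artifacts = stats::setNames(
      lapply(paths, function(f) rlang::hash(readBin(f, "raw", file.size(f)))),
      sub(paste0("^", out_dir, "/?"), "", paths)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    "<report_bundle> %d subjects (1 patient), %d pair subset(s), %d model(s)\n",
    nrow(x$subjects), length(x$tgms),
    length(x$model_timecourses %||% list())
  ))
  invisible(x)
}
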
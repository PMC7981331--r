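#' @name pipeline
#' @title End-to-end analysis pipeline
#' @description
#' Orchestrates the full analysis: EEG (read or synthesised) ->
#' preprocessing and artifact masking -> vigilance staging -> arousal
#' stability score and hypoaroused/non-hypoaroused stratification ->
#' questionnaire scoring with the inclusion cascade -> group-comparison
#' tables. Per-subject failures are quarantined with a machine-readable
#' exclusion reason rather than aborting the batch.
NULL

#' Score one subject's questionnaire row
#'
#' Applies the instrument scorers to a cohort-table row and the
#' computable inclusion rules (at most 2 missing items per
#' questionnaire; general fatigue above the sex/age norm threshold).
#'
#' @param row One-row data frame (or named list) in the cohort layout of
#'   [read_cohort()].
#' @param norms Norm table from [read_mfi_norms()], or NULL to skip the
#'   fatigue cut-off.
#' @return Named list of scores plus `included` and `exclusion_reason`.
#' @export
score_subject <- function(row, norms = NULL) {
  getv <- function(pref, n) {
    cols <- sprintf("%s%02d", pref, seq_len(n))
    unlist(row[cols], use.names = FALSE)
  }
  out <- list(subject_id = row$subject_id, included = TRUE,
              exclusion_reason = NA_character_)
  mfi <- score_mfi(as.numeric(getv("mfi_", 20)))
  bdi <- score_bdi(getv("bdi_", 21))
  ess <- score_ess(as.numeric(getv("ess_", 8)))
  qcols <- grep("^sfa_q", names(row), value = TRUE)
  sfar <- score_sfar(as.numeric(unlist(row[qcols], use.names = FALSE)),
                     row$sfa_bedtime %||% NA, row$sfa_risetime %||% NA)
  for (res in list(mfi, bdi, ess)) {
    if (!res$valid) {
      out$included <- FALSE
      out$exclusion_reason <- "missing_items"
    }
  }
  out$mfi <- if (mfi$valid) mfi$scores else
    stats::setNames(rep(NA_real_, 5), names(mfi_key()$dimensions))
  out$bdi_total <- if (bdi$valid) bdi$total else NA_real_
  out$ess_total <- if (ess$valid) ess$total else NA_real_
  out$ess_flag_sleepy <- if (ess$valid) ess$sleepy_flag else NA
  out$sss <- as.numeric(row$sss %||% NA)
  out$sfar_quality <- sfar$quality
  out$sfar_time_in_bed <- sfar$time_in_bed_hours
  if (out$included && !is.null(norms)) {
    inc <- apply_inclusion(out$mfi[["general_fatigue"]], norms,
                           age = row$age, sex = row$sex)
    if (!inc) {
      out$included <- FALSE
      out$exclusion_reason <- "below_mfi_cutoff"
    }
  }
  out
}

#' Score a whole cohort table
#'
#' @param cohort Data frame from [read_cohort()] or [generate_cohort()].
#' @param norms Norm table, or NULL to skip the fatigue cut-off.
#' @return Data frame: one row per subject with questionnaire scores,
#'   `included` and `exclusion_reason`.
#' @export
score_cohort <- function(cohort, norms = NULL) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    s <- score_subject(cohort[i, ], norms)
    data.frame(subject_id = s$subject_id,
               age = cohort$age[i], sex = cohort$sex[i],
               med_status = cohort$med_status[i] %||% NA,
               general_fatigue = s$mfi[["general_fatigue"]],
               physical_fatigue = s$mfi[["physical_fatigue"]],
               mental_fatigue = s$mfi[["mental_fatigue"]],
               reduced_activity = s$mfi[["reduced_activity"]],
               reduced_motivation = s$mfi[["reduced_motivation"]],
               bdi_total = s$bdi_total, ess_total = s$ess_total,
               ess_flag_sleepy = s$ess_flag_sleepy, sss = s$sss,
               sfar_quality = s$sfar_quality,
               sfar_time_in_bed = s$sfar_time_in_bed,
               included = s$included,
               exclusion_reason = s$exclusion_reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-comparison tables
#'
#' For each continuous variable: per-group mean and SD, Mann-Whitney Z,
#' two-sided p, eta-squared and a percentile-bootstrap confidence
#' interval. For each categorical variable: 2x2 counts and Pearson
#' chi-square. With fewer than 2 subjects in a group the tests are
#' marked not computable instead of failing.
#'
#' @param subjects Data frame with a `group` column ("hypoaroused" /
#'   "non_hypoaroused") and the variables below.
#' @param continuous Character vector of continuous variable names.
#' @param categorical Character vector of binary categorical variable
#'   names.
#' @param boot_reps Bootstrap replications for the CI (default 10000).
#' @param ci_level Confidence level (default 0.90).
#' @param seed Seed for the bootstrap.
#' @return List with data frames `continuous` and `categorical`.
#' @export
make_group_tables <- function(subjects,
                              continuous = c("general_fatigue",
                                             "physical_fatigue",
                                             "mental_fatigue",
                                             "reduced_activity",
                                             "reduced_motivation",
                                             "bdi_total", "ess_total",
                                             "sss", "sfar_quality",
                                             "sfar_time_in_bed", "age"),
                              categorical = c("sex", "med_status"),
                              boot_reps = 10000L, ci_level = 0.90,
                              seed = 1L) {
  nh <- subjects[subjects$group == "non_hypoaroused", , drop = FALSE]
  hy <- subjects[subjects$group == "hypoaroused", , drop = FALSE]
  computable <- nrow(nh) >= 2 && nrow(hy) >= 2
  continuous <- intersect(continuous, names(subjects))
  cont <- lapply(continuous, function(v) {
    x <- nh[[v]]; y <- hy[[v]]
    base <- data.frame(
      variable = v,
      mean_non_hypo = mean(x, na.rm = TRUE),
      sd_non_hypo = stats::sd(x, na.rm = TRUE),
      n_non_hypo = sum(!is.na(x)),
      mean_hypo = mean(y, na.rm = TRUE),
      sd_hypo = stats::sd(y, na.rm = TRUE),
      n_hypo = sum(!is.na(y)))
    if (!computable || sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) {
      return(cbind(base, z = NA_real_, p = NA_real_,
                   eta_squared = NA_real_, eta_ci_lo = NA_real_,
                   eta_ci_hi = NA_real_))
    }
    mw <- mann_whitney(x, y)
    ci <- bootstrap_ci(x, y, reps = boot_reps, level = ci_level,
                       seed = seed)
    cbind(base, z = mw$z, p = mw$p, eta_squared = mw$eta_squared,
          eta_ci_lo = ci$lo, eta_ci_hi = ci$hi)
  })
  categorical <- intersect(categorical, names(subjects))
  cat_rows <- lapply(categorical, function(v) {
    lv <- sort(unique(stats::na.omit(subjects[[v]])))
    base <- data.frame(variable = v,
                       levels = paste(lv, collapse = "/"),
                       counts_non_hypo = paste(
                         table(factor(nh[[v]], levels = lv)),
                         collapse = "/"),
                       counts_hypo = paste(
                         table(factor(hy[[v]], levels = lv)),
                         collapse = "/"))
    if (!computable || length(lv) != 2L) {
      return(cbind(base, chi_squared = NA_real_, p = NA_real_))
    }
    tab <- rbind(table(factor(nh[[v]], levels = lv)),
                 table(factor(hy[[v]], levels = lv)))
    res <- tryCatch(chi_square_2x2(tab), error = function(e) NULL)
    if (is.null(res)) {
      cbind(base, chi_squared = NA_real_, p = NA_real_)
    } else {
      cbind(base, chi_squared = res$statistic, p = res$p)
    }
  })
  list(continuous = do.call(rbind, cont),
       categorical = do.call(rbind, cat_rows))
}

#' Plot a vigilance stage time course
#'
#' Step plot of the per-second stage score over the recording, in the
#' style of a stage hypnogram (higher = higher arousal); artifact
#' segments are shown as gaps.
#'
#' @param seq A [stage_sequence()].
#' @return A ggplot object.
#' @export
plot_stage_timecourse <- function(seq) {
  stopifnot(inherits(seq, "stage_sequence"))
  df <- data.frame(time_s = seq_along(seq$stages) - 1L,
                   score = stage_score(seq$stages))
  df$score[seq$artifact_mask] <- NA
  time_s <- score <- NULL  # appease R CMD check for aes() columns
  ggplot2::ggplot(df, ggplot2::aes(x = time_s, y = score)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::scale_y_continuous(
      breaks = 7:1, labels = VIGILANCE_STAGES, limits = c(1, 7),
      name = "vigilance stage") +
    ggplot2::labs(x = "time (s)",
                  title = paste("EEG vigilance time course:",
                                seq$subject_id)) +
    ggplot2::theme_minimal()
}

#' Run the full pipeline from a config
#'
#' The config (YAML path or list) may contain:
#' \describe{
#'   \item{seed}{master seed (default 1)}
#'   \item{out_dir}{output directory; NULL for no file output}
#'   \item{synth_eeg}{list(n, duration_s, sfreq, profiles) — synthesise
#'     an EEG batch; `profiles` recycles over subjects}
#'   \item{eeg_files}{character vector of .vhdr/.edf paths}
#'   \item{cohort_csv / cohort_synth}{questionnaire table source;
#'     `cohort_synth` is a list passed to [cohort_config()]}
#'   \item{norms_csv}{MFI norm table (default: shipped synthetic
#'     placeholder)}
#'   \item{preprocess / vigilance / stats}{parameter overrides for
#'     [preprocess_config()], [classifier_config()],
#'     [make_group_tables()]}
#' }
#' EEG-derived stability scores override any generator-side group label
#' for subjects that have both. Every excluded subject carries a
#' machine-readable reason; per-subject EEG failures are quarantined.
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @return List of class `analysis_report`: `subjects` (per-subject
#'   table), `stage_sequences`, `group_tables`, `exclusions`, `meta`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- cfg$seed %||% 1L
  pre_cfg <- do.call(preprocess_config, cfg$preprocess %||% list())
  vig_cfg <- do.call(classifier_config, cfg$vigilance %||% list())
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  # --- EEG batch ---------------------------------------------------------
  recs <- list()
  if (!is.null(cfg$synth_eeg)) {
    se <- cfg$synth_eeg
    n <- se$n %||% 10L
    profiles <- rep(se$profiles %||% c("stable_high", "declining"),
                    length.out = n)
    for (i in seq_len(n)) {
      sid <- sprintf("S%03d", i)
      script <- make_stage_script(profiles[i],
                                  duration_s = se$duration_s %||% 900,
                                  seed = seed + i)
      recs[[sid]] <- list(rec = synthesize_recording(
        script, sfreq = se$sfreq %||% 256, seed = seed + 1000L + i,
        subject_id = sid), script = script)
    }
  }
  for (p in cfg$eeg_files %||% character(0)) {
    rec <- tryCatch(
      if (grepl("\\.vhdr$", p)) read_brainvision(p) else read_edf(p),
      error = function(e) e)
    recs[[length(recs) + 1L]] <- list(rec = rec, script = NULL)
    names(recs)[length(recs)] <- if (inherits(rec, "error"))
      basename(p) else rec$subject_id
  }

  stage_seqs <- list()
  eeg_rows <- list()
  exclusions <- list()
  for (sid in names(recs)) {
    entry <- recs[[sid]]
    if (inherits(entry$rec, "error")) {
      exclusions[[sid]] <- paste0("read_error: ",
                                  conditionMessage(entry$rec))
      next
    }
    res <- tryCatch({
      pp <- preprocess_recording(entry$rec, pre_cfg)
      if (!pp$usable) {
        exclusions[[sid]] <- "artifact_fraction"
        NULL
      } else {
        seqr <- classify_recording(pp$rec, pp$mask, vig_cfg)
        stab <- stability_score(seqr)
        stage_seqs[[sid]] <- seqr
        if (!is.null(out_dir)) {
          write_stage_sequence(seqr,
                               file.path(out_dir,
                                         paste0(sid, "_stages.csv")))
        }
        data.frame(subject_id = sid, stability_score = stab$score,
                   group = stab$group,
                   matched_criterion = stab$matched_criterion,
                   true_score = if (!is.null(entry$script))
                     entry$script$true_score else NA_integer_,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      exclusions[[sid]] <<- paste0("stage_error: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) eeg_rows[[sid]] <- res
  }
  eeg_tab <- if (length(eeg_rows)) do.call(rbind, eeg_rows) else NULL

  # --- cohort ------------------------------------------------------------
  subjects <- NULL
  if (!is.null(cfg$cohort_csv) || !is.null(cfg$cohort_synth)) {
    cohort <- if (!is.null(cfg$cohort_csv)) read_cohort(cfg$cohort_csv)
      else generate_cohort(do.call(cohort_config,
                                   utils::modifyList(
                                     list(seed = seed),
                                     cfg$cohort_synth %||% list())))
    norms <- read_mfi_norms(cfg$norms_csv %||%
                              system.file("extdata",
                                          "mfi_norms_synthetic.csv",
                                          package = "arousalstrat"))
    scored <- score_cohort(cohort, norms)
    if (!is.null(cohort$group)) scored$group <- cohort$group
    if (!is.null(cohort$stability_score) &&
        !"stability_score" %in% names(scored)) {
      scored$stability_score <- cohort$stability_score
    }
    subjects <- scored
  }
  if (!is.null(eeg_tab)) {
    if (is.null(subjects)) {
      subjects <- eeg_tab
    } else {
      keep <- setdiff(names(eeg_tab), "subject_id")
      merged <- merge(subjects,
                      eeg_tab[, c("subject_id", "stability_score",
                                  "group")],
                      by = "subject_id", all.x = TRUE,
                      suffixes = c("", ".eeg"))
      if ("group.eeg" %in% names(merged)) {
        use <- !is.na(merged$group.eeg)
        merged$group[use] <- merged$group.eeg[use]
        merged$group.eeg <- NULL
      }
      if ("stability_score.eeg" %in% names(merged)) {
        use <- !is.na(merged$stability_score.eeg)
        merged$stability_score[use] <- merged$stability_score.eeg[use]
        merged$stability_score.eeg <- NULL
      }
      subjects <- merged
    }
  }
  for (sid in names(exclusions)) {
    if (!is.null(subjects) && sid %in% subjects$subject_id) {
      subjects$included[subjects$subject_id == sid] <- FALSE
      subjects$exclusion_reason[subjects$subject_id == sid] <-
        exclusions[[sid]]
    }
  }
  if (is.null(subjects)) stop("empty final cohort: no usable subjects",
                              call. = FALSE)

  included <- if ("included" %in% names(subjects))
    subjects[is.na(subjects$included) | subjects$included, , drop = FALSE]
    else subjects
  group_tables <- if (!is.null(included$group) &&
                      length(unique(stats::na.omit(included$group))) >= 1) {
    st <- cfg$stats %||% list()
    make_group_tables(included,
                      boot_reps = st$boot_reps %||% 10000L,
                      ci_level = st$ci_level %||% 0.90,
                      seed = seed)
  } else NULL

  report <- structure(
    list(subjects = subjects, stage_sequences = stage_seqs,
         group_tables = group_tables,
         exclusions = exclusions,
         meta = list(seed = seed, timestamp = format(Sys.time()),
                     n_subjects = nrow(subjects),
                     n_included = nrow(included))),
    class = "analysis_report")
  if (!is.null(out_dir)) {
    utils::write.csv(subjects, file.path(out_dir, "subjects.csv"),
                     row.names = FALSE)
    if (!is.null(group_tables)) {
      utils::write.csv(group_tables$continuous,
                       file.path(out_dir, "group_table_continuous.csv"),
                       row.names = FALSE)
      utils::write.csv(group_tables$categorical,
                       file.path(out_dir, "group_table_categorical.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report$meta,
                         file.path(out_dir, "run_meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", x$meta$n_subjects, "subjects,",
      x$meta$n_included, "included,", length(x$exclusions),
      "excluded\n")
  if (!is.null(x$group_tables)) {
    cat("group sizes:\n")
    print(table(x$subjects$group))
  }
  invisible(x)
}
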
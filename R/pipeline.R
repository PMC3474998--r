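#' Subset the trials of a beta series
#'
#' @param bs A [beta_series()].
#' @param rows Trial rows to keep (indices into the current rows).
#' @return A [beta_series()] with the retained trials.
#' @export
subset_trials <- function(bs, rows) {
  stopifnot(inherits(bs, "beta_series"))
  beta_series(bs$betas[rows, , drop = FALSE], bs$voxel_coords,
              trial_index = bs$trial_index[rows],
              roi_label = bs$roi_label, hemisphere = bs$hemisphere)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic-cohort analysis
#'
#' For every subject: simulate masks, behavior and BOLD; smooth; fit the
#' per-trial GLM in each of the eight subfield ROIs; apply the
#' trial-exclusion rules; and run up to three decoding analyses per ROI —
#' `"scenes"` (leave-one-out decoding of the two original scenes from
#' choice-labelled trials), `"cross"` (train on 100% scenes, test on
#' choice-labelled 50% morphs; the motor-confound control), and `"morph50"`
#' (leave-one-out decoding of the choice on 50% morph trials). Group-level
#' statistics (hemisphere check and collapse, t-tests against 50% chance,
#' one-way repeated-measures ANOVA across subfields, paired t-tests) are
#' computed per analysis when at least two subjects are available.
#'
#' The run is fully deterministic given the config (including its seed).
#'
#' @param config A [sim_config()].
#' @param analyses Subset of `c("scenes", "cross", "morph50")`.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 3).
#' @param radius_voxels Searchlight radius (default 3).
#' @param svm An [svm_spec()].
#' @param rule,target_fraction Feature selection settings, see
#'   [select_features()].
#' @param out_dir Optional directory for artifacts (config snapshot, event
#'   tables, masks, per-ROI results JSON, group CSVs).
#' @param verbose Print per-stage progress to stderr.
#' @return A `cohort_run`: `accuracy` (long data.frame of per
#'   subject/ROI/hemisphere/analysis accuracies), `group` (per-analysis
#'   group statistics), `config`.
#' @export
run_cohort <- function(config, analyses = c("scenes", "cross", "morph50"),
                       fwhm_mm = 3, radius_voxels = 3L, svm = svm_spec(),
                       rule = "union_top", target_fraction = 0.6,
                       out_dir = NULL, verbose = FALSE) {
  validate_sim_config(config)
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  rows <- list()
  for (s in seq_len(config$n_subjects)) {
    say("subject %d/%d: simulate", s, config$n_subjects)
    sim <- run_stage(sprintf("simulate subject %d", s), simulate_subject(config, s))
    bold_s <- run_stage(sprintf("smooth subject %d", s),
                        smooth_gaussian(sim$bold, fwhm_mm))
    n_scans <- dim(bold_s$data)[4]
    design <- run_stage(sprintf("design subject %d", s),
                        build_design(sim$events, n_scans, config$tr_s,
                                     stimulus_dur_s = config$stimulus_dur_s))
    ev_sc <- filter_trials(sim$events, "original_scenes")
    ev_50 <- filter_trials(sim$events, "morph50")
    if (!is.null(out_dir)) {
      sd <- file.path(out_dir, sprintf("sub-%02d", s))
      dir.create(sd, showWarnings = FALSE)
      write_events_tsv(sim$events, file.path(sd, "events.tsv"))
      for (nm in names(sim$masks))
        write_mask_nifti(sim$masks[[nm]], file.path(sd, paste0("mask_", nm, ".nii.gz")))
      write_ground_truth_json(sim$truth, file.path(sd, "ground_truth.json"))
    }
    for (nm in names(sim$masks)) {
      mask <- sim$masks[[nm]]
      say("subject %d: GLM + decode %s", s, nm)
      bs <- run_stage(sprintf("GLM subject %d ROI %s", s, nm),
                      fit_beta_series(bold_s, design, mask))
      spec <- searchlight_spec(mask, radius_voxels)
      res <- list()
      if ("scenes" %in% analyses)
        res$scenes <- run_stage(sprintf("decode scenes subject %d ROI %s", s, nm),
          loo_decode(subset_trials(bs, attr(ev_sc, "trial_index")),
                     ev_sc$choice, spec, svm, rule, target_fraction, subject = s))
      if ("morph50" %in% analyses)
        res$morph50 <- run_stage(sprintf("decode morph50 subject %d ROI %s", s, nm),
          loo_decode(subset_trials(bs, attr(ev_50, "trial_index")),
                     ev_50$choice, spec, svm, rule, target_fraction, subject = s))
      if ("cross" %in% analyses)
        res$cross <- run_stage(sprintf("decode cross subject %d ROI %s", s, nm),
          cross_decode(subset_trials(bs, attr(ev_sc, "trial_index")), ev_sc$choice,
                       subset_trials(bs, attr(ev_50, "trial_index")), ev_50$choice,
                       spec, svm, rule, target_fraction, subject = s))
      for (an in names(res)) {
        r <- res[[an]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, subfield = mask$subfield, hemisphere = mask$hemisphere,
          analysis = an, accuracy = r$accuracy, n_test = r$n_test,
          mean_selected_voxels = r$mean_selected_voxels,
          stringsAsFactors = FALSE)
      }
      if (!is.null(out_dir)) {
        sd <- file.path(out_dir, sprintf("sub-%02d", s))
        for (an in names(res))
          jsonlite::write_json(
            list(subject = s, roi = nm, analysis = an,
                 accuracy = res[[an]]$accuracy, n_test = res[[an]]$n_test,
                 mean_selected_voxels = res[[an]]$mean_selected_voxels,
                 seed = config$seed),
            file.path(sd, sprintf("decode_%s_%s.json", nm, an)),
            auto_unbox = TRUE, digits = NA)
      }
    }
  }
  accuracy <- do.call(rbind, rows)
  group <- list()
  if (config$n_subjects >= 2L) {
    for (an in unique(accuracy$analysis)) {
      sub <- accuracy[accuracy$analysis == an, ]
      hc <- run_stage(sprintf("group stats (%s)", an),
                      hemisphere_check_and_collapse(sub))
      collapsed <- hc$collapsed
      tt <- lapply(colnames(collapsed), function(rg) {
        # degenerate cells (e.g. all subjects at ceiling) are reported, not fatal
        r <- tryCatch(ttest_vs_chance(collapsed[, rg], 0.5),
                      error = function(e) list(t = NA_real_,
                                               df = nrow(collapsed) - 1L,
                                               p = NA_real_))
        data.frame(subfield = rg, t = r$t, df = r$df, p = r$p,
                   mean_accuracy = mean(collapsed[, rg]),
                   stringsAsFactors = FALSE)
      })
      group[[an]] <- list(
        hemisphere_tests = hc$hemisphere_tests,
        collapsed = collapsed,
        vs_chance = do.call(rbind, tt),
        anova = if (ncol(collapsed) >= 2L) rm_anova(collapsed),
        pairwise = if (ncol(collapsed) >= 2L) paired_ttests(collapsed))
    }
  }
  out <- structure(list(config = config, accuracy = accuracy, group = group,
                        analyses = analyses, fwhm_mm = fwhm_mm,
                        radius_voxels = radius_voxels,
                        rule = rule, target_fraction = target_fraction),
                   class = "cohort_run")
  if (!is.null(out_dir)) {
    cfg <- unclass(config)
    cfg$target_counts <- as.list(cfg$target_counts)
    jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    write.table(accuracy, file.path(out_dir, "accuracy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (an in names(group)) {
      write.table(group[[an]]$vs_chance,
                  file.path(out_dir, sprintf("group_%s_vs_chance.csv", an)),
                  sep = ",", quote = FALSE, row.names = FALSE)
      if (!is.null(group[[an]]$pairwise))
        write.table(group[[an]]$pairwise,
                    file.path(out_dir, sprintf("group_%s_pairwise.csv", an)),
                    sep = ",", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' @export
print.cohort_run <- function(x, ...) {
  cat(sprintf("<cohort_run> %d subjects, analyses: %s\n",
              x$config$n_subjects, paste(x$analyses, collapse = ", ")))
  agg <- stats::aggregate(accuracy ~ analysis + subfield, data = x$accuracy, FUN = mean)
  for (an in unique(agg$analysis)) {
    sub <- agg[agg$analysis == an, ]
    cat(sprintf("  %-8s %s\n", an,
                paste(sprintf("%s %.3f", sub$subfield, sub$accuracy),
                      collapse = "  ")))
  }
  invisible(x)
}

#' @export
summary.cohort_run <- function(object, ...) {
  print(object)
  for (an in names(object$group)) {
    g <- object$group[[an]]
    cat(sprintf("\n-- %s: t-tests vs chance (50%%) --\n", an))
    print(g$vs_chance, row.names = FALSE)
    if (!is.null(g$anova))
      cat(sprintf("ANOVA across subfields: F(%d, %d) = %.3f, p = %.4g\n",
                  g$anova$df_between, g$anova$df_error, g$anova$F, g$anova$p))
  }
  invisible(object)
}

#' Mean decoding accuracy per subfield with standard errors
#'
#' @param x A `cohort_run`.
#' @param ... Unused.
#' @export
plot.cohort_run <- function(x, ...) {
  ans <- unique(x$accuracy$analysis)
  old <- graphics::par(mfrow = c(1, length(ans)))
  on.exit(graphics::par(old))
  for (an in ans) {
    sub <- x$accuracy[x$accuracy$analysis == an, ]
    m <- tapply(sub$accuracy, sub$subfield, mean)
    se <- tapply(sub$accuracy, sub$subfield, function(v) sd(v) / sqrt(length(v)))
    bp <- graphics::barplot(m, ylim = c(0, 1), main = an,
                            ylab = "decoding accuracy")
    graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3, length = 0.05)
    graphics::abline(h = 0.5, lty = 2)
  }
  invisible(x)
}
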
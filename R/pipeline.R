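#' Pipeline run configuration
#'
#' Bundles every stage's settings: cohort simulation, filtering, event
#' detection, step filtering, impact-peak definition, modeling and evaluation.
#' All thresholds default to the package's documented conventions.
#'
#' @param cohort A [cohort_config()] (used when simulating).
#' @param filter List: `grf_cutoff_hz` (30), `accel_cutoff_hz` (60), `order` (5).
#' @param events List: `ic_threshold_g` (0.18), `rise_g` (0.5),
#'   `rise_window_s` (0.10), `pre_window_s` (0.10), `refractory_s` (0.2),
#'   `to_threshold_g` (-0.25), `match_tol_s` (0.10).
#' @param steps List: `min_duration_s` (0.167), `max_duration_s` (0.4),
#'   `min_peak_bw` (1.2).
#' @param impact List: `window_frac` (0.10), `prominence_bw` (0.05).
#' @param model List: `lambdas` (the 20-point grid), `window_kinds`
#'   (both), `use_speed` (both with and without).
#' @param test_fraction Subject-level test fraction (default 7/43).
#' @param speed_groups Speed groups for per-speed evaluation (default: the
#'   cohort's speeds).
#' @param seed Integer seed for split and simulation sub-streams.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       filter = list(),
                       events = list(),
                       steps = list(),
                       impact = list(),
                       model = list(),
                       test_fraction = 7 / 43,
                       speed_groups = NULL,
                       seed = 1L) {
  merge_defaults <- function(user, defaults) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  structure(list(
    cohort = cohort,
    filter = merge_defaults(filter, list(grf_cutoff_hz = 30, accel_cutoff_hz = 60, order = 5L)),
    events = merge_defaults(events, list(ic_threshold_g = 0.18, rise_g = 0.5,
                                         rise_window_s = 0.10, pre_window_s = 0.10,
                                         refractory_s = 0.2, to_threshold_g = -0.25,
                                         match_tol_s = 0.10)),
    steps = merge_defaults(steps, list(min_duration_s = 0.167, max_duration_s = 0.4,
                                       min_peak_bw = 1.2)),
    impact = merge_defaults(impact, list(window_frac = 0.10, prominence_bw = 0.05)),
    model = merge_defaults(model, list(lambdas = lambda_grid(),
                                       window_kinds = c("stance", "entire_step"),
                                       use_speed = c(FALSE, TRUE))),
    test_fraction = test_fraction,
    speed_groups = speed_groups,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `cohort` keys are
#' passed to [cohort_config()]. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, if (is.null(y$cohort)) list() else y$cohort)
  run_config(cohort = cohort,
             filter = if (is.null(y$filter)) list() else y$filter,
             events = if (is.null(y$events)) list() else y$events,
             steps = if (is.null(y$steps)) list() else y$steps,
             impact = if (is.null(y$impact)) list() else y$impact,
             test_fraction = if (is.null(y$test_fraction)) 7 / 43 else y$test_fraction,
             speed_groups = y$speed_groups,
             seed = if (is.null(y$seed)) cohort$seed else y$seed)
}

#' Process one trial: filter, detect, match, filter steps, characterize
#'
#' @param trial A `trial_record`.
#' @param config A [run_config()].
#' @return List with the filtered/normalized signals, kept steps, per-step
#'   characteristics, baseline estimates and stage counts.
#' @export
process_trial <- function(trial, config) {
  fl <- config$filter
  ev <- config$events
  grf_f <- butterworth_lowpass(trial$grf, fl$order, fl$grf_cutoff_hz)
  vgrf_bw <- normalize_to_bw(grf_f, trial$subject$mass)
  acc <- lapply(trial[c("accel_v", "accel_ap", "accel_ml")],
                butterworth_lowpass, order = fl$order, cutoff = fl$accel_cutoff_hz)
  grf_st <- detect_steps_grf(grf_f)
  acc_st <- detect_stances_accel(acc$accel_v,
                                 threshold_g = ev$ic_threshold_g, rise_g = ev$rise_g,
                                 rise_window_s = ev$rise_window_s,
                                 pre_window_s = ev$pre_window_s,
                                 refractory_s = ev$refractory_s)
  matched <- match_steps(acc_st, grf_st, tol_s = ev$match_tol_s)
  kept <- if (nrow(matched)) {
    filter_steps(matched, vgrf_bw, config$steps$min_duration_s,
                 config$steps$max_duration_s, config$steps$min_peak_bw)
  } else matched

  chars <- if (nrow(kept)) {
    extract_characteristics(kept, vgrf_bw, config$impact$window_frac,
                            config$impact$prominence_bw)
  } else NULL
  est <- if (nrow(kept)) alcantara_characteristics(acc$accel_v, trial$subject$mass, kept) else NULL

  veras_est <- rep(NA_real_, nrow(kept))
  if (nrow(kept) && !is.null(trial$accel_neck_v)) {
    anthro <- anthropometric_model()
    neck_f <- butterworth_lowpass(trial$accel_neck_v, fl$order, fl$accel_cutoff_hz)
    l5_f <- butterworth_lowpass(trial$accel_l5_v, fl$order, fl$accel_cutoff_hz)
    a_com <- trunk_com_acceleration(neck_f, l5_f, anthro)
    veras_est <- veras_impact_peak(a_com, anthro, kept, config$impact$window_frac)
  }

  ftrial <- trial
  ftrial$accel_v <- acc$accel_v; ftrial$accel_ap <- acc$accel_ap; ftrial$accel_ml <- acc$accel_ml
  feat_stance <- if (nrow(kept)) trial_feature_table(ftrial, kept, "stance") else NULL
  feat_step <- if (nrow(kept)) trial_feature_table(ftrial, kept, "entire_step") else NULL

  list(vgrf_bw = vgrf_bw, accel_v = acc$accel_v,
       steps = kept, characteristics = chars, est = est, veras_est = veras_est,
       features_stance = feat_stance, features_step = feat_step,
       counts = c(grf_detected = nrow(grf_st), accel_detected = nrow(acc_st),
                  matched = nrow(matched), retained = nrow(kept),
                  with_impact = if (is.null(chars)) 0L else sum(!is.na(chars$impact_peak_bw))))
}

target_names <- c("active_peak", "impact_peak", "impulse", "contact_time")
target_cols <- c(active_peak = "active_peak_bw", impact_peak = "impact_peak_bw",
                 impulse = "impulse_bw_s", contact_time = "contact_time_s")

# mean over LOSO folds of the per-fold RMSE for an arbitrary fit/predict pair
loso_score <- function(subject_ids, fit_fn, predict_fn, y) {
  subjects <- unique(subject_ids)
  rmse <- vapply(subjects, function(s) {
    hold <- subject_ids == s
    model <- fit_fn(!hold)
    pred <- predict_fn(model, hold)
    sqrt(mean((pred - y[hold])^2))
  }, numeric(1))
  mean(rmse)
}

#' Run the full pipeline
#'
#' Simulates (or accepts) a cohort, preprocesses every trial, detects and
#' filters steps, extracts the four ground-truth characteristics and the
#' per-step features, splits subjects into train/test, selects the penalty
#' and feature window by leave-one-subject-out validation on the train set,
#' and evaluates the Lasso models (with and without speed), the
#' acceleration-plug-in and trunk-segment comparison methods, and the
#' mean-regressor baseline on the held-out subjects, overall and per speed
#' group.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-simulated `cohort_sim` (default: simulate from
#'   `config$cohort`).
#' @param out_dir Optional directory; when given, `report.csv` and
#'   `manifest.json` are written there.
#' @return A `vgrf_run` list: `report` (data frame), `by_speed` (data frame),
#'   `manifest` (list), `models` (per-target fitted objects), `data`
#'   (assembled step/target/feature tables and the split).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$cohort)

  steps_all <- list(); targets_all <- list(); est_all <- list()
  feats_st_all <- list(); feats_sp_all <- list()
  counts <- c(grf_detected = 0L, accel_detected = 0L, matched = 0L,
              retained = 0L, with_impact = 0L)
  for (key in names(cohort$trials)) {
    tr <- cohort$trials[[key]]
    pr <- process_trial(tr, config)
    counts <- counts + pr$counts
    if (!nrow(pr$steps)) next
    meta <- data.frame(subject_id = tr$subject$subject_id, speed = tr$speed,
                       mass_kg = tr$subject$mass, stringsAsFactors = FALSE)
    steps_all[[key]] <- cbind(meta, pr$steps)
    targets_all[[key]] <- cbind(meta, pr$characteristics)
    est_all[[key]] <- cbind(pr$est, veras_est_bw = pr$veras_est)
    feats_st_all[[key]] <- pr$features_stance
    feats_sp_all[[key]] <- pr$features_step
  }
  steps <- do.call(rbind, c(steps_all, list(make.row.names = FALSE)))
  targets <- do.call(rbind, c(targets_all, list(make.row.names = FALSE)))
  est <- do.call(rbind, c(est_all, list(make.row.names = FALSE)))
  feats <- list(stance = do.call(rbind, c(feats_st_all, list(make.row.names = FALSE))),
                entire_step = do.call(rbind, c(feats_sp_all, list(make.row.names = FALSE))))

  split <- split_subjects(unique(steps$subject_id), config$test_fraction, config$seed)
  in_train <- steps$subject_id %in% split$train
  speed_groups <- if (is.null(config$speed_groups)) sort(unique(steps$speed)) else config$speed_groups

  report <- list(); by_speed <- list(); models <- list(); selection <- list()
  add_report <- function(target, model, split_name, metrics, window_kind = NA, lambda = NA) {
    report[[length(report) + 1L]] <<- cbind(
      data.frame(characteristic = target, model = model, split = split_name,
                 window_kind = window_kind, lambda = lambda, stringsAsFactors = FALSE),
      metrics)
  }
  add_by_speed <- function(target, model, metrics) {
    if (is.null(metrics)) return(invisible())
    by_speed[[length(by_speed) + 1L]] <<- cbind(
      data.frame(characteristic = target, model = model, stringsAsFactors = FALSE),
      metrics)
  }

  for (target in target_names) {
    ycol <- target_cols[[target]]
    rows <- rep(TRUE, nrow(targets))
    if (target == "impact_peak") {
      # steps with a present impact peak and an available segment-curve
      # estimate: identical evaluation rows for every method
      rows <- !is.na(targets$impact_peak_bw) & !is.na(est$veras_est_bw)
    }
    y <- targets[[ycol]][rows]
    sub <- steps$subject_id[rows]
    spd <- steps$speed[rows]
    mass <- steps$mass_kg[rows]
    tr_rows <- sub %in% split$train
    te_rows <- !tr_rows
    models[[target]] <- list()

    for (use_speed in config$model$use_speed) {
      model_name <- if (use_speed) "lasso_with_speed" else "lasso_no_speed"
      best <- NULL
      for (wk in config$model$window_kinds) {
        tbl <- feats[[wk]][rows, , drop = FALSE]
        if (use_speed) tbl$speed_ms <- tbl$speed
        train_tbl <- clean_features(tbl[tr_rows, , drop = FALSE])
        cv <- loso_cv(train_tbl, y[tr_rows], config$model$lambdas)
        val <- min(cv$scores$mean_rmse)
        if (is.null(best) || val < best$val) {
          best <- list(val = val, wk = wk, lambda = cv$selected_lambda,
                       train_tbl = train_tbl,
                       test_tbl = tbl[te_rows, names(train_tbl), drop = FALSE])
        }
      }
      model <- train_lasso_model(best$train_tbl, y[tr_rows], best$lambda)
      pred_te <- predict(model, best$test_tbl)
      add_report(target, model_name, "validation",
                 data.frame(rmse = best$val, mape_percent = NA, r2 = NA,
                            n_steps = sum(tr_rows)), best$wk, best$lambda)
      add_report(target, model_name, "test",
                 evaluate_predictions(pred_te, y[te_rows]), best$wk, best$lambda)
      add_by_speed(target, model_name,
                   evaluate_by_speed(pred_te, y[te_rows], spd[te_rows], speed_groups))
      models[[target]][[model_name]] <- model
      selection[[paste(target, model_name, sep = ".")]] <-
        list(window_kind = best$wk, lambda = best$lambda)
    }

    # comparison method: trunk-segment regression for the impact peak,
    # acceleration plug-in regression otherwise
    if (target == "impact_peak") {
      e <- est$veras_est_bw[rows]
      fit_fn <- function(sel) veras_regress(e[sel], y[sel])
      pred_fn <- function(m, sel) predict(m, e[sel])
    } else {
      e <- est[rows, , drop = FALSE]
      fit_fn <- function(sel) alcantara_regress(e[sel, , drop = FALSE], mass[sel],
                                                spd[sel], y[sel], target)
      pred_fn <- function(m, sel) predict(m, e[sel, , drop = FALSE], mass[sel], spd[sel])
    }
    cmp_val <- loso_score(sub[tr_rows],
                          function(keep) fit_fn(which(tr_rows)[keep]),
                          function(m, hold) pred_fn(m, which(tr_rows)[hold]), y[tr_rows])
    cmp_model <- fit_fn(tr_rows)
    cmp_pred <- pred_fn(cmp_model, te_rows)
    add_report(target, "comparison", "validation",
               data.frame(rmse = cmp_val, mape_percent = NA, r2 = NA, n_steps = sum(tr_rows)))
    add_report(target, "comparison", "test", evaluate_predictions(cmp_pred, y[te_rows]))
    add_by_speed(target, "comparison",
                 evaluate_by_speed(cmp_pred, y[te_rows], spd[te_rows], speed_groups))
    models[[target]]$comparison <- cmp_model

    mr_val <- loso_score(sub[tr_rows],
                         function(keep) mean_regressor(y[tr_rows][keep]),
                         function(m, hold) rep(m$mean, sum(hold)), y[tr_rows])
    mr <- mean_regressor(y[tr_rows])
    mr_pred <- predict(mr, data.frame(idx = which(te_rows)))
    add_report(target, "mean_regressor", "validation",
               data.frame(rmse = mr_val, mape_percent = NA, r2 = NA, n_steps = sum(tr_rows)))
    add_report(target, "mean_regressor", "test", evaluate_predictions(mr_pred, y[te_rows]))
    add_by_speed(target, "mean_regressor",
                 evaluate_by_speed(mr_pred, y[te_rows], spd[te_rows], speed_groups))
    models[[target]]$mean_regressor <- mr
  }

  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))
  by_speed <- do.call(rbind, c(by_speed, list(make.row.names = FALSE)))
  manifest <- list(seed = config$seed,
                   cohort = unclass(config$cohort),
                   counts = as.list(counts),
                   split = split,
                   selection = selection)
  run <- structure(list(report = report, by_speed = by_speed, manifest = manifest,
                        models = models,
                        data = list(steps = steps, targets = targets, est = est,
                                    features = feats, split = split)),
                   class = "vgrf_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write a pipeline run's reports
#'
#' @param run A `vgrf_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "vgrf_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$report, file.path(dir, "report.csv"), row.names = FALSE, na = "")
  utils::write.csv(run$by_speed, file.path(dir, "report_by_speed.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.vgrf_run <- function(x, ...) {
  cat("<vgrf_run>\n")
  cat(sprintf("  steps: %d retained (of %d matched)\n",
              x$manifest$counts$retained, x$manifest$counts$matched))
  cat(sprintf("  subjects: %d train / %d test\n",
              length(x$manifest$split$train), length(x$manifest$split$test)))
  te <- x$report[x$report$split == "test", c("characteristic", "model", "rmse", "mape_percent", "r2")]
  print(te, row.names = FALSE, digits = 4)
  invisible(x)
}
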
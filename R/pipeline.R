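# One-config orchestration of the full workflow: simulate -> preprocess ->
# latent factors -> selection + prediction -> bootstrap regression -> graph
# export, with a manifest recording seeds and output checksums so re-runs
# are bit-reproducible.

#' Build and validate a run configuration
#'
#' @param config A named list, or the path of a YAML/JSON file holding one.
#'   Recognized sections (all optional, defaults shown in the vignette):
#'   `cohort` (arguments of [cohort_spec()]), `corex` (`n_factors`, `bins`,
#'   `cardinality`, `restarts`), `selection` (`k`, `cv_repeats`, `cv_folds`),
#'   `prediction` (`n_splits`, `cv_repeats`, `cv_folds`, `grid`),
#'   `bootstrap` (`B`, `criterion`), `contrasts`, `outcomes`, `mode`, `seed`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  defaults <- list(
    cohort = list(),
    corex = list(n_factors = 25L, bins = 3L, cardinality = 2L, restarts = 5L),
    selection = list(k = 10L, cv_repeats = 10L, cv_folds = 10L),
    prediction = list(n_splits = 10L, cv_repeats = 10L, cv_folds = 10L),
    bootstrap = list(B = 1000L, criterion = "bic"),
    contrasts = 1:3,
    outcomes = c("cognitive_delta", "tbm_temporal", "tbm_ventricle"),
    mode = "paper-faithful",
    seed = 1L)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      for (sub in names(defaults[[nm]])) {
        if (is.null(config[[nm]][[sub]])) config[[nm]][[sub]] <- defaults[[nm]][[sub]]
      }
    }
  }
  if (!config$mode %in% c("paper-faithful", "split-safe")) {
    stop("mode must be 'paper-faithful' or 'split-safe'")
  }
  bad <- setdiff(config$outcomes, c("cognitive_delta", "tbm_temporal", "tbm_ventricle"))
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  if (!all(config$contrasts %in% 1:3)) stop("contrasts must be within 1..3")
  config$seed <- as.integer(config$seed)
  class(config) <- "run_config"
  config
}

write_num_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full pipeline from one configuration
#'
#' Executes every stage in order, writing plain-text outputs and a manifest
#' (seeds, configuration, and an MD5 checksum per output file) into
#' `output_dir`. Re-running with the same configuration reproduces every
#' output bit-identically.
#'
#' @param config A `run_config` (or anything [run_config()] accepts).
#' @param output_dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = run_config(), output_dir, force = FALSE) {
  config <- run_config(unclass(config))
  if (dir.exists(output_dir) && length(list.files(output_dir)) && !force) {
    stop("output directory is not empty; use force = TRUE")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- stage("simulate", {
    spec <- do.call(cohort_spec, c(config$cohort,
                                   if (is.null(config$cohort$seed)) list(seed = config$seed)))
    co <- generate_cohort(spec)
    write_cohort(co, file.path(output_dir, "cohort"), force = TRUE)
    co
  })

  pre <- stage("preprocess", {
    groups <- assign_groups(cohort$diagnoses)
    comp <- cognitive_composite(
      mmse = data.frame(baseline = cohort$outcomes$mmse_baseline,
                        followup = cohort$outcomes$mmse_followup),
      adas13 = data.frame(baseline = cohort$outcomes$adas13_baseline,
                          followup = cohort$outcomes$adas13_followup),
      cdr_sob = data.frame(baseline = cohort$outcomes$cdr_sob_baseline,
                           followup = cohort$outcomes$cdr_sob_followup))
    write_num_csv(as.data.frame(unclass(groups)), file.path(output_dir, "groups.csv"))
    write_num_csv(data.frame(subject = cohort$outcomes$subject,
                             baseline_z = comp$baseline_z,
                             followup_z = comp$followup_z,
                             delta = comp$delta),
                  file.path(output_dir, "composite.csv"))
    covars <- as.data.frame(ft_data(ft_select(cohort$features, tags = "demographic")))
    brain_res <- residualize(
      ft_select(cohort$features, tags = c("brain_thickness", "brain_area", "brain_volume")),
      covars)
    list(groups = groups, composite = comp, brain_res = brain_res)
  })

  cx <- stage("corex", {
    plasma_panel <- ft_select(cohort$features,
                              tags = c("plasma", "hallmark", "demographic"))
    dp_p <- discretize(plasma_panel, config$corex$bins)
    dp_b <- discretize(pre$brain_res, config$corex$bins)
    hp <- fit_hierarchy(dp_p, layer_sizes = config$corex$n_factors,
                        seed = config$seed,
                        cardinality = config$corex$cardinality,
                        restarts = config$corex$restarts)
    hb <- fit_hierarchy(dp_b, layer_sizes = config$corex$n_factors,
                        seed = config$seed + 1000L,
                        cardinality = config$corex$cardinality,
                        restarts = config$corex$restarts)
    lab_p <- factor_labels(hp$layers[[1]], panel = "plasma",
                           subjects = ft_subjects(plasma_panel))
    lab_b <- factor_labels(hb$layers[[1]], panel = "brain",
                           subjects = ft_subjects(pre$brain_res))
    corex_to_json(hp$layers[[1]], file.path(output_dir, "corex_plasma.json"))
    corex_to_json(hb$layers[[1]], file.path(output_dir, "corex_brain.json"))
    write_num_csv(data.frame(subject = ft_subjects(lab_p), ft_data(lab_p),
                             check.names = FALSE),
                  file.path(output_dir, "labels_plasma.csv"))
    write_num_csv(data.frame(subject = ft_subjects(lab_b), ft_data(lab_b),
                             check.names = FALSE),
                  file.path(output_dir, "labels_brain.csv"))
    list(plasma = hp, brain = hb, lab_p = lab_p, lab_b = lab_b,
         plasma_panel = plasma_panel)
  })

  pred <- stage("predict", {
    out <- list()
    grid <- if (is.null(config$prediction$grid)) default_gbm_grid() else
      do.call(expand.grid, config$prediction$grid)
    for (ct in config$contrasts) {
      res <- run_contrast(cohort, ct,
                          grid = grid,
                          n_factors = config$corex$n_factors,
                          n_bins = config$corex$bins,
                          cardinality = config$corex$cardinality,
                          restarts = config$corex$restarts,
                          k = config$selection$k,
                          selection_cv = c(config$selection$cv_repeats,
                                           config$selection$cv_folds),
                          gbm_cv = c(config$prediction$cv_repeats,
                                     config$prediction$cv_folds),
                          n_splits = config$prediction$n_splits,
                          mode = config$mode,
                          seed = config$seed + 17L * ct)
      out[[as.character(ct)]] <- res
    }
    metrics <- do.call(rbind, lapply(out, function(r) {
      cbind(contrast = r$contrast, r$metrics)
    }))
    write_num_csv(metrics, file.path(output_dir, "metrics.csv"))
    preds <- do.call(rbind, lapply(out, function(r) {
      do.call(rbind, lapply(r$splits, function(s) {
        cbind(contrast = r$contrast, split = s$split,
              feature_set = s$feature_set, s$result$predictions)
      }))
    }))
    write_num_csv(preds, file.path(output_dir, "predictions.csv"))
    out
  })

  boot <- stage("bootstrap", {
    panel <- ft_cbind(cx$plasma_panel, pre$brain_res, cx$lab_p, cx$lab_b)
    groups <- pre$groups
    out <- list()
    for (oc in config$outcomes) {
      y <- switch(oc,
                  cognitive_delta = pre$composite$delta,
                  tbm_temporal = cohort$outcomes$tbm_temporal,
                  tbm_ventricle = cohort$outcomes$tbm_ventricle)
      tags <- if (oc == "cognitive_delta") {
        c("plasma", "hallmark", "demographic", "brain_thickness", "brain_area",
          "brain_volume", "corex_plasma", "corex_brain")
      } else {
        # peripheral-only inputs for the atrophy outcomes
        c("plasma", "hallmark", "demographic", "corex_plasma")
      }
      X <- ft_select(panel, tags = tags)
      imp <- ensemble_importance(X, y, "regression", seed = config$seed,
                                 cv_repeats = config$selection$cv_repeats,
                                 cv_folds = config$selection$cv_folds)
      top <- top_k_per_class(imp, k = config$selection$k)
      rep <- bootstrap_stepwise(ft_select(X, features = top), y,
                                B = config$bootstrap$B,
                                seed = config$seed + 7L,
                                criterion = config$bootstrap$criterion)
      write_num_csv(as.data.frame(unclass(rep)),
                    file.path(output_dir, paste0("bootstrap_", oc, ".csv")))
      out[[oc]] <- rep
    }
    out
  })

  stage("export", {
    export_graph(cx$plasma, file.path(output_dir, "corex_plasma.graphml"),
                 classes = ft_classes(cx$plasma_panel))
    export_graph(cx$brain, file.path(output_dir, "corex_brain.graphml"),
                 classes = ft_classes(pre$brain_res))
  })

  manifest <- stage("manifest", {
    files <- sort(list.files(output_dir, recursive = TRUE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(output_dir, files))
    m <- list(config = unclass(config),
              seed = config$seed,
              package_version = as.character(utils::packageVersion("corexad")),
              checksums = as.list(stats::setNames(unname(sums), files)))
    jsonlite::write_json(m, file.path(output_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    m
  })

  invisible(list(cohort = cohort, preprocess = pre, corex = cx,
                 prediction = pred, bootstrap = boot, manifest = manifest))
}
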
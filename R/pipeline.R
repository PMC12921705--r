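# End-to-end orchestration: simulate (or load) a cohort, demonstrate the
# masking stage on a synthetic slide, run patient-level cross-validation,
# stratify, explain and write report CSVs, with a manifest recording the
# effective configuration, its hash, the seed and per-stage wall times.

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "gnnsurv-run",
    simulate = list(
      slides = list(enabled = TRUE, width = 768L, height = 768L,
                    n_blobs = 3L, speck_count = 6L),
      cohort = list(n_patients = 24L, slides_per_patient = c(1L, 2L),
                    nodes_per_graph = c(12L, 24L), feature_dim = 64L,
                    signal_dim_count = 8L, beta_true = 2,
                    baseline_rate = 0.008, censor_rate = 0.012)
    ),
    mask = list(median_kernel = 7L, close_kernel = 4L, min_area_px = 100L,
                min_hole_px = 16L, max_holes = 8L),
    model = list(arch = "gcn", pooling = "kde", hidden_dims = c(32L, 16L),
                 embed_dim = 16L, gat_heads = 4L, dropout = 0.25,
                 kde_grid = 8L),
    train = list(epochs = 60L, learning_rate = 1e-3, weight_decay = 1e-5),
    eval = list(n_folds = 4L, threshold = 0.9, horizon_months = 18),
    explain = list(enabled = TRUE, steps = 100L, sparsity_weight = 0.005,
                   entropy_weight = 0.1),
    log_level = "info"
  )
}

# recursive merge with unknown-key rejection
merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    key <- if (path == "") nm else paste(path, nm, sep = ".")
    if (!nm %in% names(base)) {
      gs_error(sprintf("unknown configuration key: %s", key), "configuration_error")
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]])) gs_error(sprintf("configuration key %s must be a section", key),
                                         "configuration_error")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], key)
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file (or takes a list) and merges it over the package
#' defaults; unknown keys are rejected by name so typos cannot silently
#' fall back to defaults. The merged configuration round-trips through
#' YAML unchanged.
#'
#' @param config path to a YAML file, or a (possibly partial) named list.
#' @return The complete configuration list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline
#'
#' Executes the stages in order — synthetic slide + masking demo, cohort
#' simulation, patient-level cross-validation with risk stratification,
#' explanation of the highest-risk slide graph, report CSVs — writing
#' per-stage artifacts and a `manifest.json` (package version, seed,
#' configuration hash, per-stage wall times) under `output_dir`. Any
#' stage failure moves the partial outputs to a `failed/` quarantine
#' directory and rethrows with the stage name.
#'
#' @param config a YAML path or list, see [load_run_config()].
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a list with the manifest and the main results.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  cfg <- load_run_config(config)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage_times <- list()
  current_stage <- "init"
  log_msg <- function(...) if (cfg$log_level != "quiet") message(sprintf(...))
  res <- tryCatch({
    timed <- function(stage, expr) {
      current_stage <<- stage
      t0 <- proc.time()[["elapsed"]]
      v <- force(expr)
      stage_times[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
      log_msg("stage %-12s done in %.2fs", stage, stage_times[[stage]])
      v
    }
    masking <- NULL
    if (isTRUE(cfg$simulate$slides$enabled)) {
      masking <- timed("mask", {
        sl <- simulate_slide(slide_sim_config(
          width = cfg$simulate$slides$width, height = cfg$simulate$slides$height,
          n_blobs = cfg$simulate$slides$n_blobs,
          speck_count = cfg$simulate$slides$speck_count,
          hole_spec = c(400, 9), seed = cfg$seed))
        mp <- mask_params(cfg$mask$median_kernel, cfg$mask$close_kernel,
                          cfg$mask$min_area_px, cfg$mask$min_hole_px,
                          cfg$mask$max_holes)
        tm <- compute_tissue_mask(sl$image, mp)
        write_image_png(sl$image, file.path(out, "slide.png"))
        write_image_png(tm$mask, file.path(out, "mask.png"))
        inter <- sum(tm$mask & sl$truth); uni <- sum(tm$mask | sl$truth)
        list(iou = inter / uni)
      })
    }
    cohort <- timed("simulate", {
      sc <- cfg$simulate$cohort
      simulate_cohort(cohort_sim_config(
        n_patients = sc$n_patients, slides_per_patient = sc$slides_per_patient,
        nodes_per_graph = sc$nodes_per_graph, feature_dim = sc$feature_dim,
        signal_dim_count = sc$signal_dim_count, beta_true = sc$beta_true,
        baseline_rate = sc$baseline_rate, censor_rate = sc$censor_rate,
        seed = cfg$seed))
    })
    write.csv(cohort$survival, file.path(out, "survival.csv"), row.names = FALSE)
    bcfg <- backbone_config(cfg$model$arch, cfg$model$hidden_dims,
                            cfg$model$embed_dim, cfg$model$gat_heads,
                            cfg$model$dropout, cfg$model$pooling,
                            cfg$model$kde_grid)
    tcfg <- train_config(cfg$train$epochs, cfg$train$learning_rate,
                         cfg$train$weight_decay, seed = cfg$seed)
    cv <- timed("evaluate", {
      cross_validate(cohort$graphs, cohort$survival, bcfg, tcfg,
                     n_folds = cfg$eval$n_folds, seed = cfg$seed,
                     threshold = cfg$eval$threshold,
                     horizon = cfg$eval$horizon_months)
    })
    strat <- timed("stratify", {
      df <- cv$patients[order(cv$patients$patient_id),
                        c("patient_id", "risk", "probability", "group")]
      names(df) <- c("patient_id", "risk_score",
                     sprintf("surv_prob_%gmo", cfg$eval$horizon_months),
                     "risk_group")
      write.csv(df, file.path(out, "stratification.csv"), row.names = FALSE)
      df
    })
    expl <- NULL
    if (isTRUE(cfg$explain$enabled)) {
      expl <- timed("explain", {
        fit <- gnnsurv(cohort$graphs, cohort$survival, bcfg, tcfg)
        top <- names(which.max(fit$slide_risks))
        g <- cohort$graphs[[which(vapply(cohort$graphs, function(x) x$slide_id,
                                         character(1)) == top)]]
        em <- explain_graph(fit, g, steps = cfg$explain$steps,
                            sparsity_weight = cfg$explain$sparsity_weight,
                            entropy_weight = cfg$explain$entropy_weight,
                            seed = cfg$seed)
        write.csv(data.frame(node = seq_along(em$node_importance),
                             x = em$coords[, 1], y = em$coords[, 2],
                             importance = em$node_importance),
                  file.path(out, "importance.csv"), row.names = FALSE)
        em
      })
    }
    report <- timed("report", {
      pat <- merge(unique(cohort$survival[, c("patient_id", "time_months", "event")]),
                   cv$patients[, c("patient_id", "group")], by = "patient_id")
      lr <- if (length(unique(pat$group)) == 2) {
        logrank_test(pat$time_months[pat$group == "high"],
                     pat$event[pat$group == "high"],
                     pat$time_months[pat$group == "low"],
                     pat$event[pat$group == "low"])
      } else list(statistic = NA_real_, p.value = NA_real_)
      ct <- if (length(unique(pat$group)) == 2) {
        cox_table(pat, "time_months", "event", "group")
      } else NULL
      if (!is.null(ct)) write.csv(ct, file.path(out, "cox_table.csv"),
                                  row.names = FALSE)
      metrics <- list(mean_cindex = cv$mean_cindex,
                      fold_cindex = cv$fold_cindex,
                      n_high = sum(pat$group == "high"),
                      n_low = sum(pat$group == "low"),
                      logrank_p = lr$p.value,
                      mask_iou = if (!is.null(masking)) masking$iou else NULL)
      jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      metrics
    })
    manifest <- list(package = "gnnsurv",
                     version = as.character(utils::packageVersion("gnnsurv")),
                     r_version = R.version.string,
                     seed = cfg$seed, config_hash = config_hash(cfg),
                     config = cfg, stage_seconds = stage_times)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(manifest = manifest, metrics = report, stratification = strat,
         cv = cv, masking = masking, explanation = expl)
  }, error = function(e) {
    qdir <- file.path(out, "failed")
    dir.create(qdir, showWarnings = FALSE, recursive = TRUE)
    for (f in setdiff(list.files(out), "failed")) {
      file.rename(file.path(out, f), file.path(qdir, f))
    }
    gs_error(sprintf("pipeline failed in stage '%s': %s", current_stage,
                     conditionMessage(e)), "pipeline_error")
  })
  invisible(res)
}
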
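STIM_COLS <- c("subject_id", "block_id", "trial_index", "base_rate",
               "coherence_signed", "duration_s")
BEHAV_COLS <- c("choice", "confidence_raw", "belief_report")

check_stimulus_columns <- function(df) {
  miss <- setdiff(c("block_id", "coherence_signed", "duration_s"),
                  names(df))
  if (length(miss)) {
    stop("missing stimulus column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Validate a trial table
#'
#' Schema checks with row-numbered errors: required stimulus columns,
#' coherence magnitudes in the task's six-value set, durations within the
#' stimulus range, 1-based contiguous trial indices within block, and (when
#' present) confidence in `[0.5, 1]` and belief in `[0, 1]`.
#'
#' @param df data.frame to validate.
#' @return the validated table (invisibly), classed `trial_table`.
#' @export
validate_trial_table <- function(df) {
  miss <- setdiff(STIM_COLS, names(df))
  if (length(miss)) {
    stop("validation error: missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop("validation error at row ", which(!ok)[1], ": ", what)
    }
  }
  bad_row(abs(df$coherence_signed) %in% COHERENCES |
            sapply(abs(df$coherence_signed),
                   function(x) any(abs(x - COHERENCES) < 1e-9)),
          "coherence magnitude not in the six-value set")
  bad_row(df$base_rate %in% BASE_RATES, "base rate not in the six-value set")
  bad_row(df$duration_s >= 0.1 - 1e-9 & df$duration_s <= 0.9 + 1e-9,
          "duration outside [0.1, 0.9] s")
  key <- paste(df$subject_id, df$block_id)
  idx_ok <- unlist(lapply(split(df$trial_index, factor(key, unique(key))),
                          function(ti) ti == seq_along(ti)),
                   use.names = FALSE)
  bad_row(idx_ok, "trial_index not contiguous and 1-based within block")
  if ("confidence_raw" %in% names(df)) {
    bad_row(is.na(df$confidence_raw) |
              (df$confidence_raw >= 0.5 & df$confidence_raw <= 1),
            "confidence_raw outside [0.5, 1]")
  }
  if ("belief_report" %in% names(df)) {
    bad_row(is.na(df$belief_report) |
              (df$belief_report >= 0 & df$belief_report <= 1),
            "belief_report outside [0, 1]")
  }
  if ("choice" %in% names(df)) {
    bad_row(df$choice %in% c("L", "R"), "choice not L/R")
  }
  class(df) <- unique(c("trial_table", class(df)))
  invisible(df)
}

#' Read / write tab-separated trial tables
#'
#' Tables are plain tab-separated text with a header; numeric columns are
#' written with 12 significant digits so that write-then-read round-trips.
#' Stimulus-only tables (no behaviour columns) are accepted.
#'
#' @param path file path.
#' @return `read_trial_table` returns a validated `trial_table`.
#' @export
read_trial_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_trial_table(df)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @rdname read_trial_table
#' @param table trial table to write.
#' @export
write_trial_table <- function(table, path) {
  validate_trial_table(as.data.frame(table))
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) {
    x <- out[[j]]
    out[[j]] <- ifelse(x == round(x), format(x, scientific = FALSE,
                                             trim = TRUE),
                       sprintf("%.12g", x))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    seed = 1L, n_blocks = 20L, subject_id = "s1",
    generator = list(kappa = 14, bound_A = 1.2, phi = 0.8, omega1 = 1,
                     omega2 = 0.5, model = "bayesian"),
    models = c("bayesian", "choice_only"),
    fit = list(n_starts = 3L, maxit = 150L),
    n_sim = 50L,
    analyses = c("choice_bias", "confidence_strength"),
    out_dir = NULL
  )
}

#' Run the full simulate -> fit -> predict -> evaluate pipeline
#'
#' Executes the pipeline stages on synthetic data (or a supplied data file),
#' writing all artifacts and a manifest (seeds, configuration hash, package
#' version, per-stage wall times, optimiser diagnostics) to a directory.
#' All randomness flows from the named seed; rerunning an identical
#' configuration reproduces identical numeric outputs.
#'
#' @param config named list overriding the pipeline defaults (`seed`,
#'   `n_blocks`, `generator` parameters, `models` to fit, `fit` optimiser
#'   settings, `n_sim` belief simulations, `analyses`, `out_dir`, or
#'   `data_file` to skip simulation), or a path to a JSON file holding one.
#' @return the manifest (invisibly); artifacts on disk under `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- modifyList(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) stop("configuration error: out_dir is required")
  if (!is.null(cfg$data_file) && !file.exists(cfg$data_file)) {
    stop("configuration error: data_file does not exist: ", cfg$data_file)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(config = cfg,
                   config_hash = unname(tools::md5sum(tf)),
                   package_version =
                     as.character(utils::packageVersion("priorlearn")),
                   stages = list())
  unlink(tf)
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     wall_s = proc.time()[["elapsed"]] - t0)
    res
  }

  data <- stage("simulate", {
    if (!is.null(cfg$data_file)) {
      read_trial_table(cfg$data_file)
    } else {
      design <- generate_experiment(cfg$n_blocks, cfg$seed, cfg$subject_id)
      gp <- do.call(observer_params, cfg$generator)
      ap <- accumulator_params(kappa = gp$kappa, bound_A = gp$bound_A)
      maps <- build_likelihood_maps(ap)
      d <- simulate_observer(design, gp, maps, seed = cfg$seed + 1L)
      write_trial_table(d, file.path(cfg$out_dir, "trials.tsv"))
      d
    }
  })
  fits <- stage("fit", {
    fl <- lapply(cfg$models, function(m) {
      do.call(fit_observer, c(list(data = data, model = m,
                                   seed = cfg$seed + 2L), cfg$fit))
    })
    names(fl) <- cfg$models
    for (m in names(fl)) {
      f <- fl[[m]]
      jsonlite::write_json(
        list(model = f$model, coefficients = as.list(f$coefficients),
             logLik = f$logLik, n_params = f$n_params, AIC = f$AIC,
             BIC = f$BIC, n_trials = f$n_trials,
             n_floor = f$diagnostics$n_floor,
             best_start = f$diagnostics$best_start),
        file.path(cfg$out_dir, paste0("fit_", m, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    manifest$log_floor_counts <-
      lapply(fl, function(f) f$diagnostics$n_floor)
    fl
  })
  stage("predict", {
    pred <- predict_beliefs(fits[[1]], n_sim = cfg$n_sim,
                            seed = cfg$seed + 3L)
    ends <- data.frame(block_id = pred$block_id,
                       predicted_end_belief = pred$end_mean)
    write.table(ends, file.path(cfg$out_dir, "predicted_beliefs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(fits) > 1) {
      cmp <- compare_models(fits)
      write.table(cmp, file.path(cfg$out_dir, "model_comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    NULL
  })
  stage("evaluate", {
    for (an in cfg$analyses) {
      reg <- run_regression(an, data)
      write.table(reg$coefficients,
                  file.path(cfg$out_dir, paste0(an, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    NULL
  })
  manifest$seeds <- list(task = cfg$seed, observer = cfg$seed + 1L,
                         fit = cfg$seed + 2L, predict = cfg$seed + 3L)
  write_manifest()
  invisible(manifest)
}
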
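# End-to-end orchestration: simulate -> score -> label -> (encode) -> train
# -> evaluate -> compare, driven by one configuration with a single global
# seed fanned out to per-stage sub-seeds.

#' Stack gait cycles into a signal array
#'
#' @param cycles List of [gait_cycle()] objects.
#' @return Numeric array `[B, 101, 9]`.
#' @export
cycles_to_array <- function(cycles) {
  out <- array(0, c(length(cycles), 101L, 9L))
  for (i in seq_along(cycles)) out[i, , ] <- unclass(cycles[[i]])
  out
}

# flatten a [B, 101, 9] batch time-major into [B, 909]
flatten_batch <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 3L, 2L))
  dim(m) <- c(d[1], d[2] * d[3])
  m
}

# centralized spectrum magnitudes of a [B, 101, 9] batch -> [B, 101, 9*tile, 1]
encode_batch_spectra <- function(x, tile = 1L) {
  B <- dim(x)[1]
  out <- array(0, c(B, 101L, 9L * tile, 1L))
  sr <- 101L %/% 2L; sc <- 9L %/% 2L
  ri <- ((seq_len(101L) - 1L - sr) %% 101L) + 1L
  ci <- ((seq_len(9L) - 1L - sc) %% 9L) + 1L
  for (b in seq_len(B)) {
    mag <- Mod(stats::fft(x[b, , ])) / (101 * 9)
    mag <- mag[ri, ci]
    if (tile > 1L) mag <- do.call(cbind, rep(list(mag), tile))
    out[b, , , 1L] <- mag
  }
  out
}

#' Fit a spectrum standardizer on training cycles
#'
#' Computes the mean and standard deviation of the centralized spectrum
#' magnitudes over the training set; the returned transform maps raw
#' `[B, 101, 9]` batches to standardized spectrum images for image models.
#'
#' @param x_train Training signal array `[B, 101, 9]`.
#' @param tile Width repetition factor.
#' @return Function(batch array) -> standardized `[B, 101, 9*tile, 1]` array.
#' @export
spectrum_transform <- function(x_train, tile = 1L) {
  sp <- encode_batch_spectra(x_train, tile)
  mu <- mean(sp)
  sd <- stats::sd(as.vector(sp))
  if (sd == 0) sd <- 1
  function(x) (encode_batch_spectra(x, tile) - mu) / sd
}

#' Input transform for a given architecture
#'
#' Maps raw `[B, 101, 9]` signal batches to the layout the named model
#' consumes: time-major flattening for the MLP, standardized centralized
#' spectrum images (fitted on `x_train`) for image models, and the identity
#' for native signal models (returned as `NULL`).
#'
#' @param model_name Architecture name as in [architecture_spec()].
#' @param x_train Training signal array used to fit the spectrum
#'   standardizer where needed.
#' @return A function, or `NULL` when no transform is needed.
#' @export
input_transform_for <- function(model_name, x_train) {
  if (model_name == "mlp_4_200") return(flatten_batch)
  if (model_name == "tailored_cnn") return(spectrum_transform(x_train, 1L))
  if (model_name %in% c("vgg16", "resnet34", "efficientnet_b0", "vit_b16")) {
    return(spectrum_transform(x_train, 4L))
  }
  NULL  # native [B, 101, 9] signal models
}

#' Pipeline configuration
#'
#' @param output_dir Run directory (created; reports and tables are written
#'   under it).
#' @param simulate A [cohort_config()] to generate the cohort, or `NULL` to
#'   read one from disk.
#' @param cohort_manifest,reference_path Paths used when `simulate` is NULL.
#' @param split_fractions Train/validation/test cycle fractions.
#' @param models Character vector of architecture names to train (from the
#'   trainable family: `"mlp_4_200"`, `"fcn"`, `"resnet1d"`, `"tlenet"`,
#'   `"tailored_cnn"`).
#' @param training A [training_config()] (its seed is overridden by the
#'   derived stage seed).
#' @param seed Global seed; per-stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            simulate = cohort_config(),
                            cohort_manifest = NULL,
                            reference_path = NULL,
                            split_fractions = c(0.73, 0.12, 0.14) / 0.99,
                            models = c("fcn", "tailored_cnn"),
                            training = training_config(max_epochs = 30L,
                                                       early_stopping_patience = 10L),
                            seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-8 || any(split_fractions <= 0)) {
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  }
  if (is.null(simulate) &&
      (is.null(cohort_manifest) || is.null(reference_path))) {
    stop("either simulate or cohort_manifest + reference_path required",
         call. = FALSE)
  }
  structure(list(output_dir = output_dir, simulate = simulate,
                 cohort_manifest = cohort_manifest,
                 reference_path = reference_path,
                 split_fractions = split_fractions, models = models,
                 training = training, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the [pipeline_config()] fields (blocks
#'   `simulate`, `training` map to [cohort_config()] / [training_config()]
#'   arguments).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(cohort_config, y$simulate) else NULL
  tr <- if (!is.null(y$training)) do.call(training_config, y$training) else
    training_config(max_epochs = 30L, early_stopping_patience = 10L)
  pipeline_config(
    output_dir = y$output_dir %||% stop("output_dir required"),
    simulate = sim,
    cohort_manifest = y$cohort_manifest,
    reference_path = y$reference_path,
    split_fractions = y$split_fractions %||% (c(0.73, 0.12, 0.14) / 0.99),
    models = y$models %||% c("fcn", "tailored_cnn"),
    training = tr,
    seed = y$seed %||% 1L)
}

#' Run the full prediction pipeline
#'
#' Executes: cohort simulation (or loading), per-cycle GPS scoring,
#' consecutive-pair labeling with a patient-level split, model training with
#' early stopping, evaluation on the held-out test patients, and a DeLong
#' comparison of the first two models. Every stage writes its artifact into
#' the run directory; re-running with the same configuration reproduces all
#' reports.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the run directory, the labeled table, and
#'   per-model evaluation reports.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[gaitcast] ", ...)
  run_dir <- config$output_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- local_rng(config$seed)

  # --- simulate / load -------------------------------------------------------
  if (!is.null(config$simulate)) {
    say("simulate: ", config$simulate$n_patients, " patients")
    sim_cfg <- config$simulate
    sim_cfg$seed <- seeds$derive("simulate")
    gen <- generate_cohort(sim_cfg)
    cohort <- gen$cohort; ref <- gen$reference
    write_cohort(cohort, file.path(run_dir, "cohort"))
    write_reference(ref, file.path(run_dir, "reference.csv"))
    utils::write.csv(gen$truth, file.path(run_dir, "truth.csv"),
                     row.names = FALSE)
  } else {
    say("load cohort: ", config$cohort_manifest)
    cohort <- read_cohort(config$cohort_manifest)
    ref <- read_reference(config$reference_path)
  }

  # --- score -----------------------------------------------------------------
  say("score: per-cycle GPS/GVS")
  scores <- score_cohort(cohort, ref)
  utils::write.csv(scores, file.path(run_dir, "scores.csv"), row.names = FALSE)

  # --- label + split ---------------------------------------------------------
  say("label: consecutive equipment-free pairs")
  labeled <- build_labeled_dataset(cohort, ref)
  if (!nrow(labeled$table)) stop("labeling produced no examples", call. = FALSE)
  split <- split_by_patient(labeled, config$split_fractions,
                            seed = seeds$derive("split"))
  labeled$table$split <- unname(split[labeled$table$patient_id])
  utils::write.csv(labeled$table, file.path(run_dir, "labeled.csv"),
                   row.names = FALSE)

  x_all <- cycles_to_array(labeled$cycles)
  y_all <- labeled$table$label
  in_split <- function(s) labeled$table$split == s
  x_train <- x_all[in_split("train"), , , drop = FALSE]
  y_train <- y_all[in_split("train")]
  x_val <- x_all[in_split("validation"), , , drop = FALSE]
  y_val <- y_all[in_split("validation")]
  x_test <- x_all[in_split("test"), , , drop = FALSE]
  y_test <- y_all[in_split("test")]

  # --- train / evaluate ------------------------------------------------------
  reports <- list()
  for (nm in config$models) {
    say("train: ", nm)
    tr_cfg <- config$training
    tr_cfg$seed <- seeds$derive(paste0("train_", nm))
    model <- if (nm %in% SIGNAL_MODELS) build_signal_model(nm, seed = tr_cfg$seed)
      else build_image_model(nm, seed = tr_cfg$seed)
    if (!inherits(model, "nn_model")) {
      stop("model '", nm, "' is not trainable in this pipeline", call. = FALSE)
    }
    tf <- input_transform_for(nm, x_train)
    fit <- train_model(model, x_train, y_train, x_val, y_val, tr_cfg,
                       transform_fn = tf)
    ev <- evaluate_model(fit$model, x_test, y_test, transform_fn = tf)
    report <- list(model = nm,
                   epoch_of_convergence = fit$epoch_of_convergence,
                   val_auc = fit$val_auc,
                   test_auc = ev$auc,
                   test_accuracy = ev$accuracy)
    jsonlite::write_json(report, file.path(run_dir, paste0("report_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(fit$history, file.path(run_dir, paste0("history_", nm, ".json")),
                         dataframe = "rows", digits = NA)
    utils::write.csv(ev$roc, file.path(run_dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
    reports[[nm]] <- c(report, list(scores = ev$scores))
    say(sprintf("  %s: val AUC %.3f, test AUC %.3f", nm,
                fit$val_auc, ev$auc))
  }

  # --- compare ---------------------------------------------------------------
  if (length(reports) >= 2L) {
    a <- names(reports)[1]; b <- names(reports)[2]
    dl <- delong_test(y_test, reports[[a]]$scores, reports[[b]]$scores)
    jsonlite::write_json(list(model_a = a, model_b = b,
                              auc_a = dl$auc_a, auc_b = dl$auc_b,
                              z = dl$z_statistic, p_value = dl$p_value),
                         file.path(run_dir, "compare.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(run_dir = run_dir, labeled = labeled$table,
                 reports = reports))
}
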
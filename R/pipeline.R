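#' @title End-to-end experiment orchestration
#' @description
#' Thin orchestration over the package's stages: generate a synthetic
#' dataset, run the feasibility statistics, train/evaluate the CNN over
#' wavelength sets, and run the piecewise selection — each writing CSV
#' artifacts and an append-only JSON-lines log into a self-describing run
#' directory that embeds the resolved configuration and seeds.
#' @name pipeline
NULL

#' Experiment configuration
#'
#' @param generator a [generator_spec()].
#' @param task `"classification"` or `"regression"`.
#' @param epochs,conv1_filters,conv2_filters CNN training scale.
#' @param include_rgb selection mode (RGB permanent member).
#' @param max_cardinality selection stop size (default: full set).
#' @param t_v_list,t_nv_list Bhattacharyya thresholds for the feasibility
#'   grid.
#' @param bins histogram bins.
#' @param normalize apply shot intensity normalization.
#' @param seed global experiment seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(generator = generator_spec(),
                              task = "classification",
                              epochs = 30L, conv1_filters = 8L,
                              conv2_filters = 16L, include_rgb = TRUE,
                              max_cardinality = NULL,
                              t_v_list = seq(0.2, 0.6, by = 0.1),
                              t_nv_list = seq(0.1, 0.9, by = 0.1),
                              bins = 256L, normalize = FALSE, seed = 1L) {
  task <- match.arg(task, c("classification", "regression"))
  structure(list(generator = generator, task = task,
                 epochs = as.integer(epochs),
                 conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 include_rgb = include_rgb,
                 max_cardinality = max_cardinality,
                 t_v_list = t_v_list, t_nv_list = t_nv_list,
                 bins = as.integer(bins), normalize = normalize,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Serialize / restore an experiment configuration as YAML
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `write_experiment_config` returns `path`;
#'   `read_experiment_config` the restored config.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$generator <- unclass(x$generator)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  gen <- x$generator
  gen$confusable_pairs <- lapply(gen$confusable_pairs, as.integer)
  x$generator <- do.call(generator_spec, gen)
  do.call(experiment_config, x)
}

log_jsonl <- function(run_dir, event, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = file.path(run_dir, "log.jsonl"), append = TRUE)
}

init_run_dir <- function(run_dir, config, force = FALSE) {
  if (dir.exists(run_dir) && length(dir(run_dir)) && !force) {
    stop("run directory exists and is not empty (use force = TRUE): ",
         run_dir)
  }
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  write_experiment_config(config, file.path(run_dir, "config.yaml"))
  invisible(run_dir)
}

#' Generate a dataset for an experiment
#'
#' @param config an [experiment_config()].
#' @param out_dir dataset directory.
#' @param force overwrite an existing non-empty directory.
#' @return the manifest (see [generate_dataset()]).
#' @export
run_generate <- function(config, out_dir, force = FALSE) {
  init_run_dir(out_dir, config, force = force)
  manifest <- generate_dataset(config$generator, out_dir, force = TRUE)
  log_jsonl(out_dir, "generate", n_shots = nrow(manifest),
            n_classes = config$generator$n_classes,
            n_views = config$generator$n_views,
            seed = config$generator$seed)
  manifest
}

#' Feasibility statistics of a dataset
#'
#' Computes the pairwise Bhattacharyya distance table, the grid of
#' cumulative ratios over the configured thresholds, the per-wavelength
#' correlation profile and the visible/non-visible band comparison, and
#' writes each as CSV into `run_dir`. Threshold cells with an empty
#' denominator are reported as NA, not zero.
#'
#' @param stacks list of `ms_stack` with masks and calorie labels (e.g.
#'   from [generate_stacks()] or [read_stack()] over a manifest).
#' @param config an [experiment_config()].
#' @param run_dir output directory for CSV artifacts (optional).
#' @return list with `distances`, `fc_grid`, `profile`, `band_comparison`.
#' @export
run_feasibility <- function(stacks, config = experiment_config(),
                            run_dir = NULL) {
  has_mask <- vapply(stacks, function(s) {
    all(vapply(s$shots, function(sh) !is.null(sh$mask), TRUE))
  }, TRUE)
  if (!all(has_mask)) stop("feasibility statistics require masks on every shot")
  table <- pairwise_distance_table(stacks, bins = config$bins)
  fc <- cumulative_ratio_grid(table, config$t_v_list, config$t_nv_list)
  profile <- correlation_profile(table)
  cmp <- compare_band_correlations(profile)
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(run_dir, "pairwise_distances.csv"),
                     row.names = FALSE)
    utils::write.csv(fc, file.path(run_dir, "fc_grid.csv"),
                     row.names = FALSE)
    utils::write.csv(profile, file.path(run_dir, "correlation_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cmp[c("mean_v", "mean_nv", "p_value")]),
                     file.path(run_dir, "band_comparison.csv"),
                     row.names = FALSE)
    log_jsonl(run_dir, "feasibility", n_pairs = attr(profile, "n_pairs"),
              mean_v = cmp$mean_v, mean_nv = cmp$mean_nv,
              p_value = cmp$p_value)
  }
  list(distances = table, fc_grid = fc, profile = profile,
       band_comparison = cmp)
}

#' Train and evaluate the CNN over wavelength sets
#'
#' For each requested set: assemble inputs, train the task's CNN and
#' evaluate it on the validation split, producing the
#' accuracy/MAPE-versus-image-count curve (RGB counts as one image).
#'
#' @param stacks list of `ms_stack`.
#' @param sets list of character vectors of wavelength labels.
#' @param config an [experiment_config()].
#' @param run_dir optional output directory for CSV artifacts.
#' @return list with `curve` (data.frame: set, n_images, metric value,
#'   val_loss) and `reports` (one `eval_report` per set).
#' @export
run_experiment <- function(stacks, sets, config = experiment_config(),
                           run_dir = NULL) {
  present <- names(stacks[[1]]$shots)
  reports <- list()
  rows <- list()
  for (s in sets) {
    missing <- setdiff(s, present)
    if (length(missing)) {
      stop("wavelength(s) absent from dataset: ",
           paste(missing, collapse = ", "))
    }
    ds <- assemble_dataset(stacks, s, task = config$task,
                           normalize = config$normalize)
    cfg <- cnn_config(task = config$task,
                      n_targets = if (config$task == "regression") 1L
                                  else ds$n_classes,
                      input_channels = dim(ds$train$x)[3],
                      epochs = config$epochs,
                      conv1_filters = config$conv1_filters,
                      conv2_filters = config$conv2_filters,
                      seed = mix_seed(config$seed,
                                      string_seed(set_key(s))))
    model <- train_cnn(build_model(cfg), ds$train, ds$val)
    rep <- evaluate_cnn(model, ds$val$x, ds$val$y)
    key <- set_key(s)
    reports[[key]] <- rep
    rows[[key]] <- data.frame(
      set = key, n_images = ds$n_images,
      metric = if (config$task == "classification") "accuracy" else "mape",
      value = if (config$task == "classification") rep$accuracy else rep$mape,
      val_loss = utils::tail(model$trace$val_loss, 1),
      stringsAsFactors = FALSE)
    if (!is.null(run_dir)) {
      log_jsonl(run_dir, "experiment_set", set = key,
                value = rows[[key]]$value, val_loss = rows[[key]]$val_loss)
    }
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(curve, file.path(run_dir, "experiment_curve.csv"),
                     row.names = FALSE)
  }
  list(curve = curve, reports = reports)
}

#' Run the piecewise wavelength selection on a dataset
#'
#' @param stacks list of `ms_stack`.
#' @param omega_full wavelength labels to search over (default: all
#'   present in the dataset).
#' @param config an [experiment_config()].
#' @param run_dir optional output directory for CSV artifacts.
#' @return the [run_selection()] result, with a `rates` element from
#'   [selection_rate_summary()].
#' @export
run_select <- function(stacks, omega_full = NULL,
                       config = experiment_config(), run_dir = NULL) {
  if (is.null(omega_full)) omega_full <- names(stacks[[1]]$shots)
  loss_fn <- make_cnn_loss(
    stacks, task = config$task,
    config_fn = selection_cnn_config(config$task, epochs = config$epochs,
                                     conv1_filters = config$conv1_filters,
                                     conv2_filters = config$conv2_filters),
    seed = config$seed, normalize = config$normalize)
  max_card <- if (is.null(config$max_cardinality)) length(omega_full)
              else config$max_cardinality
  result <- run_selection(omega_full, loss_fn,
                          include_rgb = config$include_rgb,
                          max_cardinality = max_card)
  result$rates <- selection_rate_summary(result)
  if (!is.null(run_dir)) {
    dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(result$per_cardinality,
                     file.path(run_dir, "selection_per_cardinality.csv"),
                     row.names = FALSE)
    utils::write.csv(result$trace,
                     file.path(run_dir, "selection_trace.csv"),
                     row.names = FALSE)
    utils::write.csv(result$rates$frequency,
                     file.path(run_dir, "selection_rates.csv"),
                     row.names = FALSE)
    log_jsonl(run_dir, "select",
              optimum = paste(result$optimum, collapse = "+"),
              loss = result$optimum_loss, seed = config$seed)
  }
  result
}

#' Summary statistics of the packaged food table
#'
#' @param source food table CSV (default: the packaged 101-item fixture).
#' @param json print the summary as JSON instead of text.
#' @return the [summarize_food_table()] list, invisibly; prints a summary.
#' @export
table_stats <- function(source = food_table_fixture(), json = FALSE) {
  s <- summarize_food_table(load_food_table(source))
  if (json) {
    cat(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA), "\n")
  } else {
    cat(sprintf("items: %d (missing calorie: %d)\n", s$n_items,
                s$n_missing_calorie))
    cat(sprintf("weight  (g):    mean %.2f  sd %.2f\n", s$mean_weight_g,
                s$std_weight_g))
    cat(sprintf("calorie (kcal): mean %.2f  sd %.2f\n",
                s$mean_calorie_kcal, s$std_calorie_kcal))
  }
  invisible(s)
}

#' Plot a feasibility cumulative-ratio grid
#'
#' One curve of `F_C(T_V, T_NV)` against `T_NV` per `T_V` value, the
#' analogue of the feasibility study's cumulative-distribution figure.
#'
#' @param fc_grid data.frame from [cumulative_ratio_grid()].
#' @param path optional PNG path; when given the plot is written there.
#' @return invisibly, the grid.
#' @export
plot_fc_grid <- function(fc_grid, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 500)
    on.exit(grDevices::dev.off())
  }
  tvs <- sort(unique(fc_grid$t_v))
  cols <- grDevices::hcl.colors(length(tvs), "Dark 2")
  graphics::plot(NULL, xlim = range(fc_grid$t_nv), ylim = c(0, 1),
                 xlab = "T_NV", ylab = "F_C(T_V, T_NV)",
                 main = "Pairs separable only outside the visible band")
  for (i in seq_along(tvs)) {
    sub <- fc_grid[fc_grid$t_v == tvs[i], ]
    graphics::lines(sub$t_nv, sub$f_c, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = sprintf("T_V = %.2f", tvs),
                   col = cols, lwd = 2, bty = "n")
  invisible(fc_grid)
}
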
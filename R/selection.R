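#' @title Piecewise wavelength-subset selection
#' @description
#' Wrapper-style subset search over wavelength labels driven by a loss
#' callback (in practice: train the CNN on the candidate set's assembled
#' inputs and return its final validation loss). Each iteration adds the
#' best wavelength (forward selection), removes the least useful member
#' (backward elimination), then adds again (final forward selection),
#' until the working set equals the full set; the best set at each
#' cardinality is recorded and the global optimum is the minimum-loss
#' end-of-iteration set. Ties are broken deterministically: RGB first,
#' then the smallest center wavelength.
#' @name wavelength_selection
NULL

# Order candidate labels for deterministic tie-breaking.
tie_order <- function(candidates) {
  wl <- wavelength_table()
  known <- candidates %in% wl$name
  if (all(known)) {
    order_wavelengths(candidates)
  } else {
    sort(candidates)  # mock label sets in tests
  }
}

set_key <- function(s) {
  if (!length(s)) return("<empty>")
  known <- s %in% wavelength_table()$name
  if (all(known)) wavelength_set_key(s) else paste(sort(s), collapse = "+")
}

#' Memoize a selection loss function
#'
#' Wraps a loss callback so each canonical wavelength set is evaluated
#' once; every evaluation (cached or not) is recorded for audit.
#'
#' @param loss_fn function(character vector of labels) -> scalar loss.
#' @return a memoized function with attributes accessible via
#'   [loss_evaluations()].
#' @export
memoize_loss <- function(loss_fn) {
  force(loss_fn)
  cache <- new.env(parent = emptyenv())
  log <- new.env(parent = emptyenv())
  log$rows <- list()
  f <- function(s) {
    key <- set_key(s)
    hit <- !is.null(cache[[key]])
    if (!hit) cache[[key]] <- loss_fn(s)
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(set = key, size = length(s), loss = cache[[key]],
                 cached = hit, stringsAsFactors = FALSE)
    cache[[key]]
  }
  attr(f, "log") <- log
  f
}

#' Evaluations recorded by a memoized loss
#' @param loss_fn a function from [memoize_loss()].
#' @return data.frame (set, size, loss, cached), one row per call.
#' @export
loss_evaluations <- function(loss_fn) {
  log <- attr(loss_fn, "log")
  if (is.null(log)) stop("loss_fn was not created by memoize_loss()")
  do.call(rbind, log$rows)
}

eval_candidates <- function(sets, labels, loss_fn) {
  losses <- vapply(seq_along(sets), function(i) loss_fn(sets[[i]]), 1.0)
  ord <- tie_order(labels)
  pick <- ord[which.min(losses[match(ord, labels)])]
  list(pick = pick, loss = losses[match(pick, labels)], losses = losses)
}

#' Forward selection step
#'
#' Evaluates `omega_prev` augmented by each wavelength of the complement
#' and returns the augmentation minimizing the loss.
#'
#' @param omega_prev current set (character vector; may be empty).
#' @param omega_full full wavelength set.
#' @param loss_fn loss callback (ideally from [memoize_loss()]).
#' @return list with `added`, `set` (the augmented set) and `loss`.
#' @export
forward_step <- function(omega_prev, omega_full, loss_fn) {
  comp <- setdiff(omega_full, omega_prev)
  if (!length(comp)) stop("forward step: the complement is empty")
  res <- eval_candidates(lapply(comp, function(w) union(omega_prev, w)),
                         comp, loss_fn)
  list(added = res$pick, set = union(omega_prev, res$pick), loss = res$loss)
}

#' Backward elimination step
#'
#' Removes the member whose removal minimizes the loss. With
#' `include_rgb = TRUE`, RGB is a permanent member and never removable.
#'
#' @param omega_f the set after forward selection.
#' @param loss_fn loss callback.
#' @param include_rgb protect RGB from elimination.
#' @return list with `removed`, `set` (the reduced set) and `loss`.
#' @export
backward_step <- function(omega_f, loss_fn, include_rgb = FALSE) {
  removable <- if (include_rgb) setdiff(omega_f, "RGB") else omega_f
  if (!length(removable)) stop("backward step: nothing removable")
  res <- eval_candidates(lapply(removable, function(w) setdiff(omega_f, w)),
                         removable, loss_fn)
  list(removed = res$pick, set = setdiff(omega_f, res$pick), loss = res$loss)
}

#' Final forward selection step
#'
#' Adds the best wavelength from the complement of the backward-reduced
#' set; the just-removed wavelength is eligible for re-addition.
#'
#' @param omega_b the set after backward elimination.
#' @inheritParams forward_step
#' @return list with `added`, `set` and `loss`.
#' @export
final_forward_step <- function(omega_b, omega_full, loss_fn) {
  forward_step(omega_b, omega_full, loss_fn)
}

#' Run the piecewise wavelength selection
#'
#' @param omega_full character vector of available wavelength labels
#'   (at least 2).
#' @param loss_fn function(set) -> scalar loss; wrapped by
#'   [memoize_loss()] automatically.
#' @param include_rgb seed the working set with RGB and never remove it
#'   (`omega_full` must then contain `"RGB"`).
#' @param max_cardinality stop once the working set reaches this size
#'   (default: the full set).
#' @return object of class `selection_result`: list with
#'   `per_cardinality` (data.frame: size, set, loss), `optimum` (set),
#'   `optimum_loss`, `trace` (every evaluated candidate) and `steps`
#'   (per-iteration added/removed wavelengths).
#' @export
run_selection <- function(omega_full, loss_fn, include_rgb = FALSE,
                          max_cardinality = length(omega_full)) {
  omega_full <- unique(as.character(omega_full))
  if (length(omega_full) < 2) stop("need at least 2 wavelengths")
  if (include_rgb && !"RGB" %in% omega_full) {
    stop("include_rgb = TRUE requires RGB in omega_full")
  }
  loss_fn <- memoize_loss(loss_fn)
  current <- if (include_rgb) "RGB" else character(0)
  records <- list()
  steps <- list()
  if (include_rgb) {
    records[[1]] <- data.frame(size = 1L, set = set_key(current),
                               loss = loss_fn(current))
  }
  i <- 0L
  while (length(current) < min(max_cardinality, length(omega_full))) {
    i <- i + 1L
    fw <- forward_step(current, omega_full, loss_fn)
    step <- list(iteration = i, forward_added = fw$added,
                 backward_removed = NA_character_,
                 final_added = NA_character_)
    if (setequal(fw$set, omega_full) ||
        length(if (include_rgb) setdiff(fw$set, "RGB") else fw$set) <= 1) {
      # nothing useful to swap: the set is complete, or backward would
      # have to evaluate an empty (untrainable) set
      current <- fw$set
      loss_i <- fw$loss
    } else {
      bw <- backward_step(fw$set, loss_fn, include_rgb = include_rgb)
      ff <- final_forward_step(bw$set, omega_full, loss_fn)
      step$backward_removed <- bw$removed
      step$final_added <- ff$added
      current <- ff$set
      loss_i <- ff$loss
    }
    steps[[i]] <- as.data.frame(step)
    records[[length(records) + 1L]] <-
      data.frame(size = length(current), set = set_key(current),
                 loss = loss_i)
  }
  per_card <- do.call(rbind, records)
  best <- which.min(per_card$loss)
  structure(list(per_cardinality = per_card,
                 optimum = strsplit(per_card$set[best], "+", fixed = TRUE)[[1]],
                 optimum_loss = per_card$loss[best],
                 trace = loss_evaluations(loss_fn),
                 steps = do.call(rbind, steps),
                 include_rgb = include_rgb),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("piecewise wavelength selection\n")
  print(x$per_cardinality, row.names = FALSE)
  cat(sprintf("optimum: {%s}, loss %.4g\n",
              paste(x$optimum, collapse = ", "), x$optimum_loss))
  invisible(x)
}

#' Selection-rate summary across selection results
#'
#' Frequency with which each wavelength appears among the per-cardinality
#' best sets, and the share of selected narrow-band slots falling in each
#' band (UV/VIS/NIR), across one or more runs.
#'
#' @param results a `selection_result` or list of them.
#' @param max_images restrict to per-cardinality sets with at most this
#'   many captured images (RGB counts as one).
#' @return list with `frequency` (data.frame: wavelength, band, count,
#'   rate over sets), `band_share` (named vector over UV/VIS/NIR, as a
#'   percentage of narrow-band slots), `n_sets`, `n_slots`.
#' @export
selection_rate_summary <- function(results, max_images = Inf) {
  if (inherits(results, "selection_result")) results <- list(results)
  stopifnot(length(results) >= 1)
  sets <- list()
  for (r in results) {
    for (s in r$per_cardinality$set) {
      labels <- strsplit(s, "+", fixed = TRUE)[[1]]
      if (count_images(labels)$n_images <= max_images) {
        sets[[length(sets) + 1L]] <- labels
      }
    }
  }
  all_lab <- unlist(sets)
  wl <- wavelength_table()
  counts <- table(factor(all_lab, levels = wl$name))
  freq <- data.frame(wavelength = wl$name, band = wl$band,
                     count = as.integer(counts),
                     rate = as.integer(counts) / length(sets),
                     stringsAsFactors = FALSE)
  nb <- freq[freq$band != "RGB", ]
  share <- tapply(nb$count, nb$band, sum)[c("UV", "VIS", "NIR")]
  share[is.na(share)] <- 0
  names(share) <- c("UV", "VIS", "NIR")
  total_nb <- sum(share)
  list(frequency = freq,
       band_share = if (total_nb > 0) 100 * share / total_nb else share * 0,
       n_sets = length(sets), n_slots = length(all_lab))
}

#' CNN-based selection loss for a dataset
#'
#' Builds the loss callback the piecewise selection drives: for a
#' candidate wavelength set, assemble inputs restricted to that set, train
#' the task's CNN, and return its final validation loss (cross-entropy for
#' classification, MAPE for regression). Each set trains with a seed
#' derived from `(global seed, canonical set key)`, so losses are
#' comparable, cacheable and reproducible.
#'
#' @param stacks list of `ms_stack` with train/val split tags.
#' @param task `"classification"` or `"regression"`.
#' @param config_fn function(n_channels, n_targets, seed) returning a
#'   [cnn_config()];
#'   see [selection_cnn_config()] for a convenient default.
#' @param seed global selection seed.
#' @param size,normalize passed to [assemble_dataset()].
#' @return function(character vector of labels) -> validation loss, with
#'   the trained models' traces discarded.
#' @export
make_cnn_loss <- function(stacks, task = "classification",
                          config_fn = selection_cnn_config(task),
                          seed = 1L, size = 64L, normalize = FALSE) {
  force(stacks); force(task); force(config_fn); force(seed)
  function(selected) {
    if (!length(selected)) stop("cannot train on an empty wavelength set")
    ds <- assemble_dataset(stacks, selected, task = task, size = size,
                           normalize = normalize)
    cfg <- config_fn(n_channels = dim(ds$train$x)[3],
                     n_targets = if (task == "regression") 1L else ds$n_classes,
                     seed = mix_seed(seed, string_seed(set_key(selected))))
    model <- train_cnn(build_model(cfg), ds$train, ds$val)
    utils::tail(model$trace$val_loss, 1)
  }
}

#' Desk-scale CNN configuration factory for selection runs
#'
#' @param task `"classification"` or `"regression"`.
#' @param epochs,conv1_filters,conv2_filters training scale knobs.
#' @return function(n_channels, n_targets, seed) -> [cnn_config()].
#' @export
selection_cnn_config <- function(task, epochs = 30L,
                                 conv1_filters = 8L, conv2_filters = 16L) {
  function(n_channels, n_targets, seed) {
    cnn_config(task = task, n_targets = n_targets,
               input_channels = n_channels, epochs = epochs,
               conv1_filters = conv1_filters,
               conv2_filters = conv2_filters, seed = seed)
  }
}
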
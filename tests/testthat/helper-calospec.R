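# Shared helpers: tiny fixtures and independent brute-force oracles.

# A masked shot with given in-mask values (row-major fill of a square grid).
tiny_shot <- function(values, wavelength = "890", side = NULL) {
  n <- length(values)
  if (is.null(side)) side <- ceiling(sqrt(n))
  px <- matrix(0, side, side)
  mask <- matrix(FALSE, side, side)
  px[seq_len(n)] <- values
  mask[seq_len(n)] <- TRUE
  ms_shot(px, wavelength, mask = mask)
}

# Histogram object straight from a probability vector.
hist_from_probs <- function(probs) {
  structure(list(probs = probs / sum(probs),
                 breaks = seq(0, 65536, length.out = length(probs) + 1L),
                 bins = length(probs), n_pixels = NA_integer_),
            class = "brightness_histogram")
}

# Independent oracle: Bhattacharyya distance by direct summation.
brute_bhattacharyya <- function(p, q) {
  bc <- 0
  for (i in seq_along(p)) bc <- bc + sqrt(p[i] * q[i])
  if (bc <= 0) Inf else -log(bc)
}

# Independent oracle: F_C by explicit pair counting.
brute_fc <- function(d_v, d_nv, t_v, t_nv) {
  num <- 0; den <- 0
  for (i in seq_along(d_v)) {
    if (d_v[i] < t_v) {
      den <- den + 1
      if (d_nv[i] > t_nv) num <- num + 1
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Independent oracle: Pearson correlation from first principles.
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exhaustive argmin oracle for one selection step: among candidate sets
# (list of label vectors, one per candidate label), pick the label whose
# set has minimal loss, ties broken by sorted label order.
brute_step_argmin <- function(cand_labels, cand_sets, loss_fn) {
  losses <- vapply(cand_sets, loss_fn, 1.0)
  ord <- sort(cand_labels)
  best <- Inf; pick <- NULL
  for (lab in ord) {
    l <- losses[match(lab, cand_labels)]
    if (l < best) { best <- l; pick <- lab }
  }
  pick
}

# Small generator spec used across tests (fast to render).
tiny_spec <- function(n_classes = 4L, n_views = 4L, ..., seed = 5L) {
  generator_spec(n_classes = n_classes, n_views = n_views,
                 image_size = c(64L, 64L),
                 confusable_pairs = list(c(0L, 1L)), seed = seed, ...)
}

# Environment-backed random mock loss over label subsets, fixed once
# populated; empty sets use a sentinel key.
subset_key <- function(s) if (length(s)) paste(sort(s), collapse = "+") else "<empty>"
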
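#' Masked brightness histogram of a shot
#'
#' The distribution of brightness values inside the food mask, on `bins`
#' equal-width bins over the 16-bit range `[0, 65535]`. For RGB shots the
#' three planes are pooled. The non-food portion is excluded entirely.
#'
#' @param shot an [ms_shot()] with a non-empty mask.
#' @param bins number of bins (default 256).
#' @param smooth pseudo-count added to every bin before normalization
#'   (0 = raw histogram). A half count (Jeffreys) keeps Bhattacharyya
#'   distances finite when supports would otherwise be disjoint.
#' @return object of class `brightness_histogram`: list with `probs`
#'   (sums to 1), `breaks`, `bins` and `n_pixels`.
#' @export
masked_histogram <- function(shot, bins = 256L, smooth = 0) {
  stopifnot(inherits(shot, "ms_shot"))
  if (is.null(shot$mask)) stop("shot has no mask")
  if (!any(shot$mask)) stop("shot mask is empty")
  px <- shot$pixels
  vals <- if (length(dim(px)) == 3) {
    c(px[, , 1][shot$mask], px[, , 2][shot$mask], px[, , 3][shot$mask])
  } else px[shot$mask]
  histogram_from_values(vals, bins, smooth)
}

#' Brightness histogram from raw pixel values
#'
#' @param vals numeric vector of intensities in `[0, 65535]`.
#' @inheritParams masked_histogram
#' @return a `brightness_histogram`.
#' @export
histogram_from_values <- function(vals, bins = 256L, smooth = 0) {
  bins <- as.integer(bins)
  stopifnot(bins >= 2, all(vals >= 0), all(vals <= 65535), smooth >= 0)
  idx <- pmin(bins, floor(vals / 65536 * bins) + 1L)
  counts <- tabulate(idx, nbins = bins) + smooth
  structure(list(probs = counts / sum(counts),
                 breaks = seq(0, 65536, length.out = bins + 1L),
                 bins = bins, n_pixels = length(vals)),
            class = "brightness_histogram")
}

#' Pooled masked histogram over several shots
#'
#' Pools the in-mask pixel values of all shots (e.g. all views of one item
#' at one wavelength) into a single histogram, used as the item's
#' representative brightness distribution.
#'
#' @param shots list of [ms_shot()] with masks, same wavelength.
#' @param bins number of bins.
#' @inheritParams masked_histogram
#' @return a `brightness_histogram`.
#' @export
pooled_histogram <- function(shots, bins = 256L, smooth = 0) {
  vals <- unlist(lapply(shots, function(s) {
    if (is.null(s$mask) || !any(s$mask)) stop("shot has no usable mask")
    px <- s$pixels
    if (length(dim(px)) == 3) {
      c(px[, , 1][s$mask], px[, , 2][s$mask], px[, , 3][s$mask])
    } else px[s$mask]
  }))
  histogram_from_values(vals, bins, smooth)
}

#' Bhattacharyya distance between two brightness histograms
#'
#' `D_B = -log(sum(sqrt(p * q)))` with the natural logarithm: 0 for
#' bin-wise identical histograms, growing with dissimilarity, and `Inf`
#' when the supports are disjoint. With `clamp = TRUE` the bounded variant
#' `1 - sum(sqrt(p * q))` (one minus the Bhattacharyya coefficient, in
#' `[0, 1]`) is returned instead.
#'
#' @param p,q `brightness_histogram` objects on the same binning.
#' @param clamp return the bounded `[0, 1]` variant.
#' @return non-negative scalar.
#' @examples
#' h1 <- histogram_from_values(c(0, 0, 40000), bins = 2)
#' h2 <- histogram_from_values(c(0, 40000, 40000), bins = 2)
#' bhattacharyya_distance(h1, h2)
#' @export
bhattacharyya_distance <- function(p, q, clamp = FALSE) {
  stopifnot(inherits(p, "brightness_histogram"),
            inherits(q, "brightness_histogram"))
  if (p$bins != q$bins) {
    stop("histograms use different binnings (", p$bins, " vs ", q$bins, ")")
  }
  bc <- sum(sqrt(p$probs * q$probs))
  if (clamp) return(max(0, 1 - bc))
  if (bc <= 0) return(Inf)
  max(0, -log(bc))
}

#' Pairwise Bhattacharyya distance table for a dataset
#'
#' For every unordered pair of distinct items and every wavelength,
#' computes the Bhattacharyya distance between the items' representative
#' (view-pooled) masked histograms.
#'
#' @param stacks list of `ms_stack` (e.g. from [generate_stacks()]); all
#'   stacks must carry masks.
#' @param wavelengths wavelength labels to include (default: those present
#'   in the first stack).
#' @param bins histogram bins.
#' @param smooth per-bin pseudo-count (default a Jeffreys half count),
#'   which regularizes empty-bin artifacts at desk-scale pixel counts and
#'   keeps every pairwise distance finite.
#' @param clamp see [bhattacharyya_distance()].
#' @return object of class `pairwise_distance_table`: a data.frame with
#'   columns `item_m`, `item_n`, `wavelength`, `d_b`, plus attributes
#'   `items` (per-item labels) and `bins`.
#' @export
pairwise_distance_table <- function(stacks, wavelengths = NULL,
                                    bins = 256L, smooth = 0.5,
                                    clamp = FALSE) {
  stopifnot(length(stacks) >= 2)
  if (is.null(wavelengths)) wavelengths <- names(stacks[[1]]$shots)
  ids <- vapply(stacks, function(s) s$item_id, 1L)
  items <- sort(unique(ids))
  if (length(items) < 2) stop("need at least two distinct items")
  hists <- lapply(items, function(it) {
    per_item <- stacks[ids == it]
    lapply(stats::setNames(wavelengths, wavelengths), function(w) {
      pooled_histogram(lapply(per_item, function(s) {
        if (is.null(s$shots[[w]])) stop("stack lacks wavelength ", w)
        s$shots[[w]]
      }), bins = bins, smooth = smooth)
    })
  })
  names(hists) <- items
  pairs <- utils::combn(items, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    m <- pairs[1, j]; n <- pairs[2, j]
    for (w in wavelengths) {
      rows[[length(rows) + 1L]] <- data.frame(
        item_m = m, item_n = n, wavelength = w,
        d_b = bhattacharyya_distance(hists[[as.character(m)]][[w]],
                                     hists[[as.character(n)]][[w]],
                                     clamp = clamp),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  lab <- unique(data.frame(
    item_id = ids,
    calorie_kcal = vapply(stacks, function(s) s$calorie_kcal, 1.0),
    class_index = vapply(stacks, function(s) s$class_index, 1L)))
  attr(out, "items") <- lab[order(lab$item_id), ]
  attr(out, "bins") <- bins
  class(out) <- c("pairwise_distance_table", "data.frame")
  out
}

#' Band-representative distance of one pair
#'
#' The representative distance of a band is the maximum Bhattacharyya
#' distance over the band's wavelengths.
#'
#' @param table a [pairwise_distance_table()].
#' @param pair integer vector `c(m, n)` of item ids.
#' @param band_set character vector of wavelength labels forming the band.
#' @return the maximum `d_b` over `band_set` for that pair.
#' @export
band_representative_distance <- function(table, pair, band_set) {
  m <- min(pair); n <- max(pair)
  rows <- table[table$item_m == m & table$item_n == n, , drop = FALSE]
  i <- match(band_set, rows$wavelength)
  if (anyNA(i)) {
    stop("pair (", m, ",", n, ") has no entry for wavelength(s): ",
         paste(band_set[is.na(i)], collapse = ", "))
  }
  max(rows$d_b[i])
}

# Per-pair band maxima D_B(V), D_B(NV); the visible band is the nine
# 430-660 nm channels, the non-visible band the UV + NIR channels.
band_maxima <- function(table) {
  vis <- intersect(band_wavelengths("VIS"), unique(table$wavelength))
  nv <- intersect(band_wavelengths("NV"), unique(table$wavelength))
  if (!length(vis) || !length(nv)) {
    stop("table must contain at least one VIS and one non-visible wavelength")
  }
  pairs <- unique(table[, c("item_m", "item_n")])
  pairs$d_b_v <- mapply(function(m, n) {
    band_representative_distance(table, c(m, n), vis)
  }, pairs$item_m, pairs$item_n)
  pairs$d_b_nv <- mapply(function(m, n) {
    band_representative_distance(table, c(m, n), nv)
  }, pairs$item_m, pairs$item_n)
  pairs
}

#' Cumulative ratio of pairs distinguishable only outside the visible band
#'
#' Among item pairs whose visible-band representative distance falls below
#' `t_v` (visually similar pairs), the fraction whose non-visible-band
#' representative distance exceeds `t_nv`:
#' `F_C = |{pairs: D_B(V) < T_V and D_B(NV) > T_NV}| / |{pairs: D_B(V) < T_V}|`.
#'
#' @param table a [pairwise_distance_table()] covering VIS and UV/NIR
#'   wavelengths.
#' @param t_v,t_nv Bhattacharyya-distance thresholds for the visible and
#'   non-visible bands.
#' @return scalar in `[0, 1]`. An empty denominator (no pair is visually
#'   similar at `t_v`) is an error, not 0.
#' @export
cumulative_ratio <- function(table, t_v, t_nv) {
  bm <- band_maxima(table)
  denom <- bm$d_b_v < t_v
  if (!any(denom)) {
    stop("no pair has visible-band distance below t_v = ", t_v,
         "; F_C is undefined")
  }
  sum(denom & bm$d_b_nv > t_nv) / sum(denom)
}

#' Grid of cumulative ratios over threshold lists
#'
#' @inheritParams cumulative_ratio
#' @param t_v_list,t_nv_list threshold vectors.
#' @return data.frame with columns `t_v`, `t_nv`, `f_c` (NA where the
#'   denominator set is empty) and `n_pairs` (denominator size).
#' @export
cumulative_ratio_grid <- function(table, t_v_list, t_nv_list) {
  bm <- band_maxima(table)
  grid <- expand.grid(t_v = t_v_list, t_nv = t_nv_list,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_pairs <- vapply(grid$t_v, function(tv) sum(bm$d_b_v < tv), 1L)
  grid$f_c <- mapply(function(tv, tnv) {
    d <- bm$d_b_v < tv
    if (!any(d)) NA_real_ else sum(d & bm$d_b_nv > tnv) / sum(d)
  }, grid$t_v, grid$t_nv)
  grid
}

#' Absolute relative caloric difference
#'
#' `D_C = |c_n - c_m| / (c_n + c_m)`, in `[0, 1]`.
#'
#' @param c_n,c_m calories (kcal) of the two items; their sum must be
#'   positive.
#' @return scalar in `[0, 1]`.
#' @examples
#' caloric_difference(18.56, 55.74)
#' @export
caloric_difference <- function(c_n, c_m) {
  stopifnot(c_n >= 0, c_m >= 0)
  if (c_n + c_m <= 0) stop("caloric difference undefined when both calories are zero")
  abs(c_n - c_m) / (c_n + c_m)
}

#' Pearson correlation between image distances and caloric differences
#'
#' @param d_b Bhattacharyya distances at one wavelength across item pairs.
#' @param d_c caloric differences for the same pairs.
#' @return Pearson correlation coefficient.
#' @export
wavelength_correlation <- function(d_b, d_c) {
  stopifnot(length(d_b) == length(d_c))
  if (length(d_b) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(d_b)) || any(!is.finite(d_c))) {
    stop("non-finite distances; compute the distance table with histogram ",
         "smoothing (smooth > 0) to keep disjoint-support pairs finite")
  }
  if (stats::sd(d_b) == 0 || stats::sd(d_c) == 0) {
    stop("correlation undefined: zero variance")
  }
  stats::cor(d_b, d_c)
}

#' Per-wavelength correlation profile of a dataset
#'
#' For each wavelength, the Pearson correlation across item pairs between
#' the Bhattacharyya distance at that wavelength and the absolute relative
#' caloric difference. Pairs involving an item with a missing calorie are
#' excluded; pairs where both calories are zero are excluded.
#'
#' @param table a [pairwise_distance_table()].
#' @return object of class `correlation_profile`: data.frame with columns
#'   `wavelength`, `band`, `rho` and attribute `n_pairs`.
#' @export
correlation_profile <- function(table) {
  items <- attr(table, "items")
  cal <- stats::setNames(items$calorie_kcal, items$item_id)
  pairs <- unique(table[, c("item_m", "item_n")])
  keep <- !is.na(cal[as.character(pairs$item_m)]) &
    !is.na(cal[as.character(pairs$item_n)]) &
    (cal[as.character(pairs$item_m)] + cal[as.character(pairs$item_n)]) > 0
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 3) stop("need at least 3 pairs with usable calories")
  d_c <- mapply(function(m, n) {
    caloric_difference(cal[[as.character(n)]], cal[[as.character(m)]])
  }, pairs$item_m, pairs$item_n)
  wls <- unique(table$wavelength)
  rho <- vapply(wls, function(w) {
    sub <- table[table$wavelength == w, , drop = FALSE]
    key <- paste(sub$item_m, sub$item_n)
    d_b <- sub$d_b[match(paste(pairs$item_m, pairs$item_n), key)]
    wavelength_correlation(d_b, d_c)
  }, 1.0)
  out <- data.frame(wavelength = wls, band = wavelength_band(wls),
                    rho = unname(rho), stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- nrow(pairs)
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Compare visible and non-visible band correlations
#'
#' Band means of the per-wavelength correlations, and a two-sided p-value
#' from a two-sample t-test on Fisher-z transformed correlations, testing
#' whether the visible and non-visible (UV + NIR) bands are equally
#' informative about caloric differences.
#'
#' @param profile a [correlation_profile()] (RGB entries are ignored).
#' @return list with `mean_v`, `mean_nv`, `p_value`, `method`.
#' @export
compare_band_correlations <- function(profile) {
  v <- profile$rho[profile$band == "VIS"]
  nv <- profile$rho[profile$band %in% c("UV", "NIR")]
  if (length(v) < 2 || length(nv) < 2) {
    stop("need at least 2 wavelengths per band")
  }
  zt <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  zv <- zt(v); znv <- zt(nv)
  p <- if (stats::sd(zv) == 0 && stats::sd(znv) == 0) {
    # degenerate limit of the t-test: constant samples
    if (isTRUE(all.equal(mean(zv), mean(znv)))) 1.0 else 0.0
  } else {
    stats::t.test(zv, znv)$p.value
  }
  list(mean_v = mean(v), mean_nv = mean(nv), p_value = p,
       method = "two-sample t-test on Fisher-z transformed correlations")
}
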
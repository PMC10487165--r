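#' Reference intensity for one wavelength
#'
#' The reference intensity is obtained by averaging the mean intensity of a
#' large number of shots of one wavelength taken at different times; each
#' shot's mean is taken over the full frame.
#'
#' @param shots list of [ms_shot()] of one wavelength.
#' @return scalar reference intensity (16-bit scale).
#' @export
compute_reference <- function(shots) {
  if (length(shots) == 0) stop("need at least one shot to compute a reference")
  mean(vapply(shots, function(s) mean(s$pixels), 1.0))
}

#' Build a per-wavelength normalization reference from stacks
#'
#' @param stacks list of `ms_stack`.
#' @param wavelengths labels to include (default: those in the first stack).
#' @return named numeric vector of reference intensities per wavelength.
#' @export
normalization_reference <- function(stacks, wavelengths = NULL) {
  if (is.null(wavelengths)) wavelengths <- names(stacks[[1]]$shots)
  mu <- vapply(wavelengths, function(w) {
    compute_reference(lapply(stacks, function(s) {
      if (is.null(s$shots[[w]])) stop("stack lacks wavelength ", w)
      s$shots[[w]]
    }))
  }, 1.0)
  if (any(mu <= 0)) stop("reference intensities must be positive")
  mu
}

#' Normalize a shot's intensity to a reference
#'
#' Compensates shot-to-shot illumination drift: the scale factor is
#' `alpha = mean(shot) / mu_ref` and every pixel is divided by `alpha`, so
#' the output mean equals `mu_ref` (before clipping to the 16-bit range).
#' Normalizing an already-normalized shot is the identity (`alpha = 1`).
#'
#' @param shot an [ms_shot()] with positive mean intensity.
#' @param mu_ref reference intensity for the shot's wavelength.
#' @return the normalized [ms_shot()] (pixels are real-valued).
#' @export
normalize_shot <- function(shot, mu_ref) {
  stopifnot(inherits(shot, "ms_shot"), mu_ref > 0)
  mu <- mean(shot$pixels)
  if (mu <= 0) stop("cannot normalize a zero-mean shot")
  alpha <- mu / mu_ref
  out <- shot
  out$pixels[] <- pmin(65535, pmax(0, shot$pixels / alpha))
  out
}

#' Resize an image to the network input size
#'
#' Bilinear interpolation over the full frame; no cropping, so a 640 x 480
#' acquisition maps to 64 x 64 without preserving aspect ratio. Constant
#' images stay constant.
#'
#' @param x numeric matrix (H x W) or H x W x 3 array, H and W >= `size`.
#' @param size output side length (default 64).
#' @return `size` x `size` matrix (or `size` x `size` x 3 array).
#' @export
resize_to_input <- function(x, size = 64L) {
  d <- dim(x)
  if (d[1] < size || d[2] < size) {
    stop("image (", d[1], "x", d[2], ") is smaller than the target size ", size)
  }
  if (length(d) == 3) {
    out <- array(0, c(size, size, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- resize_to_input(x[, , k], size)
    return(out)
  }
  EBImage::resize(x, w = size, h = size, filter = "bilinear")
}

#' Split an RGB shot into its three planes
#'
#' @param shot an [ms_shot()] with wavelength `"RGB"`.
#' @return list of three H x W matrices in R, G, B order.
#' @export
split_rgb <- function(shot) {
  stopifnot(inherits(shot, "ms_shot"))
  if (length(dim(shot$pixels)) != 3) {
    stop("split_rgb requires a 3-plane RGB shot")
  }
  list(R = shot$pixels[, , 1], G = shot$pixels[, , 2], B = shot$pixels[, , 3])
}

#' Assemble a network input from a stack
#'
#' Selected channels are (optionally) intensity-normalized, resized to
#' `size` x `size` by bilinear interpolation, rescaled to `[0, 1]`, and
#' stacked in canonical order: the three RGB planes first when RGB is
#' selected, then narrow-band channels by ascending wavelength. The
#' reported image count treats the RGB shot as one image; the channel
#' count treats it as three.
#'
#' @param stack an `ms_stack` containing every selected wavelength.
#' @param selected character vector of wavelength labels.
#' @param size spatial input size (default 64).
#' @param reference optional named vector from [normalization_reference()];
#'   when supplied each shot is normalized before resizing.
#' @return object of class `input_stack`: list with `channels`
#'   (`size` x `size` x C array in `[0, 1]`), `channel_map` (data.frame of
#'   wavelength/plane per channel), `n_images`, `class_index`,
#'   `calorie_kcal`, `split`.
#' @export
assemble_input <- function(stack, selected, size = 64L, reference = NULL) {
  stopifnot(inherits(stack, "ms_stack"))
  selected <- order_wavelengths(selected)
  missing <- setdiff(selected, names(stack$shots))
  if (length(missing)) {
    stop("stack lacks selected wavelength(s): ",
         paste(missing, collapse = ", "))
  }
  planes <- list()
  map <- list()
  for (w in selected) {
    shot <- stack$shots[[w]]
    if (!is.null(reference)) {
      if (is.na(reference[w])) stop("no reference intensity for ", w)
      shot <- normalize_shot(shot, reference[[w]])
    }
    if (w == "RGB") {
      rgb <- split_rgb(shot)
      for (pl in c("R", "G", "B")) {
        planes[[length(planes) + 1L]] <- resize_to_input(rgb[[pl]], size)
        map[[length(map) + 1L]] <- data.frame(wavelength = "RGB", plane = pl)
      }
    } else {
      planes[[length(planes) + 1L]] <- resize_to_input(shot$pixels, size)
      map[[length(map) + 1L]] <- data.frame(wavelength = w, plane = "I")
    }
  }
  channels <- array(unlist(planes), c(size, size, length(planes))) / 65535
  channels[] <- pmin(1, pmax(0, channels))
  structure(list(channels = channels,
                 channel_map = do.call(rbind, map),
                 n_images = count_images(selected)$n_images,
                 class_index = stack$class_index,
                 calorie_kcal = stack$calorie_kcal,
                 split = stack$split),
            class = "input_stack")
}

#' Replace zero calorie labels by the labelling minimum
#'
#' A printed zero in a nutrition table means "below the labelling minimum",
#' not a true zero, and the percentage-error loss is undefined at zero
#' truth; exact zeros are therefore replaced by 5 kcal before training.
#'
#' @param labels numeric vector of non-negative calorie labels.
#' @param minimum replacement value (default 5 kcal).
#' @return the labels with exact zeros replaced.
#' @export
replace_zero_calories <- function(labels, minimum = 5) {
  if (any(labels < 0, na.rm = TRUE)) stop("calorie labels must be non-negative")
  labels[!is.na(labels) & labels == 0] <- minimum
  labels
}

#' Assemble a train/validation dataset for the network
#'
#' @param stacks list of `ms_stack`.
#' @param selected wavelength labels to use as channels.
#' @param task `"classification"` (labels = class indices) or
#'   `"regression"` (labels = calories, zeros replaced).
#' @inheritParams assemble_input
#' @param normalize compute a per-wavelength reference from the training
#'   stacks and normalize every shot to it.
#' @return list with `train` and `val`, each a list with `x`
#'   (`size` x `size` x C x N array) and `y`; plus `channel_map`,
#'   `n_images`, `n_classes`.
#' @export
assemble_dataset <- function(stacks, selected, task = "classification",
                             size = 64L, normalize = FALSE) {
  task <- match.arg(task, c("classification", "regression"))
  splits <- vapply(stacks, function(s) s$split, "")
  reference <- if (normalize) {
    normalization_reference(stacks[splits == "train"],
                            order_wavelengths(selected))
  }
  inputs <- lapply(stacks, assemble_input, selected = selected, size = size,
                   reference = reference)
  n_classes <- length(unique(vapply(stacks, function(s) s$class_index, 1L)))
  pack <- function(keep) {
    xs <- inputs[keep]
    if (!length(xs)) stop("empty split")
    x <- array(unlist(lapply(xs, `[[`, "channels")),
               c(dim(xs[[1]]$channels), length(xs)))
    y <- if (task == "classification") {
      vapply(xs, `[[`, 1L, "class_index")
    } else {
      replace_zero_calories(vapply(xs, `[[`, 1.0, "calorie_kcal"))
    }
    list(x = x, y = y)
  }
  list(train = pack(splits == "train"), val = pack(splits == "val"),
       channel_map = inputs[[1]]$channel_map,
       n_images = inputs[[1]]$n_images, n_classes = n_classes)
}
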
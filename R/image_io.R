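#' Construct a multispectral image shot
#'
#' One captured frame: a 16-bit grayscale image for a narrow-band channel
#' or a 3-plane image for the white/RGB shot, with acquisition identity and
#' an optional food mask.
#'
#' @param pixels numeric matrix (H x W) or 3-d array (H x W x 3 for RGB)
#'   of intensities in `[0, 65535]`.
#' @param wavelength wavelength label (see [wavelength_table()]).
#' @param item_id,view_index,camera_index integers identifying the shot.
#' @param mask optional logical/0-1 matrix of the same H x W marking the
#'   food region.
#' @return object of class `ms_shot`.
#' @export
ms_shot <- function(pixels, wavelength, item_id = 1L, view_index = 0L,
                    camera_index = 0L, mask = NULL) {
  wavelength <- as.character(wavelength)
  band <- wavelength_band(wavelength)
  if (wavelength == "RGB") {
    if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
      stop("RGB shot requires an H x W x 3 pixel array")
    }
  } else if (length(dim(pixels)) != 2) {
    stop("narrow-band shot requires an H x W pixel matrix")
  }
  if (min(pixels) < 0 || max(pixels) > 65535) {
    stop("pixel intensities must lie in the 16-bit range [0, 65535]")
  }
  hw <- dim(pixels)[1:2]
  if (!is.null(mask)) {
    mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
    if (!identical(dim(mask), as.integer(hw))) {
      stop("mask dimensions must equal the image dimensions")
    }
  }
  structure(list(pixels = pixels, wavelength = wavelength, band = band,
                 item_id = as.integer(item_id),
                 view_index = as.integer(view_index),
                 camera_index = as.integer(camera_index),
                 mask = mask),
            class = "ms_shot")
}

#' @export
print.ms_shot <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ms_shot: item %d view %d cam %d, wavelength %s (%s), %dx%d%s%s\n",
              x$item_id, x$view_index, x$camera_index, x$wavelength, x$band,
              d[1], d[2], if (length(d) == 3) " x3" else "",
              if (is.null(x$mask)) "" else ", masked"))
  invisible(x)
}

#' Write a shot as a 16-bit TIFF
#'
#' Pixels are stored losslessly as unsigned 16-bit samples (one sample for
#' narrow-band shots, three for RGB). Fractional intensities are rounded.
#'
#' @param shot an [ms_shot()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shot <- function(shot, path) {
  stopifnot(inherits(shot, "ms_shot"))
  px <- round(shot$pixels)
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = TRUE)
  invisible(path)
}

#' Read a 16-bit TIFF shot
#'
#' @param path TIFF file path (16 bits per sample; 1 or 3 samples).
#' @param wavelength wavelength label to attach; `"RGB"` required for
#'   3-sample files.
#' @inheritParams ms_shot
#' @param mask_path optional path of a companion mask TIFF (non-zero =
#'   food). By default a file named `<path minus extension>_mask.tif` is
#'   used when it exists.
#' @return an [ms_shot()].
#' @export
read_shot <- function(path, wavelength, item_id = 1L, view_index = 0L,
                      camera_index = 0L, mask_path = NULL) {
  info <- tryCatch(tiff::readTIFF(path, payload = FALSE),
                   error = function(e) stop("not a readable TIFF: ", path))
  if (!identical(as.integer(info$bits.per.sample), 16L)) {
    stop("expected 16 bits per sample, got ", info$bits.per.sample,
         " in ", path)
  }
  # 16-bit samples come back as [0,1] floats; round(x * 65535) is exact
  px <- round(tiff::readTIFF(path) * 65535)
  if (is.null(mask_path)) {
    cand <- paste0(tools::file_path_sans_ext(path), "_mask.tif")
    if (file.exists(cand)) mask_path <- cand
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- tiff::readTIFF(mask_path) > 0
  }
  ms_shot(px, wavelength, item_id, view_index, camera_index, mask)
}

manifest_columns <- c("path", "item_id", "class_index", "view_index",
                      "camera_index", "wavelength", "weight_g",
                      "calorie_kcal", "split", "mask_path")

#' Read and validate a dataset manifest
#'
#' A manifest indexes every shot of a dataset: one CSV row per image file
#' with acquisition identity, labels and train/validation split tag. Paths
#' are relative to the manifest's directory. `mask_path` may be empty for
#' shots without a mask.
#'
#' @param path manifest CSV path.
#' @param check_files verify that every referenced image file exists.
#' @return data.frame of validated manifest rows (class `ms_manifest`),
#'   with attribute `root` holding the manifest directory.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(manifest_columns, "mask_path"), names(d))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.null(d$mask_path)) d$mask_path <- NA_character_
  root <- dirname(normalizePath(path))
  validate_manifest(d, root, check_files = check_files)
  attr(d, "root") <- root
  class(d) <- c("ms_manifest", "data.frame")
  d
}

validate_manifest <- function(d, root, check_files = TRUE) {
  key <- paste(d$item_id, d$view_index, d$wavelength, d$camera_index)
  if (anyDuplicated(key)) {
    stop("duplicate (item, view, wavelength, camera) manifest entries: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  wavelength_band(d$wavelength)  # validates labels
  if (any(d$weight_g <= 0)) stop("manifest has non-positive weights")
  if (check_files) {
    p <- file.path(root, d$path)
    missing <- p[!file.exists(p)]
    if (length(missing)) {
      stop("manifest references missing file(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Write a dataset manifest
#'
#' @param rows data.frame of manifest rows (see [read_manifest()] for the
#'   column set; `mask_path` is optional).
#' @param path output CSV path; image paths in `rows` must be relative to
#'   its directory.
#' @param check_files verify referenced files exist before writing.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(rows, path, check_files = TRUE) {
  rows <- as.data.frame(rows)
  if (is.null(rows$mask_path)) rows$mask_path <- NA_character_
  rows <- rows[, manifest_columns]
  validate_manifest(rows, dirname(path), check_files = check_files)
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load all shots of one (item, view) from a manifest
#'
#' @param manifest an `ms_manifest` from [read_manifest()].
#' @param item_id,view_index identity of the stack.
#' @return object of class `ms_stack`: list with `item_id`, `view_index`,
#'   `weight_g`, `calorie_kcal`, `class_index`, `split` and `shots`, a
#'   named list of [ms_shot()] keyed by wavelength label.
#' @export
read_stack <- function(manifest, item_id, view_index) {
  root <- attr(manifest, "root")
  rows <- manifest[manifest$item_id == item_id &
                     manifest$view_index == view_index, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no manifest rows for item ", item_id, " view ", view_index)
  }
  shots <- lapply(seq_len(nrow(rows)), function(i) {
    mp <- rows$mask_path[i]
    mp <- if (is.na(mp) || mp == "") NULL else file.path(root, mp)
    read_shot(file.path(root, rows$path[i]), rows$wavelength[i],
              rows$item_id[i], rows$view_index[i], rows$camera_index[i],
              mask_path = mp)
  })
  names(shots) <- rows$wavelength
  ms_stack(shots, weight_g = rows$weight_g[1],
           calorie_kcal = rows$calorie_kcal[1],
           class_index = rows$class_index[1], split = rows$split[1])
}

#' Bundle shots of one (item, view) into a stack
#'
#' @param shots named list of [ms_shot()] keyed by wavelength label, all
#'   sharing item/view identity and image size.
#' @param weight_g,calorie_kcal,class_index,split labels carried with the
#'   stack.
#' @return object of class `ms_stack`.
#' @export
ms_stack <- function(shots, weight_g = NA_real_, calorie_kcal = NA_real_,
                     class_index = NA_integer_, split = NA_character_) {
  stopifnot(length(shots) >= 1, all(vapply(shots, inherits, TRUE, "ms_shot")))
  ids <- vapply(shots, function(s) s$item_id, 1L)
  views <- vapply(shots, function(s) s$view_index, 1L)
  if (length(unique(ids)) != 1 || length(unique(views)) != 1) {
    stop("all shots in a stack must share item and view identity")
  }
  hw <- lapply(shots, function(s) dim(s$pixels)[1:2])
  if (length(unique(vapply(hw, paste, "", collapse = "x"))) != 1) {
    stop("all shots in a stack must share image dimensions")
  }
  names(shots) <- vapply(shots, function(s) s$wavelength, "")
  structure(list(item_id = ids[[1]], view_index = views[[1]],
                 weight_g = weight_g, calorie_kcal = calorie_kcal,
                 class_index = as.integer(class_index), split = split,
                 shots = shots),
            class = "ms_stack")
}
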
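#' Wavelength labels of the multispectral acquisition rig
#'
#' The imaging system uses 19 narrow-band LED light sources plus one white
#' shot from which an RGB image is obtained. Each narrow-band channel is
#' labelled by its LED center wavelength in nanometres. Band membership
#' follows the counting used throughout the selection-rate analyses:
#' the white LED spans roughly 430--640 nm, so 385 and 405 nm count as UV,
#' 430--660 nm as VIS (9 wavelengths) and 810--1020 nm as NIR
#' (8 wavelengths).
#'
#' @return A data.frame with one row per label and columns `name`
#'   (character, `"385"` ... `"1020"` and `"RGB"`), `nm` (numeric center
#'   wavelength, `NA` for RGB) and `band` (one of `"UV"`, `"VIS"`, `"NIR"`,
#'   `"RGB"`).
#' @examples
#' wl <- wavelength_table()
#' table(wl$band)
#' @export
wavelength_table <- function() {
  nm <- c(385, 405, 430, 470, 490, 510, 560, 590, 625, 645, 660,
          810, 850, 870, 890, 910, 950, 970, 1020)
  band <- ifelse(nm < 430, "UV", ifelse(nm <= 660, "VIS", "NIR"))
  data.frame(
    name = c(as.character(nm), "RGB"),
    nm = c(nm, NA_real_),
    band = c(band, "RGB"),
    stringsAsFactors = FALSE
  )
}

#' Band of one or more wavelength labels
#'
#' @param name character vector of wavelength labels (e.g. `"890"`, `"RGB"`).
#' @return character vector of bands (`"UV"`, `"VIS"`, `"NIR"`, `"RGB"`).
#' @export
wavelength_band <- function(name) {
  wl <- wavelength_table()
  i <- match(as.character(name), wl$name)
  if (anyNA(i)) {
    stop("unknown wavelength label(s): ",
         paste(unique(name[is.na(i)]), collapse = ", "))
  }
  wl$band[i]
}

#' Wavelength labels belonging to a band
#'
#' @param band one of `"UV"`, `"VIS"`, `"NIR"`, `"RGB"`, or `"NV"` for the
#'   non-visible union UV + NIR.
#' @return character vector of labels.
#' @export
band_wavelengths <- function(band = c("UV", "VIS", "NIR", "RGB", "NV")) {
  band <- match.arg(band)
  wl <- wavelength_table()
  if (band == "NV") wl$name[wl$band %in% c("UV", "NIR")]
  else wl$name[wl$band == band]
}

#' Put wavelength labels in canonical channel order
#'
#' RGB first (its three planes lead the channel stack), then narrow-band
#' labels by ascending center wavelength. Unknown labels are an error.
#'
#' @param names character vector of wavelength labels.
#' @return the labels reordered; duplicates are dropped.
#' @export
order_wavelengths <- function(names) {
  names <- unique(as.character(names))
  wl <- wavelength_table()
  i <- match(names, wl$name)
  if (anyNA(i)) {
    stop("unknown wavelength label(s): ",
         paste(names[is.na(i)], collapse = ", "))
  }
  has_rgb <- "RGB" %in% names
  nb <- names[names != "RGB"]
  nb <- nb[order(wl$nm[match(nb, wl$name)])]
  c(if (has_rgb) "RGB", nb)
}

# Canonical string key of a wavelength set, used for memoization and for
# deriving per-set training seeds.
wavelength_set_key <- function(names) {
  paste(order_wavelengths(names), collapse = "+")
}

#' Count captured images represented by a wavelength set
#'
#' An RGB shot contributes three input channels but is one captured image;
#' evaluation curves are indexed by shots, not channels.
#'
#' @param names character vector of wavelength labels.
#' @return list with `n_images` (RGB counts as 1) and `n_channels`
#'   (RGB counts as 3).
#' @export
count_images <- function(names) {
  names <- unique(as.character(names))
  wavelength_band(names)  # validates
  n_rgb <- as.integer("RGB" %in% names)
  n_nb <- length(names) - n_rgb
  list(n_images = n_nb + n_rgb, n_channels = n_nb + 3L * n_rgb)
}
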
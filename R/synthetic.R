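#' @title Synthetic multispectral dataset generator
#' @description
#' The generator emulates the statistical structure of multispectral food
#' acquisition that the analysis stages rely on: 19 narrow-band channels at
#' the rig's center wavelengths plus a white/RGB shot, several views per
#' item obtained by rotating the scene, shot-to-shot illumination jitter,
#' additive sensor noise, class pairs that are indistinguishable in all
#' visible channels but separable at one designated NIR channel, and
#' calorie labels driven by a latent composition that is coupled to NIR
#' reflectance. It makes no attempt at photorealistic rendering.
#' @name synthetic_data
NULL

# Run code under a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically mix integers into one 31-bit seed.
mix_seed <- function(...) {
  parts <- c(...)
  s <- 11
  for (x in parts) {
    s <- (s * 69069 + (as.numeric(x) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s)
}

# Hash a string into a 31-bit integer (for set-keyed training seeds).
string_seed <- function(s) {
  mix_seed(utf8ToInt(s))
}

full_scale <- 60000  # in-mask intensity of a reflectance-1 surface, counts

#' Specification of a synthetic multispectral dataset
#'
#' Defaults are a desk-scale scene: 6 food classes observed from 8 views,
#' two visually confusable class pairs whose members differ only at the
#' 890 nm channel by a reflectance contrast of 0.3, multiplicative
#' log-normal illumination jitter of sigma 0.05 per shot, and additive
#' Gaussian sensor noise of sigma 0.01 of full scale. Images default to
#' 96 x 96 because the downstream network input is 64 x 64 and the masked
#' histogram statistics are resolution independent.
#'
#' @param n_classes number of food classes (one item per class).
#' @param n_views views per item; view v rotates the scene by
#'   `v * 360 / n_views` degrees.
#' @param image_size integer `c(H, W)`.
#' @param confusable_pairs list of pairs `c(a, b)` of 0-based class
#'   indices rendered identically in UV/VIS/RGB.
#' @param nir_delta exact reflectance difference planted at `nir_channel`
#'   between the members of each confusable pair.
#' @param nir_channel wavelength label of the planted NIR contrast.
#' @param pair_sugar_delta sugar-fraction contrast between the members of
#'   a confusable pair (default 0.10, the scale of a sugared versus plain
#'   drink), which drives their caloric difference.
#' @param illumination_jitter_sigma sigma of the per-shot log-normal
#'   intensity multiplier.
#' @param sensor_noise_sigma additive Gaussian noise sigma as a fraction of
#'   the 16-bit full scale.
#' @param texture_amp,texture_scale amplitude and maximum spatial frequency
#'   (cycles per object diameter) of the multiplicative surface texture.
#' @param nir_coupling couple NIR reflectance to the latent composition
#'   (water/sugar/fat), so caloric differences correlate with NIR image
#'   differences. Disable for null simulations.
#' @param holdout_frac fraction of views tagged as the validation split
#'   (every k-th view with `k = round(1 / holdout_frac)`).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_classes = 6L, n_views = 8L,
                           image_size = c(96L, 96L),
                           confusable_pairs = list(c(0L, 1L), c(2L, 3L)),
                           nir_delta = 0.3, nir_channel = "890",
                           pair_sugar_delta = 0.10,
                           illumination_jitter_sigma = 0.05,
                           sensor_noise_sigma = 0.01,
                           texture_amp = 0.15, texture_scale = 3,
                           nir_coupling = TRUE, holdout_frac = 0.25,
                           seed = 1L) {
  stopifnot(n_classes >= 2, n_views >= 1, length(image_size) == 2,
            all(image_size >= 16), nir_delta > 0,
            illumination_jitter_sigma >= 0, sensor_noise_sigma >= 0,
            holdout_frac > 0, holdout_frac < 1)
  if (!wavelength_band(nir_channel) %in% "NIR") {
    stop("nir_channel must be a NIR wavelength label")
  }
  if (length(confusable_pairs)) {
    idx <- unlist(confusable_pairs)
    if (length(idx) != 2 * length(confusable_pairs) ||
        anyDuplicated(idx) || any(idx < 0) || any(idx >= n_classes)) {
      stop("confusable_pairs must be disjoint pairs of class indices in ",
           "[0, n_classes)")
    }
    if (n_classes < 2 * length(confusable_pairs)) {
      stop("n_classes too small for the requested confusable pairs")
    }
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_views = as.integer(n_views),
                 image_size = as.integer(image_size),
                 confusable_pairs = confusable_pairs,
                 nir_delta = nir_delta, nir_channel = as.character(nir_channel),
                 pair_sugar_delta = pair_sugar_delta,
                 illumination_jitter_sigma = illumination_jitter_sigma,
                 sensor_noise_sigma = sensor_noise_sigma,
                 texture_amp = texture_amp, texture_scale = texture_scale,
                 nir_coupling = nir_coupling, holdout_frac = holdout_frac,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Calorie of a latent composition (Atwater-style)
#'
#' `kcal = weight_g * (4 * sugar_frac + 9 * fat_frac)`; water contributes
#' nothing. This ties the generated calorie label to the same composition
#' that modulates NIR reflectance.
#'
#' @param composition numeric vector or list with `water_frac`,
#'   `sugar_frac`, `fat_frac`, each in `[0, 1]`, summing to at most 1.
#' @param weight_g item weight in grams.
#' @return calories in kcal.
#' @examples
#' calorie_from_composition(c(water_frac = .9, sugar_frac = .1, fat_frac = 0), 100)
#' @export
calorie_from_composition <- function(composition, weight_g) {
  comp <- unlist(composition)[c("water_frac", "sugar_frac", "fat_frac")]
  if (anyNA(comp) || any(comp < 0) || any(comp > 1) || sum(comp) > 1 + 1e-9) {
    stop("composition fractions must lie in [0,1] and sum to at most 1")
  }
  stopifnot(weight_g > 0)
  unname(weight_g * (4 * comp["sugar_frac"] + 9 * comp["fat_frac"]))
}

#' Build per-class reflectance spectra
#'
#' Draws, deterministically given the spec seed, one reflectance value per
#' wavelength label per class (three values for RGB), a latent composition,
#' a silhouette shape and texture parameters. With `nir_coupling` on, NIR
#' reflectance decreases with water and sugar content (plus a small
#' per-wavelength offset), so pairwise NIR image differences track caloric
#' differences. Members of a confusable pair are exact copies of each other
#' everywhere except at the designated NIR channel, where their reflectance
#' differs by exactly `nir_delta`; their compositions (hence calories)
#' differ through the sugar fraction.
#'
#' @param spec a [generator_spec()].
#' @return list of `class_spectrum` objects (one per class) with fields
#'   `class_index`, `reflectance` (named list; numeric scalars plus a
#'   3-vector for `"RGB"`), `composition`, `shape_id`, `texture_scale` and
#'   internal shape/texture parameters.
#' @export
build_class_spectra <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  wl <- wavelength_table()
  nb <- wl$name[wl$name != "RGB"]
  shapes <- c("disk", "square", "annulus", "blob")
  with_seed(mix_seed(spec$seed, 101), {
    spectra <- lapply(seq_len(spec$n_classes), function(ci) {
      refl <- stats::setNames(as.list(stats::runif(length(nb), 0.2, 0.8)), nb)
      # caloric density scales with dry matter, as in real foods: sugar
      # and fat are drawn as fractions of the non-water remainder
      water <- stats::runif(1, 0.3, 0.8)
      sugar <- (1 - water) * stats::runif(1, 0.05, 0.3)
      fat <- (1 - water) * stats::runif(1, 0.1, 0.4)
      if (spec$nir_coupling) {
        # NIR reflectance encodes caloric density (kcal/g): watery foods
        # absorb NIR strongly, sugary/fatty (dry, dense) foods reflect it
        density <- 4 * sugar + 9 * fat
        for (w in band_wavelengths("NIR")) {
          refl[[w]] <- min(0.95, max(0.05,
            0.15 + 0.22 * density + stats::runif(1, -0.03, 0.03)))
        }
      }
      refl[["RGB"]] <- stats::runif(3, 0.2, 0.8)
      structure(list(
        class_index = ci - 1L,
        reflectance = refl,
        composition = c(water_frac = water, sugar_frac = sugar,
                        fat_frac = fat),
        shape_id = shapes[(ci - 1L) %% length(shapes) + 1L],
        texture_scale = spec$texture_scale,
        texture_params = list(
          amp = spec$texture_amp,
          a = stats::runif(4, 0.5, 1),
          freq = stats::runif(4, 0.5, spec$texture_scale),
          phi = stats::runif(4, 0, 2 * pi),
          psi = stats::runif(4, 0, 2 * pi)),
        blob_harmonics = list(amp = stats::runif(3, 0, 0.12),
                              phase = stats::runif(3, 0, 2 * pi))
      ), class = "class_spectrum")
    })
    for (pair in spec$confusable_pairs) {
      a <- pair[1] + 1L
      b <- pair[2] + 1L
      # member a becomes a drink-like low-calorie item ...
      spectra[[a]]$composition <- c(
        water_frac = stats::runif(1, 0.6, 0.85),
        sugar_frac = stats::runif(1, 0.005, 0.05),
        fat_frac = stats::runif(1, 0, 0.03))
      if (spec$nir_coupling) {
        # keep the NIR coupling coherent with the overridden composition
        dens <- 4 * spectra[[a]]$composition["sugar_frac"] +
          9 * spectra[[a]]$composition["fat_frac"]
        for (w in band_wavelengths("NIR")) {
          spectra[[a]]$reflectance[[w]] <- min(0.95, max(0.05,
            0.15 + 0.22 * dens + stats::runif(1, -0.03, 0.03)))
        }
      }
      # ... and member b is its sugared twin: identical everywhere except
      # the designated NIR channel (exact nir_delta) and the sugar fraction
      twin <- spectra[[a]]
      twin$class_index <- spectra[[b]]$class_index
      ra <- twin$reflectance[[spec$nir_channel]]
      twin$reflectance[[spec$nir_channel]] <-
        if (ra + spec$nir_delta <= 0.98) ra + spec$nir_delta
        else ra - spec$nir_delta
      comp <- twin$composition
      ds <- min(spec$pair_sugar_delta,
                1 - comp["sugar_frac"] - comp["fat_frac"])
      comp["sugar_frac"] <- comp["sugar_frac"] + ds
      comp["water_frac"] <- max(0, comp["water_frac"] - ds)
      twin$composition <- comp
      spectra[[b]] <- twin
    }
    spectra
  })
}

# Rotated object-frame coordinates for an H x W grid; theta in degrees.
object_coords <- function(h, w, theta_deg) {
  scale <- min(h, w) / 2
  x <- (col(matrix(0, h, w)) - (w + 1) / 2) / scale
  y <- (row(matrix(0, h, w)) - (h + 1) / 2) / scale
  th <- theta_deg * pi / 180
  list(u = cos(th) * x + sin(th) * y,
       v = -sin(th) * x + cos(th) * y)
}

silhouette_mask <- function(cs, uv) {
  u <- uv$u; v <- uv$v
  r <- sqrt(u^2 + v^2)
  switch(cs$shape_id,
    disk = r <= 0.7,
    square = abs(u) <= 0.55 & abs(v) <= 0.55,
    annulus = r >= 0.35 & r <= 0.7,
    blob = {
      ang <- atan2(v, u)
      bh <- cs$blob_harmonics
      rad <- 0.6 * (1 + bh$amp[1] * sin(2 * ang + bh$phase[1]) +
                        bh$amp[2] * sin(3 * ang + bh$phase[2]) +
                        bh$amp[3] * sin(5 * ang + bh$phase[3]))
      r <= rad
    },
    stop("unknown shape_id: ", cs$shape_id))
}

texture_field <- function(cs, uv) {
  tp <- cs$texture_params
  f <- 0
  for (j in seq_along(tp$a)) {
    f <- f + tp$a[j] * sin(2 * pi * tp$freq[j] *
                             (cos(tp$phi[j]) * uv$u + sin(tp$phi[j]) * uv$v) +
                             tp$psi[j])
  }
  pmax(0.05, 1 + tp$amp * f / sqrt(sum(tp$a^2) / 2))
}

#' Render one synthetic shot
#'
#' The class silhouette and its surface texture are analytic functions of
#' object-frame coordinates, so rotating the view rotates the content
#' exactly; in-mask intensity is `reflectance * jitter * 60000 * texture`
#' where the jitter multiplier is drawn once per shot from a log-normal
#' with sigma `illumination_jitter_sigma`. Additive Gaussian sensor noise
#' is applied everywhere and the result is clipped to the 16-bit range.
#' Background is zero apart from noise. Deterministic given
#' `(spec seed, item, view, wavelength)`.
#'
#' @param class_spectrum a `class_spectrum` from [build_class_spectra()].
#' @param view_index 0-based view; the scene is rotated by
#'   `view_index * 360 / n_views` degrees.
#' @param wavelength wavelength label to render (`"RGB"` gives 3 planes).
#' @param spec the [generator_spec()].
#' @return an [ms_shot()] carrying the ground-truth mask.
#' @export
render_shot <- function(class_spectrum, view_index, wavelength, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  cs <- class_spectrum
  wavelength <- as.character(wavelength)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  theta <- view_index * 360 / spec$n_views
  uv <- object_coords(h, w, theta)
  mask <- silhouette_mask(cs, uv)
  tex <- texture_field(cs, uv)
  wl_index <- match(wavelength, wavelength_table()$name)
  refl <- cs$reflectance[[wavelength]]
  px <- with_seed(mix_seed(spec$seed, cs$class_index, view_index, wl_index), {
    jitter <- exp(stats::rnorm(1, 0, spec$illumination_jitter_sigma))
    render_plane <- function(rf) {
      img <- ifelse(mask, rf * jitter * full_scale * tex, 0)
      if (spec$sensor_noise_sigma > 0) {
        img <- img + stats::rnorm(length(img), 0,
                                  spec$sensor_noise_sigma * 65535)
      }
      matrix(pmin(65535, pmax(0, img)), h, w)
    }
    if (wavelength == "RGB") {
      planes <- lapply(refl, render_plane)
      array(c(planes[[1]], planes[[2]], planes[[3]]), c(h, w, 3))
    } else {
      render_plane(refl)
    }
  })
  ms_shot(px, wavelength, item_id = cs$class_index + 1L,
          view_index = view_index, camera_index = 0L, mask = mask)
}

# Per-item weights and calorie labels, deterministic given the spec.
# Served weight anti-correlates with caloric density, as in real serving
# sizes (dense snacks come light, watery foods heavy; the packaged food
# table shows cor(weight, kcal/g) = -0.76). Confusable-pair members share
# a weight: such pairs are served as the same amount in the same
# container, so amount is no cue.
item_labels <- function(spec, spectra) {
  density <- vapply(spectra, function(s) {
    calorie_from_composition(s$composition, 1)
  }, 1.0)
  weights <- with_seed(mix_seed(spec$seed, 202), {
    pmin(350, pmax(20, 180 / (1 + 0.8 * density) *
                     exp(stats::rnorm(spec$n_classes, 0, 0.15))))
  })
  for (pair in spec$confusable_pairs) {
    weights[pair[2] + 1L] <- weights[pair[1] + 1L]
  }
  data.frame(
    item_id = seq_len(spec$n_classes),
    class_index = vapply(spectra, function(s) s$class_index, 1L),
    weight_g = weights,
    calorie_kcal = vapply(seq_along(spectra), function(i) {
      calorie_from_composition(spectra[[i]]$composition, weights[i])
    }, 1.0)
  )
}

view_split <- function(spec) {
  k <- max(2L, round(1 / spec$holdout_frac))
  ifelse((seq_len(spec$n_views)) %% k == 0, "val", "train")
}

#' Generate a dataset in memory
#'
#' Renders every (item, view, wavelength) shot of the spec without touching
#' disk. One item per class; 20 shots per view (19 narrow-band + RGB)
#' unless `wavelengths` restricts the channel set.
#'
#' @param spec a [generator_spec()].
#' @param wavelengths wavelength labels to render (default: all 20).
#' @return list of `ms_stack` objects, one per (item, view), each carrying
#'   weight, calorie, class and split labels.
#' @export
generate_stacks <- function(spec, wavelengths = wavelength_table()$name) {
  spectra <- build_class_spectra(spec)
  labels <- item_labels(spec, spectra)
  split <- view_split(spec)
  out <- list()
  for (ci in seq_len(spec$n_classes)) {
    for (v in seq_len(spec$n_views) - 1L) {
      shots <- lapply(wavelengths, function(w) {
        render_shot(spectra[[ci]], v, w, spec)
      })
      names(shots) <- wavelengths
      out[[length(out) + 1L]] <- ms_stack(
        shots, weight_g = labels$weight_g[ci],
        calorie_kcal = labels$calorie_kcal[ci],
        class_index = labels$class_index[ci], split = split[v + 1L])
    }
  }
  out
}

#' Generate a dataset on disk
#'
#' Writes one 16-bit TIFF per (item, view, wavelength), one mask TIFF per
#' (item, view), and a manifest CSV indexing them, with calorie labels from
#' [calorie_from_composition()] and a view-based train/validation split.
#'
#' @param spec a [generator_spec()].
#' @param out_dir output directory (created if needed).
#' @param force overwrite an existing non-empty directory.
#' @return the manifest (invisibly readable back via [read_manifest()]).
#' @export
generate_dataset <- function(spec, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir)
  }
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  spectra <- build_class_spectra(spec)
  labels <- item_labels(spec, spectra)
  split <- view_split(spec)
  wls <- wavelength_table()$name
  rows <- vector("list", spec$n_classes * spec$n_views * length(wls))
  k <- 0L
  for (ci in seq_len(spec$n_classes)) {
    for (v in seq_len(spec$n_views) - 1L) {
      mask_rel <- sprintf("masks/item%03d_v%02d.tif", ci, v)
      mask_written <- FALSE
      for (w in wls) {
        shot <- render_shot(spectra[[ci]], v, w, spec)
        rel <- sprintf("images/item%03d_v%02d_%s.tif", ci, v, w)
        write_shot(shot, file.path(out_dir, rel))
        if (!mask_written) {
          tiff::writeTIFF(shot$mask * 1, file.path(out_dir, mask_rel),
                          bits.per.sample = 16L, compression = "none")
          mask_written <- TRUE
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          path = rel, item_id = ci, class_index = labels$class_index[ci],
          view_index = v, camera_index = 0L, wavelength = w,
          weight_g = labels$weight_g[ci],
          calorie_kcal = labels$calorie_kcal[ci],
          split = split[v + 1L], mask_path = mask_rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  read_manifest(file.path(out_dir, "manifest.csv"))
}

#' Serialize / restore a generator spec as YAML
#' @param spec a [generator_spec()].
#' @param path YAML file path.
#' @return `write_generator_spec` returns `path`; `read_generator_spec`
#'   returns the restored [generator_spec()].
#' @export
write_generator_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$confusable_pairs <- lapply(x$confusable_pairs, as.integer)
  do.call(generator_spec, x)
}
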
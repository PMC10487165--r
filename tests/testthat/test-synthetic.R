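test_that("confusable pairs are identical in UV/VIS/RGB and differ only at the planted channel", {
  spec <- generator_spec(n_classes = 8L, confusable_pairs =
                           list(c(0L, 1L), c(4L, 6L)), nir_delta = 0.3)
  sp <- build_class_spectra(spec)
  expect_length(sp, 8)
  for (pair in spec$confusable_pairs) {
    a <- sp[[pair[1] + 1]]; b <- sp[[pair[2] + 1]]
    for (w in c(band_wavelengths("UV"), band_wavelengths("VIS"))) {
      expect_identical(a$reflectance[[w]], b$reflectance[[w]])
    }
    expect_identical(a$reflectance[["RGB"]], b$reflectance[["RGB"]])
    expect_equal(abs(a$reflectance[["890"]] - b$reflectance[["890"]]), 0.3)
    expect_identical(a$shape_id, b$shape_id)
  }
})

test_that("spectra are deterministic given the seed", {
  expect_identical(build_class_spectra(generator_spec(seed = 3)),
                   build_class_spectra(generator_spec(seed = 3)))
  s1 <- build_class_spectra(generator_spec(seed = 3))
  s2 <- build_class_spectra(generator_spec(seed = 4))
  expect_false(identical(s1, s2))
})

test_that("infeasible confusable pair lists are rejected", {
  expect_error(generator_spec(n_classes = 3,
                              confusable_pairs = list(c(0, 1), c(1, 2))),
               "disjoint")
  expect_error(generator_spec(n_classes = 4,
                              confusable_pairs = list(c(0, 5))),
               "confusable_pairs")
})

test_that("calorie follows the Atwater-style composition rule", {
  expect_equal(calorie_from_composition(
    c(water_frac = .9, sugar_frac = .1, fat_frac = 0), 100), 40)
  expect_equal(calorie_from_composition(
    c(water_frac = 1, sugar_frac = 0, fat_frac = 0), 250), 0)
  expect_equal(calorie_from_composition(
    c(water_frac = 0.5, sugar_frac = 0.2, fat_frac = 0.1), 150), 255)
  expect_error(calorie_from_composition(
    c(water_frac = 0.8, sugar_frac = 0.5, fat_frac = 0), 100), "sum")
  expect_error(calorie_from_composition(
    c(water_frac = -0.1, sugar_frac = 0.5, fat_frac = 0), 100), "\\[0,1\\]")
})

test_that("noise-free renders hit the reflectance-scaled intensity exactly", {
  spec <- tiny_spec(illumination_jitter_sigma = 0, sensor_noise_sigma = 0,
                    texture_amp = 0)
  sp <- build_class_spectra(spec)
  sh <- render_shot(sp[[3]], 0, "560", spec)
  expect_equal(mean(sh$pixels[sh$mask]),
               sp[[3]]$reflectance[["560"]] * 60000, tolerance = 1e-10)
  expect_lt(max(sh$pixels[!sh$mask]), 1)
  # reflectance pinned to zero leaves the food region at background level
  sp[[3]]$reflectance[["560"]] <- 0
  sh0 <- render_shot(sp[[3]], 0, "560", spec)
  expect_equal(mean(sh0$pixels[sh0$mask]), 0)
})

test_that("rendering is deterministic and rotation-covariant", {
  spec <- tiny_spec()
  sp <- build_class_spectra(spec)
  expect_identical(render_shot(sp[[1]], 1, "890", spec),
                   render_shot(sp[[1]], 1, "890", spec))
  # views rotate content: masked histograms agree up to noise/resampling
  h0 <- masked_histogram(render_shot(sp[[1]], 0, "890", spec), bins = 16)
  h1 <- masked_histogram(render_shot(sp[[1]], 1, "890", spec), bins = 16)
  expect_lt(bhattacharyya_distance(h0, h1), 0.05)
})

test_that("in-memory and on-disk datasets have the expected layout", {
  spec <- generator_spec(n_classes = 6L, n_views = 4L,
                         image_size = c(64L, 64L))
  d <- tempfile()
  manifest <- generate_dataset(spec, d)
  expect_equal(nrow(manifest), 6 * 4 * 20)
  expect_error(generate_dataset(spec, d), "force")
  expect_equal(sort(unique(manifest$split)), c("train", "val"))
  expect_equal(mean(manifest$split == "val"), 0.25)
  # regenerating with the same seed gives identical labels and ordering
  d2 <- tempfile()
  m2 <- generate_dataset(spec, d2)
  expect_equal(manifest$calorie_kcal, m2$calorie_kcal)
  expect_equal(manifest$path, m2$path)
  st <- read_stack(manifest, 2, 1)
  expect_length(st$shots, 20)
  expect_true(all(vapply(st$shots, function(s) !is.null(s$mask), TRUE)))

  stacks <- generate_stacks(tiny_spec(), wavelengths = c("RGB", "890"))
  expect_length(stacks, 4 * 4)
  expect_named(stacks[[1]]$shots, c("RGB", "890"))
})

test_that("confusable pairs look identical in RGB but split at the planted NIR channel", {
  spec <- tiny_spec(seed = 9)
  stacks <- generate_stacks(spec, wavelengths = c("RGB", "470", "560", "890"))
  tab <- pairwise_distance_table(stacks, bins = 64)
  pair <- tab[tab$item_m == 1 & tab$item_n == 2, ]
  d_rgb <- pair$d_b[pair$wavelength == "RGB"]
  d_890 <- pair$d_b[pair$wavelength == "890"]
  d_vis <- pair$d_b[pair$wavelength %in% c("470", "560")]
  expect_lt(d_rgb, 0.05)
  expect_gt(d_890, max(d_vis))
  expect_gt(d_890, 10 * max(d_vis))
})

test_that("the correlation profile peaks in the NIR band when coupling is on", {
  # pair-free datasets isolate the composition-to-NIR coupling; a strong
  # texture keeps the histogram distances graded rather than saturated
  wls <- c("405", "470", "560", "660", "850", "890", "970")
  hits <- 0
  for (sd in 1:5) {
    spec <- generator_spec(n_classes = 8L, n_views = 4L,
                           image_size = c(64L, 64L),
                           confusable_pairs = list(), texture_amp = 0.35,
                           seed = sd)
    stacks <- generate_stacks(spec, wavelengths = wls)
    prof <- correlation_profile(pairwise_distance_table(stacks, bins = 64))
    if (prof$band[which.max(prof$rho)] == "NIR") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("generator spec YAML round trip is stable", {
  spec <- generator_spec(n_classes = 5L, seed = 77L,
                         confusable_pairs = list(c(1L, 3L)))
  f <- tempfile(fileext = ".yaml")
  write_generator_spec(spec, f)
  expect_equal(read_generator_spec(f), spec)
})
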
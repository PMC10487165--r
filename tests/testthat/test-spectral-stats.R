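test_that("masked histograms count only in-mask pixels and normalize to 1", {
  sh <- tiny_shot(rep(40000, 10))
  h <- masked_histogram(sh, bins = 8)
  expect_equal(sum(h$probs), 1)
  expect_equal(sum(h$probs > 0), 1)  # constant region: one occupied bin

  # out-of-mask values are invisible to the histogram
  px <- matrix(60000, 4, 4)
  mask <- matrix(FALSE, 4, 4); mask[1:8] <- TRUE
  px[mask] <- 1000
  h2 <- masked_histogram(ms_shot(px, "890", mask = mask), bins = 16)
  expect_equal(h2$probs[[1]], 1)

  expect_error(masked_histogram(ms_shot(px, "890")), "mask")
  expect_error(masked_histogram(ms_shot(px, "890",
                                        mask = matrix(FALSE, 4, 4))), "empty")
})

test_that("uniform random pixels fill bins evenly", {
  set.seed(42)
  vals <- sample(0:65535, 40000, replace = TRUE)
  h <- histogram_from_values(vals, bins = 256)
  chisq <- sum((h$probs * length(vals) - length(vals) / 256)^2 /
                 (length(vals) / 256))
  # 255 df: the 99.9% quantile is ~330
  expect_lt(chisq, stats::qchisq(0.999, 255))
  expect_equal(sum(h$probs), 1)
})

test_that("Bhattacharyya distance matches hand-computed values", {
  expect_equal(bhattacharyya_distance(hist_from_probs(c(1, 0)),
                                      hist_from_probs(c(0.5, 0.5))),
               0.34657, tolerance = 1e-4)
  expect_equal(bhattacharyya_distance(hist_from_probs(c(0.25, 0.75)),
                                      hist_from_probs(c(0.75, 0.25))),
               0.14384, tolerance = 1e-4)
  p <- hist_from_probs(c(0.3, 0.7))
  expect_equal(bhattacharyya_distance(p, p), 0)
  expect_equal(bhattacharyya_distance(hist_from_probs(c(1, 0)),
                                      hist_from_probs(c(0, 1))), Inf)
  expect_error(bhattacharyya_distance(p, hist_from_probs(c(1, 0, 0))),
               "binning")
  # clamped variant stays in [0, 1] and is 1 for disjoint supports
  expect_equal(bhattacharyya_distance(hist_from_probs(c(1, 0)),
                                      hist_from_probs(c(0, 1)),
                                      clamp = TRUE), 1)
})

test_that("Bhattacharyya distance is symmetric, non-negative, zero only at equality, permutation-invariant", {
  set.seed(7)
  for (i in 1:20) {
    p <- hist_from_probs(stats::runif(16))
    q <- hist_from_probs(stats::runif(16))
    d <- bhattacharyya_distance(p, q)
    expect_gte(d, 0)
    expect_equal(d, bhattacharyya_distance(q, p))
    expect_equal(d, brute_bhattacharyya(p$probs, q$probs))
    perm <- sample(16)
    expect_equal(d, bhattacharyya_distance(hist_from_probs(p$probs[perm]),
                                           hist_from_probs(q$probs[perm])))
    expect_gt(d, 0)  # random draws never bin-wise equal
  }
})

test_that("band representative distance is the band maximum", {
  stacks <- generate_stacks(tiny_spec(), wavelengths = c("470", "560", "890"))
  tab <- pairwise_distance_table(stacks, bins = 64)
  sub <- tab[tab$item_m == 1 & tab$item_n == 3, ]
  expect_equal(band_representative_distance(tab, c(1, 3), c("470", "560")),
               max(sub$d_b[sub$wavelength %in% c("470", "560")]))
  expect_equal(band_representative_distance(tab, c(3, 1), "890"),
               sub$d_b[sub$wavelength == "890"])
  expect_error(band_representative_distance(tab, c(1, 3), "970"), "970")
})

test_that("cumulative ratio matches brute-force counting and handles degenerate thresholds", {
  # direct worked example
  fake <- data.frame(item_m = c(1, 1, 2), item_n = c(2, 3, 3))
  fake_tab <- rbind(
    data.frame(item_m = fake$item_m, item_n = fake$item_n,
               wavelength = "560", d_b = c(0.1, 0.3, 0.5)),
    data.frame(item_m = fake$item_m, item_n = fake$item_n,
               wavelength = "890", d_b = c(0.6, 0.2, 0.9)))
  expect_equal(cumulative_ratio(fake_tab, t_v = 0.4, t_nv = 0.5), 1 / 2)
  expect_equal(cumulative_ratio(fake_tab, t_v = 0.4, t_nv = 0), 1)
  expect_error(cumulative_ratio(fake_tab, t_v = 0.05, t_nv = 0.5),
               "undefined")

  # randomized comparison against the explicit counting oracle
  set.seed(11)
  for (i in 1:20) {
    n <- 8
    dv <- stats::runif(n); dnv <- stats::runif(n)
    pairs <- utils::combn(1:5, 2)[, 1:n]
    tab <- rbind(
      data.frame(item_m = pairs[1, ], item_n = pairs[2, ],
                 wavelength = "560", d_b = dv),
      data.frame(item_m = pairs[1, ], item_n = pairs[2, ],
                 wavelength = "890", d_b = dnv))
    tv <- stats::runif(1, 0.3, 1); tnv <- stats::runif(1)
    expected <- brute_fc(dv, dnv, tv, tnv)
    if (is.na(expected)) {
      expect_error(cumulative_ratio(tab, tv, tnv))
    } else {
      expect_equal(cumulative_ratio(tab, tv, tnv), expected)
    }
  }
})

test_that("F_C lies in [0,1] and is non-increasing in T_NV", {
  stacks <- generate_stacks(tiny_spec(seed = 2),
                            wavelengths = c("470", "560", "890", "970"))
  tab <- pairwise_distance_table(stacks, bins = 64)
  grid <- cumulative_ratio_grid(tab, t_v_list = c(0.5, 2),
                                t_nv_list = seq(0, 1, 0.1))
  ok <- !is.na(grid$f_c)
  expect_true(all(grid$f_c[ok] >= 0 & grid$f_c[ok] <= 1))
  for (tv in unique(grid$t_v)) {
    sub <- grid[grid$t_v == tv & !is.na(grid$f_c), ]
    sub <- sub[order(sub$t_nv), ]
    expect_true(all(diff(sub$f_c) <= 1e-12))
  }
})

test_that("caloric difference is the absolute relative difference", {
  expect_equal(caloric_difference(100, 100), 0)
  expect_equal(caloric_difference(18.56, 55.74), 0.5004, tolerance = 1e-4)
  expect_equal(caloric_difference(10, 0), 1)
  expect_error(caloric_difference(0, 0), "undefined")
  expect_error(caloric_difference(-1, 5))
})

test_that("wavelength correlation equals first-principles Pearson", {
  expect_equal(wavelength_correlation(c(0.1, 0.2, 0.3), c(0.2, 0.4, 0.6)), 1)
  expect_equal(wavelength_correlation(c(0, 1, 2), c(1, 3, 2)), 0.5)
  expect_equal(wavelength_correlation(c(0.1, 0.2, 0.3), c(0.6, 0.4, 0.2)), -1)
  expect_error(wavelength_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(wavelength_correlation(c(1, 2), c(1, 2)), "3")
  set.seed(13)
  for (i in 1:20) {
    x <- stats::rnorm(10); y <- stats::rnorm(10)
    expect_equal(wavelength_correlation(x, y), brute_pearson(x, y))
  }
})

test_that("band correlation comparison reports means and a calibrated p-value", {
  prof <- data.frame(wavelength = c("470", "560", "625", "850", "890", "970"),
                     band = c("VIS", "VIS", "VIS", "NIR", "NIR", "NIR"),
                     rho = c(0.5, 0.6, 0.7, 0.5, 0.6, 0.7))
  cmp <- compare_band_correlations(prof)
  expect_equal(cmp$mean_v, cmp$mean_nv)
  expect_equal(cmp$p_value, 1)

  prof$rho <- c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1)
  cmp2 <- compare_band_correlations(prof)
  expect_equal(cmp2$mean_v, 0.9)
  expect_equal(cmp2$mean_nv, 0.1)
  expect_lt(cmp2$p_value, 0.05)

  expect_error(compare_band_correlations(prof[c(1, 4, 5), ]), "at least 2")

  # under no band difference the p-value is roughly uniform across seeds
  set.seed(21)
  ps <- replicate(60, {
    rho <- stats::runif(19, 0.2, 0.8)
    p <- data.frame(wavelength = wavelength_table()$name[1:19],
                    band = wavelength_table()$band[1:19], rho = rho)
    compare_band_correlations(p)$p_value
  })
  expect_lt(mean(ps < 0.05), 0.2)  # false-positive rate not inflated
  expect_gt(mean(ps), 0.3)
})
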
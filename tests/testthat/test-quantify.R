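make_pair <- function(voxels, mask_arr, spacing = 10) {
  list(
    stack = image_stack(voxels, plane_spacing_um = spacing),
    mask = segmentation_mask(mask_arr, "internal", 0.5)
  )
}

test_that("plane metrics count and average exactly on hand-built cases", {
  v <- array(0.5, c(2, 2, 2))
  m <- array(FALSE, c(2, 2, 2))
  m[1, 1, 1] <- TRUE
  pr <- with(make_pair(v, m), plane_metrics(stack, mask))
  expect_equal(pr$fraction, c(0.25, 0))
  expect_equal(pr$plane, c(0L, 1L))
  expect_equal(pr$depth_um, c(0, 10))
  expect_true(is.na(pr$signal[2]))

  v2 <- array(c(10, 10, 2, 2), c(2, 2, 1))
  m2 <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  pr2 <- with(make_pair(v2, m2), plane_metrics(stack, mask))
  expect_equal(pr2$signal, 10)
  expect_equal(pr2$noise, 2)
  expect_equal(pr2$snr, 5)
})

test_that("plane metrics equal the exhaustive per-voxel oracle", {
  set.seed(202)
  for (rep in 1:10) {
    shape <- c(8, 8, 5)
    v <- array(runif(prod(shape)), shape)
    m <- array(runif(prod(shape)) > runif(1, 0.3, 0.95), shape)
    pr <- with(make_pair(v, m), plane_metrics(stack, mask))
    oracle <- naive_plane_metrics(v, m)
    expect_equal(pr$fraction, oracle$fraction)
    expect_equal(pr$signal, oracle$signal)
    expect_equal(pr$noise, oracle$noise)
    expect_equal(pr$snr, oracle$snr)
  }
})

test_that("shape mismatches are refused with both shapes named", {
  st <- image_stack(array(0, c(4, 4, 3)), 5)
  mk <- segmentation_mask(array(FALSE, c(4, 4, 2)), "internal")
  expect_error(plane_metrics(st, mk), "4, 4, 3.*4, 4, 2")
})

profile_from <- function(signal, spacing = 10, fraction = NULL) {
  n <- length(signal)
  out <- tibble::tibble(
    plane = seq_len(n) - 1L,
    depth_um = (seq_len(n) - 1L) * spacing,
    fraction = fraction %||% rep(0.5, n),
    signal = signal,
    noise = rep(0.1, n),
    snr = signal / 0.1
  )
  attr(out, "plane_spacing_um") <- spacing
  class(out) <- c("depth_profile", class(out))
  out
}

test_that("start-plane detection finds staining onset", {
  pr <- profile_from(c(0, 0, 0, 5, 5))
  expect_equal(find_start_plane(pr, "signal", onset_frac = 0.1,
                                smooth_window = 1), 3L)
  expect_equal(find_start_plane(profile_from(rep(0, 6)), "signal"), 0L)
})

test_that("start plane of a rising profile ignores appended trailing planes", {
  set.seed(9)
  for (rep in 1:20) {
    base <- cumsum(runif(10))
    p1 <- profile_from(base)
    # appended planes plateau at the maximum: still monotone non-decreasing
    p2 <- profile_from(c(base, rep(max(base), 5)))
    expect_equal(find_start_plane(p1, "signal", smooth_window = 1),
                 find_start_plane(p2, "signal", smooth_window = 1))
  }
})

test_that("half-max depth interpolates the first crossing after the maximum", {
  pr <- profile_from(c(1.0, 0.8, 0.6, 0.4, 0.2))
  hm <- half_max_depth(pr, metric = "signal", start_plane = 0)
  expect_equal(hm$half_max_depth_um, 25)
  expect_equal(hm$max_value, 1.0)
  expect_equal(hm$start_plane, 0L)

  # constant positive profile never crosses half its maximum
  const <- half_max_depth(profile_from(rep(0.7, 5)), start_plane = 0)
  expect_true(is.na(const$half_max_depth_um))
  expect_equal(const$max_value, 0.7)

  all_na <- profile_from(rep(NA_real_, 4))
  expect_error(half_max_depth(all_na, start_plane = 0), "undefined")
})

test_that("half-max depth is measured relative to the start plane", {
  sig <- c(0, 0, 1.0, 0.8, 0.6, 0.4, 0.2)
  pr <- profile_from(sig)
  hm <- half_max_depth(pr, metric = "signal", smooth_window = 1)
  expect_equal(hm$start_plane, 2L)
  expect_equal(hm$half_max_depth_um, 25)
})

test_that("undefined planes are skipped, not treated as zero", {
  sig <- c(1.0, 0.8, NA, 0.4, 0.2)
  hm <- half_max_depth(profile_from(sig), start_plane = 0)
  # crossing interpolated between plane 1 (0.8) and plane 3 (0.4)
  expect_equal(hm$half_max_depth_um, 10 + (0.8 - 0.5) / 0.4 * 20)
})

test_that("half-max depth is invariant to positive intensity rescaling", {
  p <- tiny_scene_params(seed = 8L)
  sc <- make_scene(p)
  st <- render_stack(sc, attenuation_model("sigmoid", d_half_um = 80),
                     noise = noise_params(blur_sigma_um = 0), seed = 4L)
  mask <- threshold_mask(st, "fixed", 0.2)
  hm1 <- half_max_depth(plane_metrics(st, mask))
  st2 <- st
  st2$voxels <- st$voxels * 7.3
  hm2 <- half_max_depth(plane_metrics(st2, mask))
  expect_equal(hm1$half_max_depth_um, hm2$half_max_depth_um)
  expect_equal(hm1$start_plane, hm2$start_plane)
})

test_that("noise-free sigmoid stacks yield half-max within one plane spacing", {
  p <- scene_params(shape = c(40L, 40L, 60L), plane_spacing_um = 5,
                    feature_density = 0.05, feature_size_um = 10, seed = 31L)
  sc <- make_scene(p)
  st <- render_stack(sc, attenuation_model("sigmoid", d_half_um = 150,
                                           front_width_um = 15),
                     noise = noise_free(), amplitude = 0.9)
  mask <- segmentation_mask(sc$truth_mask, "imported")
  hm <- half_max_depth(plane_metrics(st, mask), metric = "signal")
  expect_lt(abs(hm$half_max_depth_um - 150), 5)
})

test_that("normalization divides by the single group-wide maximum", {
  pa <- profile_from(c(2, 1), fraction = c(2, 1) / 10)
  pa$condition_id <- "A"; pa$fluorophore <- "FL1"; pa$replicate_id <- "r1"
  pb <- profile_from(c(4, 2), fraction = c(4, 2) / 10)
  pb$condition_id <- "B"; pb$fluorophore <- "FL1"; pb$replicate_id <- "r1"
  sc <- normalize_across_conditions(list(pa, pb), metric = "signal")
  expect_equal(sc$score[sc$condition_id == "A"], c(0.5, 0.25))
  expect_equal(sc$score[sc$condition_id == "B"], c(1.0, 0.5))
  expect_equal(unique(sc$reference_max), 4)

  single <- normalize_across_conditions(list(pa), metric = "signal")
  expect_equal(max(single$score), 1)
})

test_that("normalized scores are scale invariant and group max is one", {
  set.seed(17)
  profs <- lapply(1:4, function(i) {
    p <- profile_from(runif(6), fraction = runif(6))
    p$condition_id <- paste0("c", i)
    p$fluorophore <- if (i <= 2) "green" else "red"
    p$replicate_id <- "r1"
    p
  })
  s1 <- normalize_across_conditions(profs, metric = "fraction")
  scaled <- lapply(profs, function(p) {
    p$fraction <- p$fraction * 11
    p
  })
  s2 <- normalize_across_conditions(scaled, metric = "fraction")
  expect_equal(s1$score, s2$score)
  for (g in c("green", "red")) {
    expect_equal(max(s1$score[s1$fluorophore == g]), 1)
  }

  zero <- profile_from(rep(0, 3))
  zero$condition_id <- "z"; zero$fluorophore <- "FLz"; zero$replicate_id <- "r1"
  expect_warning(sz <- normalize_across_conditions(list(zero), metric = "signal"),
                 "no positive")
  expect_true(all(sz$score == 0))

  expect_error(normalize_across_conditions(list()), "no profiles")
})

test_that("figure of merit selects the right series without mutating input", {
  pr <- profile_from(c(0.9, 0.5, 0.2), fraction = c(0.3, 0.2, 0.1))
  before <- pr
  fc <- figure_of_merit(pr, "constant")
  fn <- figure_of_merit(pr, "nonconstant")
  expect_equal(fc$value, pr$fraction)
  expect_equal(fn$value, pr$signal)
  expect_equal(attr(fc, "label"), "area_fraction")
  expect_equal(attr(fn, "label"), "mean_intensity")
  expect_identical(pr, before)
})
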
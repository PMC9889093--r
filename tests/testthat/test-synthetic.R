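test_that("scene generation handles the empty case and is deterministic", {
  p <- tiny_scene_params(density = 0)
  sc <- make_scene(p)
  expect_false(any(sc$truth_mask))

  p2 <- tiny_scene_params(seed = 42L)
  m1 <- make_scene(p2)$truth_mask
  m2 <- make_scene(p2)$truth_mask
  expect_identical(m1, m2)
  m3 <- make_scene(tiny_scene_params(seed = 43L))$truth_mask
  expect_false(identical(m1, m3))
})

test_that("a forced sphere matches the brute-force discrete ball count", {
  p <- scene_params(shape = c(9L, 9L, 9L), plane_spacing_um = 1,
                    feature_density = 0.1, feature_size_um = 2, seed = 1L)
  # centre voxel (5,5,5) in 1-based indexing sits at (4,4,4) um
  sc <- make_scene(p, centers = matrix(c(4, 4, 4), 1))
  expect_equal(sum(sc$truth_mask),
               naive_ball_count(2, c(5, 5, 5), c(9L, 9L, 9L)))
})

test_that("realised feature density is within 20% of the target", {
  for (kind in c("sphere", "tube", "filament")) {
    p <- scene_params(shape = c(40L, 40L, 40L), plane_spacing_um = 5,
                      feature_kind = kind, feature_density = 0.05,
                      feature_size_um = 12, seed = 7L)
    frac <- mean(make_scene(p)$truth_mask)
    expect_gt(frac, 0.05 * 0.8)
    expect_lt(frac, 0.05 * 1.2)
  }
})

test_that("impossible geometry errors name the violated dimension", {
  p <- scene_params(shape = c(40L, 40L, 3L), plane_spacing_um = 5,
                    feature_density = 0.05, feature_size_um = 50, seed = 1L)
  expect_error(make_scene(p), "z")
})

test_that("parametric attenuation matches its closed forms and invariants", {
  z <- seq(0, 500, by = 5)
  sig <- attenuation_model("sigmoid", d_half_um = 150, front_width_um = 20)
  f <- attenuation_profile(sig, z)
  expect_equal(attenuation_profile(sig, 150), 0.5)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(diff(f) < 0))

  ex <- attenuation_model("exponential", d_half_um = 100)
  g <- attenuation_profile(ex, z)
  expect_equal(attenuation_profile(ex, 200), 0.25)
  expect_equal(attenuation_profile(ex, 100), 0.5)
  expect_true(all(diff(g) < 0))

  expect_error(attenuation_model("pde"), "pde_params")
  expect_error(attenuation_profile(sig, c(5, 3, 8)), "ascending")
})

test_that("binding PDE respects trivial limits and bounds", {
  base <- pde_params(duration_s = 600, n_nodes = 51L)

  p_nok <- pde_params(binding_rate = 0, duration_s = 600, n_nodes = 51L)
  expect_true(all(simulate_binding_pde(p_nok)$b == 0))

  p_noc <- pde_params(surface_conc = 0, duration_s = 600, n_nodes = 51L)
  expect_true(all(simulate_binding_pde(p_noc)$b == 0))

  sol <- simulate_binding_pde(base)
  expect_true(all(sol$b >= 0 & sol$b <= base$site_density))
  expect_true(all(sol$bound_fraction >= 0 & sol$bound_fraction <= 1))
  # monotone non-increasing bound profile with depth at final time
  expect_true(all(diff(sol$b) <= 1e-12))
})

test_that("stability bound violations are rejected with advice", {
  expect_error(
    pde_params(diffusivity_um2_s = 10, dz_um = 1, duration_s = 100,
               n_steps = 100L),
    "n_steps"
  )
})

test_that("mass is conserved under discrete flux accounting", {
  p <- pde_params(duration_s = 900, n_nodes = 101L, dz_um = 2)
  sol <- simulate_binding_pde(p)
  fx <- attr(sol, "flux_series")
  dt <- attr(sol, "dt_s")
  dz <- p$dz_um
  D <- p$diffusivity_um2_s
  c0 <- p$surface_conc
  # mass that entered: diffusive flux past node 1 plus binding at the surface
  # node, both reconstructed from the recorded boundary series
  influx <- sum(dt * D * (c0 - fx$c2) / dz^2) * dz +
    sum(dt * p$binding_rate * c0 * (p$site_density - fx$b1)) * dz +
    sum(dt * D * (fx$c_nm1 - fx$c_n) / dz^2) * dz
  mass <- dz * sum(sol$c[-1] + sol$b[-1]) + dz * sol$b[1]
  expect_lt(abs(mass - influx) / influx, 0.01)
})

test_that("strong-binding front depth scales as sqrt(incubation time)", {
  front_depth <- function(duration) {
    p <- pde_params(diffusivity_um2_s = 10, binding_rate = 0.2,
                    site_density = 50, surface_conc = 1,
                    duration_s = duration, dz_um = 1, n_nodes = 61L)
    sol <- simulate_binding_pde(p)
    prof <- sol$bound_fraction
    i <- which(prof < 0.5)[1]
    approx(prof[c(i - 1, i)], sol$z_um[c(i - 1, i)], xout = 0.5)$y
  }
  T1 <- 600
  ratio <- front_depth(4 * T1) / front_depth(T1)
  expect_gt(ratio, 2 * 0.85)
  expect_lt(ratio, 2 * 1.15)
})

test_that("rendering reproduces the attenuation curve exactly without noise", {
  p <- tiny_scene_params(seed = 5L)
  sc <- make_scene(p)
  model <- attenuation_model("sigmoid", d_half_um = 80, front_width_um = 15)
  st <- render_stack(sc, model, noise = noise_free(), seed = 1L,
                     amplitude = 0.8)
  att <- attenuation_profile(model, (seq_len(p$shape[3]) - 1) * p$plane_spacing_um)
  for (z in seq_len(p$shape[3])) {
    in_feat <- sc$truth_mask[, , z]
    if (any(in_feat)) {
      expect_equal(mean(st$voxels[, , z][in_feat]) / 0.8, att[z],
                   tolerance = 1e-12)
    }
    expect_true(all(st$voxels[, , z][!in_feat] == 0))
  }
  expect_equal(st$meta$true_d_half_um, 80)

  # empty truth, zero noise and background -> all-zero stack
  empty <- make_scene(tiny_scene_params(density = 0))
  st0 <- render_stack(empty, model, noise = noise_free(), seed = 1L)
  expect_true(all(st0$voxels == 0))
})

test_that("rendering is reproducible per seed and varies across seeds", {
  p <- tiny_scene_params(seed = 5L)
  sc <- make_scene(p)
  model <- attenuation_model("sigmoid", d_half_um = 80)
  nz <- noise_params(background_level = 0.05, gaussian_sd = 0.03,
                     blur_sigma_um = 0)
  a <- render_stack(sc, model, noise = nz, seed = 10L)
  b <- render_stack(sc, model, noise = nz, seed = 10L)
  c <- render_stack(sc, model, noise = nz, seed = 11L)
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, c$voxels))
})

test_that("two-sided rendering mirrors attenuation about the section middle", {
  p <- tiny_scene_params(seed = 2L, shape = c(16L, 16L, 21L))
  sc <- make_scene(p, centers = matrix(c(40, 40, 50), 1))
  model <- attenuation_model("exponential", d_half_um = 40)
  st <- render_stack(sc, model, noise = noise_free(), two_sided = TRUE)
  att <- st$meta$true_attenuation
  expect_equal(att, rev(att))
  expect_true(all(diff(att[1:10]) < 0))
})

test_that("condition sets count, share geometry, and regenerate bitwise", {
  conds <- data.frame(condition_id = paste0("p", 1:12),
                      d_half_um = seq(60, 390, by = 30))
  p <- tiny_scene_params(shape = c(12L, 12L, 10L), size = 6)
  set <- generate_condition_set(conds, n_replicates = 3L, scene = p,
                                noise = noise_free(), seed = 99L)
  expect_equal(nrow(set), 36L)
  expect_equal(sum(set$baseline), 3L)  # one baseline condition x 3 replicates

  # same replicate index -> same geometry across conditions
  r1 <- set[set$replicate_id == "r1", ]
  masks <- lapply(r1$scene, function(s) s$truth_mask)
  for (m in masks[-1]) expect_identical(masks[[1]], m)

  set2 <- generate_condition_set(conds, n_replicates = 3L, scene = p,
                                 noise = noise_free(), seed = 99L)
  expect_identical(
    lapply(set$stack, function(s) s$voxels),
    lapply(set2$stack, function(s) s$voxels)
  )

  expect_error(
    generate_condition_set(data.frame(condition_id = c("a", "a")), scene = p),
    "duplicate"
  )
})
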
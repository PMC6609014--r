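test_that("phantom writes the configured tissue parameters back", {
  cfg <- small_phantom_config(gm_parcel_t1 = c(1.25, 1.45), n_parcels = 2L,
                              t1 = list(wm = 0.85, gm = 1.35, csf = 4.0))
  ph <- make_phantom(cfg)
  expect_true(all(ph$t1_vol[ph$label_vol == 1L] == 0.85))
  expect_true(all(ph$t1_vol[ph$label_vol == 2L] == 4.0))
  m1 <- mean(ph$t1_vol[ph$label_vol %in% c(101L, 201L)])
  m2 <- mean(ph$t1_vol[ph$label_vol %in% c(102L, 202L)])
  expect_equal(c(m1, m2), c(1.25, 1.45))

  expect_error(make_phantom(small_phantom_config(t1 = list(wm = -1, gm = 1.35, csf = 4))),
               "validation")
  expect_error(make_phantom(small_phantom_config(grid_shape = c(8L, 8L, 8L))),
               "geometry")
})

test_that("symmetric phantom equals its mid-sagittal mirror image exactly", {
  ph <- small_phantom()
  d <- ph$grid_shape
  expect_identical(ph$t1_vol, ph$t1_vol[d[1]:1, , ])
  expect_identical(ph$label_vol[ph$label_vol > 100L] %% 100L,
                   ph$label_vol[d[1]:1, , ][ph$label_vol[d[1]:1, , ] > 100L] %% 100L)
  ph_a <- make_phantom(small_phantom_config(symmetric = FALSE))
  expect_false(identical(ph_a$t1_vol, ph_a$t1_vol[d[1]:1, , ]))
})

test_that("transmit field has the configured centre/edge/asymmetry structure", {
  ph <- small_phantom()
  f <- small_fields()
  d <- ph$grid_shape
  ctr <- round(d / 2)
  expect_equal(f$b1_tx[ctr[1], ctr[2], ctr[3]], 1.1, tolerance = 0.02)
  expect_equal(min(f$b1_tx[ph$brain_mask]), 0.8, tolerance = 0.02)
  # monotone decreasing along a +y ray from the centre
  ray <- f$b1_tx[ctr[1], ctr[2]:d[2], ctr[3]]
  expect_true(all(diff(ray) <= 0))

  fc <- make_fields(field_config(b1 = list(center = 1, edge = 1, asym = 0)), ph)
  expect_true(all(fc$b1_tx == 1))

  fa <- make_fields(field_config(b1 = list(center = 1.1, edge = 0.8, asym = 0.05)), ph)
  left <- mp2ratio:::.left_mask(ph) & ph$brain_mask
  gap <- mean(fa$b1_tx[left]) - mean(fa$b1_tx[!mp2ratio:::.left_mask(ph) & ph$brain_mask])
  expect_equal(gap, 0.05, tolerance = 0.0005 / 0.05)

  expect_error(make_fields(field_config(b1 = list(center = 0.1, edge = -0.5, asym = 0)), ph),
               "validation")
  # smoothness: bounded voxel-to-voxel jumps
  expect_lt(max_voxel_jump(f$b1_tx), 0.05)
})

test_that("surface model vertices live in cortex with mirror correspondence", {
  ph <- small_phantom()
  surf <- small_surface()
  for (h in c("left", "right")) {
    vox <- mm_to_voxel(surf[[h]]$midthickness, ph$voxel_size_mm, ph$grid_shape)
    expect_true(all(is_gm_label(ph$label_vol[vox])))
  }
  # mirroring left vertices across the mid-sagittal plane lands on the
  # corresponding right vertex (exactly, by construction)
  fovx <- ph$grid_shape[1] * ph$voxel_size_mm
  mirrored <- surf$left$vertices
  mirrored[, 1] <- fovx - mirrored[, 1]
  expect_lt(max(abs(mirrored - surf$right$vertices[surf$correspondence, ])),
            ph$voxel_size_mm)
  # requested parcel count realized on both hemispheres
  expect_length(unique(surf$left$labels), 12)
  expect_length(unique(surf$right$labels), 12)
  expect_error(make_surface_model(surface_config(n_vertices = 1000), ph),
               "valid counts")
})

test_that("noise-free nominal-field session reproduces closed-form UNI exactly", {
  ph <- small_phantom()
  f1 <- make_fields(field_config(b1 = list(center = 1, edge = 1, asym = 0),
                                 rx = list(center = 1, edge = 1, asym = 0),
                                 b0 = list(amp_hz = 0, width_mm = 25, asym = 0)), ph)
  ses <- simulate_session(ph, f1, noise_cfg = noise_config(noise_frac = 0, b1_noise_sd = 0),
                          seed = 7)
  idx <- which(ph$brain_mask)
  s <- mp2rage_signal(ph$t1_vol[idx], 1, mp2rage_protocol())
  expect_equal(ses$uni[idx], uni_combine(s$s1, s$s2), tolerance = 1e-12)
  expect_true(all(ses$uni >= -0.5 & ses$uni <= 0.5))
})

test_that("sessions are reproducible and receive bias cancels in UNI", {
  ph <- small_phantom(); f <- small_fields()
  a <- simulate_session(ph, f, seed = 99)
  b <- simulate_session(ph, f, seed = 99)
  expect_identical(a, b)

  f2 <- f; f2$rx_field <- array(2, dim(f$rx_field))
  f1 <- f; f1$rx_field <- array(1, dim(f$rx_field))
  n0 <- noise_config(noise_frac = 0, b1_noise_sd = 0)
  s1 <- simulate_session(ph, f1, noise_cfg = n0, seed = 1)
  s2 <- simulate_session(ph, f2, noise_cfg = n0, seed = 1)
  expect_equal(s2$t1w, 2 * s1$t1w)
  expect_equal(s2$t2w, 2 * s1$t2w)
  expect_equal(s2$uni, s1$uni)
})

test_that("noise scaling: doubling the SD doubles the residual SD", {
  # needs >= 1e4 brain voxels: use the full desk-scale grid
  ph <- fixture("ph64", function() make_phantom(phantom_config()))
  f <- fixture("f64", function() make_fields(field_config(), ph))
  n0 <- noise_config(noise_frac = 0, b1_noise_sd = 0)
  ses0 <- simulate_session(ph, f, noise_cfg = n0, seed = 5)
  ses1 <- simulate_session(ph, f, noise_cfg = noise_config(noise_frac = 0.02, b1_noise_sd = 0), seed = 5)
  ses2 <- simulate_session(ph, f, noise_cfg = noise_config(noise_frac = 0.04, b1_noise_sd = 0), seed = 5)
  idx <- which(ph$brain_mask)
  expect_gt(length(idx), 1e4)
  r1 <- sd(ses1$t1w[idx] - ses0$t1w[idx])
  r2 <- sd(ses2$t1w[idx] - ses0$t1w[idx])
  expect_equal(r2 / r1, 2, tolerance = 0.05)
  expect_error(simulate_session(ph, f, noise_cfg = noise_config(noise_frac = -1)),
               "negative noise")
  expect_error(simulate_session(ph, f, protocols = list(mprage = mprage_protocol())),
               "missing protocol")
})

test_that("study generation respects jitter and retest perturbation settings", {
  base <- study_config(n_subjects = 2, jitter_sd = 0, retest_field_sd = 0,
                       noise = noise_config(noise_frac = 0, b1_noise_sd = 0),
                       phantom = small_phantom_config(),
                       surface = surface_config(n_vertices = 162L))
  st <- make_study(base)
  expect_identical(st$subjects[[1]]$phantom$t1_vol, st$subjects[[2]]$phantom$t1_vol)
  # retest perturbation 0 + noise 0: sessions identical apart from the tag/seed
  s <- st$subjects[[1]]
  expect_equal(s$test$uni, s$retest$uni)
  expect_equal(s$test$t1w, s$retest$t1w)
  expect_error(make_study(study_config(n_subjects = 0)), "n_subjects")
})

test_that("between-subject parcel T1 jitter has the configured spread", {
  set.seed(123)
  draws <- replicate(200, jitter_parcel_t1(c(1.35, 1.2), 0.05)$left)
  expect_equal(sd(draws[1, ]), 0.05, tolerance = 0.15)
  expect_equal(mean(draws[2, ]), 1.2, tolerance = 0.01)
  set.seed(9)
  sym <- jitter_parcel_t1(rep(1.35, 5), 0.05, symmetric = TRUE)
  expect_identical(sym$left, sym$right)
})
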
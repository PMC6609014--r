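test_that("receive field is recovered from the sqrt-product construction", {
  ph <- small_phantom()
  vs <- ph$voxel_size_mm
  f <- small_fields()
  Ftrue <- f$rx_field
  # latent contrast x with inverse contrast in the T2w image
  x <- array(1, dim(Ftrue))
  x[ph$brain_mask] <- 1 + 0.3 * sin(ph$t1_vol[ph$brain_mask])
  t1w <- x * Ftrue
  t2w <- Ftrue / x
  Fhat <- estimate_receive_field(t1w, t2w, ph$brain_mask, field_prep_params(), vs)
  expect_gt(cor(Fhat[ph$brain_mask], Ftrue[ph$brain_mask]), 0.99)

  # corrected T1w recovers x up to a global constant
  corr <- correct_receive(t1w, Fhat, ph$brain_mask)
  expect_gt(cor(corr[ph$brain_mask], x[ph$brain_mask]), 0.999)

  # F = 1 and t2w = 1/t1w exactly: estimate is the unit field
  t1w0 <- x; t2w0 <- array(0, dim(x)); t2w0[ph$brain_mask] <- 1 / x[ph$brain_mask]
  F1 <- estimate_receive_field(t1w0, t2w0, ph$brain_mask, field_prep_params(), vs)
  expect_equal(F1[ph$brain_mask], rep(1, sum(ph$brain_mask)), tolerance = 1e-8)

  # global scaling of both inputs does not change the normalized field
  F2 <- estimate_receive_field(3 * t1w, 3 * t2w, ph$brain_mask, field_prep_params(), vs)
  expect_equal(F2[ph$brain_mask], Fhat[ph$brain_mask], tolerance = 1e-10)
})

test_that("correct_receive divides inside the mask and rejects zero fields", {
  ph <- small_phantom()
  F <- small_fields()$rx_field
  expect_equal(correct_receive(F, F, ph$brain_mask)[ph$brain_mask],
               rep(1, sum(ph$brain_mask)))
  Fbad <- F; Fbad[which(ph$brain_mask)[1]] <- 0
  expect_error(correct_receive(F, Fbad, ph$brain_mask), "zero")
})

test_that("ratio map is exact arithmetic and invariant to shared fields", {
  ph <- small_phantom()
  m <- ph$brain_mask
  a <- array(2, dim(m)); b <- array(0.5, dim(m))
  r <- ratio_map(a, b, m)
  expect_true(all(r[m] == 4))
  expect_true(all(r[!m] == 0))

  set.seed(21)
  t1w <- array(runif(length(m), 0.5, 2), dim(m))
  t2w <- array(runif(length(m), 0.5, 2), dim(m))
  F <- array(runif(length(m), 0.5, 3), dim(m))
  expect_equal(ratio_map(F * t1w, F * t2w, m), ratio_map(t1w, t2w, m),
               tolerance = 1e-14)
  expect_identical(ratio_map(t1w, t1w, m)[m], rep(1, sum(m)))

  # receive correction of both images cancels in the ratio (to float tol)
  Fhat <- estimate_receive_field(t1w, t2w, m, field_prep_params(), ph$voxel_size_mm)
  r0 <- ratio_map(t1w, t2w, m)
  r1 <- ratio_map(correct_receive(t1w, Fhat, m), correct_receive(t2w, Fhat, m), m)
  expect_equal(r1[m], r0[m], tolerance = 1e-12)

  t2w_bad <- t2w; t2w_bad[which(m)[5]] <- 0
  rb <- ratio_map(t1w, t2w_bad, m)
  expect_identical(attr(rb, "n_invalid"), 1L)
  expect_true(is.nan(rb[which(m)[5]]))
})

test_that("residual bias correction removes smooth bias, keeps spikes", {
  mesh <- make_planar_mesh(41, 41, 3) # 120 x 120 mm sheet
  n <- nrow(mesh$vertices)
  ref <- rep(1.5, n)

  expect_identical(residual_bias_correct(ref, ref, mesh, 30), ref)

  # smooth low-order bias of amplitude 0.2: >= 90% removed
  bias <- 0.2 * sin(pi * mesh$vertices[, 1] / 120)
  corr <- residual_bias_correct(ref + bias, ref, mesh, 30)
  inner <- mesh$vertices[, 1] > 15 & mesh$vertices[, 1] < 105 &
    mesh$vertices[, 2] > 15 & mesh$vertices[, 2] < 105
  expect_lt(max(abs(corr - ref)[inner]), 0.02)

  # single-vertex spike is high-frequency content, preserved within 5%
  spike <- rep(0, n); iv <- which(inner)[100]; spike[iv] <- 1
  corr2 <- residual_bias_correct(ref + spike, ref, mesh, 30)
  expect_lt(abs(corr2[iv] - (ref[iv] + 1)) / 1, 0.05)

  expect_error(residual_bias_correct(ref[-1], ref, mesh), "mismatch")
})

test_that("residual bias correction halves transmit-driven parcel deviation", {
  # transmit dependence in the ratio path: parcel means deviate from the
  # b = 1 case; correcting against a clean reference removes >= 50% (RMS)
  ph <- small_phantom()
  surf <- small_surface()
  n0 <- noise_config(noise_frac = 0, b1_noise_sd = 0)
  fc1 <- field_config(b1 = list(center = 1, edge = 1, asym = 0),
                      rx = list(center = 1, edge = 1, asym = 0),
                      b0 = list(amp_hz = 0, width_mm = 25, asym = 0))
  f1 <- make_fields(fc1, ph)
  fb <- make_fields(utils::modifyList(fc1, list(b1 = list(center = 1.1, edge = 0.8, asym = 0))), ph)
  s1 <- simulate_session(ph, f1, noise_cfg = n0, seed = 3)
  sb <- simulate_session(ph, fb, noise_cfg = n0, seed = 3)
  gm <- is_gm_label(ph$label_vol)
  vs <- ph$voxel_size_mm
  mref <- smooth_surface(map_volume_to_surface(
    ratio_map(s1$t1w, s1$t2w, ph$brain_mask), surf$left, gm, vs), surf$left, 4)
  mb <- smooth_surface(map_volume_to_surface(
    ratio_map(sb$t1w, sb$t2w, ph$brain_mask), surf$left, gm, vs), surf$left, 4)
  mbc <- residual_bias_correct(mb, mref, surf$left, 8)
  pm_ref <- parcel_stats(mref, surf$left$labels)$mean
  rms <- function(x) sqrt(mean(x^2))
  dev_raw <- rms(parcel_stats(mb, surf$left$labels)$mean - pm_ref)
  dev_bc <- rms(parcel_stats(mbc, surf$left$labels)$mean - pm_ref)
  expect_lt(dev_bc, 0.5 * dev_raw)
})
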
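test_that("lookup tables expose a monotone branch around the GM anchor", {
  lk <- default_lookup()
  rng <- lookup_branch_range(lk, b = 1)
  expect_lt(rng[1], 0.5)
  expect_gt(rng[2], 2.5)
  expect_true(rng[1] < 1.35 && 1.35 < rng[2])
  # every b row is strictly monotone on its branch
  for (k in c(1, 51, 101)) {
    br <- lk$branch[k, ]
    expect_true(all(diff(lk$uni_table[k, br[1]:br[2]]) < 0))
  }
})

test_that("single-b lookup works and the table is proton-density free", {
  lk1 <- build_lookup(mp2rage_protocol(), b_grid = 1.0)
  inv <- invert_uni(lk1$uni_table[1, 400], b = 2.7, lk1) # b ignored/clamped
  expect_equal(inv$t1, lk1$t1_grid[400], tolerance = 1e-12)
  expect_true(inv$b_clamped)
  # UNI is a ratio: the table cannot depend on any pd scaling by construction
  s <- mp2rage_signal(1.1, 1, mp2rage_protocol())
  expect_equal(uni_combine(2 * s$s1, 2 * s$s2), uni_combine(s$s1, s$s2))
})

test_that("lookup inversion is exact at nodes and round-trips off-grid", {
  lk <- default_lookup()
  # node identity (b exactly on the grid)
  kb <- which(lk$b_grid == 0.8)
  it <- 500
  expect_equal(invert_uni(lk$uni_table[kb, it], 0.8, lk)$t1, lk$t1_grid[it])

  # off-grid round trip at the GM anchor
  s <- mp2rage_signal(1.35, 0.83, mp2rage_protocol())
  inv <- invert_uni(uni_combine(s$s1, s$s2), 0.83, lk)
  expect_lt(abs(inv$t1 - 1.35) / 1.35, 0.005)
  expect_false(inv$clamped)

  # saturated UNI clamps and flags
  invc <- invert_uni(0.5, 1.0, lk)
  expect_true(invc$clamped)
})

test_that("prep_b1 preserves constants and rejects spike outliers", {
  ph <- small_phantom()
  vs <- ph$voxel_size_mm
  d <- ph$grid_shape
  const <- array(0.9, d)
  out <- prep_b1(const, ph$brain_mask, field_prep_params(), vs)
  expect_equal(out, const, tolerance = 1e-10)

  f <- small_fields()
  spiked <- f$b1_tx
  idx <- which(ph$brain_mask)[c(100, 2000, 4000)]
  spiked[idx] <- 0.1
  clean <- prep_b1(spiked, ph$brain_mask, field_prep_params(), vs)
  expect_gt(cor(clean[ph$brain_mask], f$b1_tx[ph$brain_mask]), 0.99)
  # the spikes themselves are repaired towards the smooth field
  expect_true(all(abs(clean[idx] - f$b1_tx[idx]) < 0.15))
})

test_that("prep_b1 ignores values outside the mask", {
  ph <- small_phantom(); f <- small_fields()
  vs <- ph$voxel_size_mm
  a <- f$b1_tx
  b <- f$b1_tx
  b[!ph$brain_mask] <- 17 # garbage outside the mask
  ca <- prep_b1(a, ph$brain_mask, field_prep_params(), vs)
  cb <- prep_b1(b, ph$brain_mask, field_prep_params(), vs)
  expect_equal(ca[ph$brain_mask], cb[ph$brain_mask], tolerance = 1e-10)
})

test_that("noise-free end-to-end fit recovers R1 inside the lookup branch", {
  ph <- small_phantom()
  f1 <- make_fields(field_config(b1 = list(center = 1, edge = 1, asym = 0),
                                 rx = list(center = 1, edge = 1, asym = 0),
                                 b0 = list(amp_hz = 0, width_mm = 25, asym = 0)), ph)
  ses <- simulate_session(ph, f1, noise_cfg = noise_config(noise_frac = 0, b1_noise_sd = 0),
                          seed = 2)
  lk <- default_lookup()
  fit <- fit_r1_volume(ses$uni, f1$b1_tx, lk, ph$brain_mask)
  tissue <- ph$label_vol == 1L | is_gm_label(ph$label_vol) # WM + GM: T1 in branch
  rel <- abs(1 / fit$r1_vol[tissue] - ph$t1_vol[tissue]) / ph$t1_vol[tissue]
  expect_lt(max(rel), 0.005)
  # CSF (T1 = 4 s) lies beyond the invertible branch at b = 1: its UNI value
  # folds back onto the branch, so the estimate cannot exceed the branch end
  expect_true(all(fit$t1_vol[ph$label_vol == 2L] < lookup_branch_range(lk, 1)[2] + 0.05))
  # masked-out voxels are zero (or NaN on request)
  expect_true(all(fit$r1_vol[!ph$brain_mask] == 0))
  fitn <- fit_r1_volume(ses$uni, f1$b1_tx, lk, ph$brain_mask, na_outside = TRUE)
  expect_true(all(is.nan(fitn$r1_vol[!ph$brain_mask])))
  expect_error(fit_r1_volume(ses$uni, f1$b1_tx, lk, ph$brain_mask,
                             protocol = mp2rage_protocol(alpha1 = 5)),
               "mismatch")
})

test_that("skipping the B1 correction inflates T1 error monotonically in |b-1|", {
  lk <- default_lookup()
  p <- mp2rage_protocol()
  grid <- expand.grid(t1 = seq(0.8, 2.0, by = 0.2), b = seq(0.7, 1.3, by = 0.05))
  s <- mp2rage_signal(grid$t1, grid$b, p)
  uni <- uni_combine(s$s1, s$s2)
  corr <- invert_uni(uni, grid$b, lk)$t1
  uncorr <- invert_uni(uni, 1, lk)$t1
  rel_c <- abs(corr - grid$t1) / grid$t1
  rel_u <- abs(uncorr - grid$t1) / grid$t1
  expect_gt(median(rel_u), median(rel_c))
  expect_gt(sqrt(mean(rel_u^2)), 5 * sqrt(mean(rel_c^2)))
  # error grows with transmit miscalibration (median over T1 at each b)
  med_by_b <- tapply(rel_u, abs(round(grid$b - 1, 10)), median)
  expect_gt(cor(med_by_b, as.numeric(names(med_by_b)), method = "spearman"), 0.9)
})
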
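## Acquisition simulation: one session produces the two MP2RAGE gradient-echo
## images and their UNI combination, the T1w (MPRAGE) and T2w (SPACE) images,
## and a coarse noisy copy of the transmit field (emulating a low-resolution
## turboFLASH B1 map). A study pairs a test and a retest session per subject.

#' Default protocol set
#'
#' @param kappa B0 coupling strength of the inversion efficiency
#'   (see [inv_eff_b0()]; 0 disables the coupling).
#' @param b0_ref reference B0 offset (Hz) for the coupling.
#' @param ... protocol overrides (`mp2rage`, `mprage`, `space`).
#' @return named list of protocol objects plus coupling parameters.
#' @export
protocol_set <- function(kappa = 0, b0_ref = 100, ...) {
  utils::modifyList(
    list(mp2rage = mp2rage_protocol(), mprage = mprage_protocol(),
         space = space_protocol(), kappa = kappa, b0_ref = b0_ref),
    list(...))
}

#' Default noise configuration
#'
#' Gaussian noise is added to each magnitude image with a standard deviation
#' expressed as a fraction of the image's mean absolute brain signal
#' (default 2%, a high-SNR 3T regime). The measured B1 map is block-averaged
#' at 4x coarser resolution with 2% absolute noise, matching the coarse
#' turboFLASH calibration scan. The optional motion surrogate multiplies an
#' image with a smooth low-order ripple (no k-space simulation).
#'
#' @param ... overrides.
#' @return named list.
#' @export
noise_config <- function(...) {
  utils::modifyList(list(noise_frac = 0.02, b1_noise_sd = 0.02,
                         b1_down_factor = 4L, rician = FALSE,
                         motion = FALSE, motion_amp = 0.05), list(...))
}

.add_noise <- function(img, frac, mask, rician = FALSE) {
  if (frac < 0) stop("negative noise SD")
  if (frac == 0) return(img)
  sdv <- frac * mean(abs(img[mask]))
  n1 <- array(rnorm(length(img), sd = sdv), dim(img))
  if (!rician) return(img + n1)
  n2 <- array(rnorm(length(img), sd = sdv), dim(img))
  sign(img + n1) * sqrt((img + n1)^2 + n2^2)
}

.motion_ripple <- function(d, vs, amp) {
  ## smooth low-order multiplicative ripple with random phases
  ph <- stats::runif(3, 0, 2 * pi)
  x <- 2 * pi * (seq_len(d[1]) - 0.5) / d[1]
  y <- 2 * pi * (seq_len(d[2]) - 0.5) / d[2]
  z <- 2 * pi * (seq_len(d[3]) - 0.5) / d[3]
  X <- array(rep(x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  1 + amp * sin(2 * X + ph[1]) * sin(Y + ph[2]) * sin(Z + ph[3])
}

#' Simulate one acquisition session
#'
#' Voxelwise signals are computed from the phantom's local (T1, T2, PD) and
#' the field set's (b, F_rx, B0) through the closed-form signal models. The
#' UNI image is formed from the noisy gradient-echo images, so it inherits
#' their noise but none of the proton-density or receive-bias weighting.
#'
#' @param phantom an `mp2r_phantom`.
#' @param fields an `mp2r_fields`.
#' @param protocols a [protocol_set()].
#' @param noise_cfg a [noise_config()].
#' @param seed integer RNG seed (reproducibility contract: identical
#'   arguments and seed give bitwise-identical output).
#' @param tag session tag, e.g. `"test"` or `"retest"`.
#' @return object of class `mp2r_session` with volumes `mp2rage_s1`,
#'   `mp2rage_s2`, `uni`, `t1w`, `t2w`, `b1_measured` (coarser grid) and
#'   bookkeeping fields.
#' @export
simulate_session <- function(phantom, fields, protocols = protocol_set(),
                             noise_cfg = noise_config(), seed = 1,
                             tag = "test") {
  for (nm in c("mp2rage", "mprage", "space"))
    if (is.null(protocols[[nm]])) stop("missing protocol: ", nm)
  ncfg <- utils::modifyList(noise_config(), noise_cfg)
  if (ncfg$noise_frac < 0 || ncfg$b1_noise_sd < 0) stop("negative noise SD")
  set.seed(seed)
  ph <- phantom; d <- ph$grid_shape
  mask <- ph$brain_mask
  idx <- which(mask)
  t1 <- ph$t1_vol[idx]; t2 <- ph$t2_vol[idx]; pd <- ph$pd_vol[idx]
  b <- fields$b1_tx[idx]; rx <- fields$rx_field[idx]; b0 <- fields$b0_off[idx]
  eff <- inv_eff_b0(b0, protocols$mp2rage$inv_eff, protocols$kappa,
                    protocols$b0_ref)

  s <- mp2rage_signal(t1, b, protocols$mp2rage, inv_eff = eff)
  s1 <- array(0, d); s2 <- array(0, d)
  s1[idx] <- rx * pd * s$s1
  s2[idx] <- rx * pd * s$s2
  eff_m <- inv_eff_b0(b0, protocols$mprage$inv_eff, protocols$kappa,
                      protocols$b0_ref)
  t1w <- array(0, d)
  t1w[idx] <- rx * mprage_signal(t1, pd, b, protocols$mprage, inv_eff = eff_m)
  t2w <- array(0, d)
  t2w[idx] <- rx * space_signal(t1, t2, pd, b, protocols$space)

  if (ncfg$motion) {
    s1 <- s1 * .motion_ripple(d, ph$voxel_size_mm, ncfg$motion_amp)
    s2 <- s2 * .motion_ripple(d, ph$voxel_size_mm, ncfg$motion_amp)
    t1w <- t1w * .motion_ripple(d, ph$voxel_size_mm, ncfg$motion_amp)
    t2w <- t2w * .motion_ripple(d, ph$voxel_size_mm, ncfg$motion_amp)
  }
  s1 <- .add_noise(s1, ncfg$noise_frac, mask, ncfg$rician)
  s2 <- .add_noise(s2, ncfg$noise_frac, mask, ncfg$rician)
  t1w <- .add_noise(t1w, ncfg$noise_frac, mask, ncfg$rician)
  t2w <- .add_noise(t2w, ncfg$noise_frac, mask, ncfg$rician)
  uni <- array(uni_combine(s1, s2, undefined = "zero"), d)

  f <- as.integer(ncfg$b1_down_factor)
  if (any(d %% f != 0)) stop("grid not divisible by b1 downsampling factor")
  b1m <- block_downsample_3d(fields$b1_tx, f)
  if (ncfg$b1_noise_sd > 0)
    b1m <- b1m + array(rnorm(length(b1m), sd = ncfg$b1_noise_sd), dim(b1m))

  structure(list(mp2rage_s1 = s1, mp2rage_s2 = s2, uni = uni,
                 t1w = t1w, t2w = t2w, b1_measured = b1m,
                 b1_down_factor = f, tag = tag, seed = seed,
                 voxel_size_mm = ph$voxel_size_mm),
            class = "mp2r_session")
}

#' Draw subject-specific parcel T1 values
#'
#' Adds independent Gaussian jitter (SD `jitter_sd` seconds) to each
#' parcel's grey-matter T1; with `symmetric = TRUE` the same draw is applied
#' to both hemispheres.
#'
#' @param base_t1 per-parcel T1 vector (s).
#' @param jitter_sd between-subject SD (s).
#' @param symmetric share the draw across hemispheres.
#' @return list `list(left =, right =)` of per-parcel T1 vectors.
#' @export
jitter_parcel_t1 <- function(base_t1, jitter_sd, symmetric = TRUE) {
  l <- base_t1 + rnorm(length(base_t1), sd = jitter_sd)
  r <- if (symmetric) l else base_t1 + rnorm(length(base_t1), sd = jitter_sd)
  l <- pmax(l, 0.2); r <- pmax(r, 0.2) # keep physical
  list(left = l, right = r)
}

#' Default study configuration
#'
#' 14 subjects at the desk scale (64^3 grid, 2 mm voxels, 2562 vertices per
#' hemisphere, 12 parcels per hemisphere). Test and retest share each
#' subject's tissue ground truth; the retest differs by noise realization
#' and a small perturbation of the transmit-field parameters.
#'
#' @param ... overrides (nested lists are merged).
#' @return named list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_subjects = 14L,
    seed = 1L,
    jitter_sd = 0.03,          # between-subject parcel T1 SD (s)
    symmetric_jitter = TRUE,
    retest_field_sd = 0.02,    # perturbation of b1 center/edge at retest
    phantom = phantom_config(),
    fields = field_config(),
    surface = surface_config(n_vertices = 2562L),
    protocols = protocol_set(),
    noise = noise_config(),
    residual_bc_fwhm_mm = 8,   # desk-scale analogue of the 30 mm default
    map_fwhm_mm = 4,
    toggles = list(receive_correction = TRUE, residual_bc = TRUE,
                   b1_correction = TRUE)
  )
  structure(utils::modifyList(cfg, list(...)), class = "study_config")
}

#' Generate a multi-subject test-retest study
#'
#' Each subject receives a distinct tissue draw ([jitter_parcel_t1()]);
#' test and retest sessions share it but differ in noise realization and,
#' optionally, in the transmit field parameters.
#'
#' @param config a [study_config()].
#' @return object of class `mp2r_study`: `subjects` (list of
#'   `subject`/`phantom`/`test`/`retest`), shared `phantom_base`, `fields`,
#'   `surface`, and the `config` (the manifest).
#' @export
make_study <- function(config = study_config()) {
  cfg <- if (inherits(config, "study_config")) config
         else do.call(study_config, config)
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  set.seed(cfg$seed)
  ph0 <- make_phantom(cfg$phantom)
  fields <- make_fields(cfg$fields, ph0)
  surf <- make_surface_model(cfg$surface, ph0)
  subjects <- vector("list", cfg$n_subjects)
  seeds <- sample.int(.Machine$integer.max - 1L, 2 * cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    t1s <- jitter_parcel_t1(ph0$parcel_t1, cfg$jitter_sd, cfg$symmetric_jitter)
    ph_s <- set_parcel_t1(ph0, t1s)
    fields_rt <- fields
    if (cfg$retest_field_sd > 0) {
      fc <- cfg$fields
      fc$b1$center <- fc$b1$center + rnorm(1, sd = cfg$retest_field_sd)
      fc$b1$edge <- max(fc$b1$edge + rnorm(1, sd = cfg$retest_field_sd), 0.05)
      fields_rt <- make_fields(fc, ph0)
    }
    subjects[[s]] <- list(
      subject = s,
      parcel_t1 = t1s,
      phantom = ph_s,
      test = simulate_session(ph_s, fields, cfg$protocols, cfg$noise,
                              seed = seeds[2 * s - 1], tag = "test"),
      retest = simulate_session(ph_s, fields_rt, cfg$protocols, cfg$noise,
                                seed = seeds[2 * s], tag = "retest"),
      fields_retest = fields_rt)
  }
  structure(list(subjects = subjects, phantom_base = ph0, fields = fields,
                 surface = surf, config = cfg),
            class = "mp2r_study")
}
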
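## End-to-end driver: simulate a study, run both map-construction pipelines,
## build surface maps, run the statistical battery and write a deterministic
## report (CSV tables + JSON summary).

#' Surface maps of one session (both methods, both hemispheres)
#'
#' Runs the R1 pipeline (B1 prep, lookup inversion) and the ratio pipeline
#' (receive-field estimation/correction, ratio) on a simulated session, then
#' samples both volumes onto the mid-thickness surfaces and smooths them.
#'
#' @param session an `mp2r_session`.
#' @param phantom the subject's `mp2r_phantom` (grid/mask/labels).
#' @param surface the shared `mp2r_surface`.
#' @param lookup an `mp2rage_lookup`.
#' @param config a [study_config()].
#' @return list with per-hemisphere vectors `r1` and `ratio` (list(L =, R =))
#'   plus the fitted volumes.
#' @export
session_surface_maps <- function(session, phantom, surface, lookup, config) {
  cfg <- config; ph <- phantom
  mask <- ph$brain_mask; vs <- ph$voxel_size_mm
  fp <- field_prep_params()
  b1_clean <- if (isTRUE(cfg$toggles$b1_correction))
    prep_b1(session$b1_measured, mask, fp, vs, session$b1_down_factor)
  else array(1, dim(mask))
  fit <- fit_r1_volume(session$uni, b1_clean, lookup, mask)

  t1w <- session$t1w; t2w <- session$t2w
  if (isTRUE(cfg$toggles$receive_correction)) {
    Fhat <- estimate_receive_field(t1w, t2w, mask, fp, vs)
    t1w <- correct_receive(t1w, Fhat, mask)
    t2w <- correct_receive(t2w, Fhat, mask)
  }
  ratio <- ratio_map(t1w, t2w, mask)

  gm <- is_gm_label(ph$label_vol)
  sp <- smoothing_params(map_fwhm_mm = cfg$map_fwhm_mm)
  samp <- function(vol) {
    lapply(list(L = surface$left, R = surface$right), function(mesh) {
      m <- map_volume_to_surface(vol, mesh, gm, vs, sp)
      smooth_surface(m, mesh, sp$map_fwhm_mm)
    })
  }
  list(r1 = samp(fit$r1_vol), ratio = samp(ratio),
       r1_vol = fit$r1_vol, ratio_vol = ratio, b1_clean = b1_clean)
}

.nominal_reference <- function(config, phantom, surface, lookup) {
  ## external-atlas stand-in: ratio surface map of a noise-free session of
  ## the base phantom under nominal fields (b = 1, F_rx = 1, no B0)
  fc <- field_config(b1 = list(center = 1, edge = 1, asym = 0),
                     rx = list(center = 1, edge = 1, asym = 0),
                     b0 = list(amp_hz = 0, width_mm = 25, asym = 0))
  fields0 <- make_fields(fc, phantom)
  ses0 <- simulate_session(phantom, fields0, config$protocols,
                           noise_config(noise_frac = 0, b1_noise_sd = 0),
                           seed = 1L, tag = "reference")
  cfg0 <- config
  cfg0$toggles$b1_correction <- TRUE
  session_surface_maps(ses0, phantom, surface, lookup, cfg0)
}

.parcel_means <- function(map, labels) {
  st <- parcel_stats(map, labels)
  setNames(st$mean, st$parcel)
}

#' Run the full study pipeline
#'
#' Simulate -> fit R1 -> fit ratio -> surface maps -> statistical battery.
#' Deterministic given the config seed. The ratio method is analysed both
#' with (`ratio_bc`) and without (`ratio_nonbc`) residual bias correction,
#' mirroring the BC / non-BC contrast; the R1 method is never
#' residual-bias-corrected.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory: if given, [build_report()] writes the
#'   report tables there.
#' @return list of class `mp2r_comparison` with the group statistics
#'   (regressions, deviation summaries, effect sizes, hemispheric analyses),
#'   the per-method map matrices and the manifest.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  cfg <- if (inherits(config, "study_config")) config
         else do.call(study_config, config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    timings[[nm]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  lookup <- build_lookup(cfg$protocols$mp2rage)
  tick("lookup")
  study <- make_study(cfg)
  tick("simulate")
  surf <- study$surface
  labels_h <- surf$left$labels # identical ordering on the right
  ref <- .nominal_reference(cfg, study$phantom_base, surf, lookup)
  tick("reference")

  nsub <- length(study$subjects)
  methods <- c("r1", "ratio_bc", "ratio_nonbc")
  maps <- list()
  for (m in methods) for (ses in c("test", "retest"))
    maps[[m]][[ses]] <- list(L = NULL, R = NULL)
  for (s in seq_len(nsub)) {
    sub <- study$subjects[[s]]
    for (ses in c("test", "retest")) {
      sm <- tryCatch(
        session_surface_maps(sub[[ses]], sub$phantom, surf, lookup, cfg),
        error = function(e) stop("stage session_surface_maps failed for subject ",
                                 s, " (", ses, "): ", conditionMessage(e)))
      bc <- list(
        L = residual_bias_correct(sm$ratio$L, ref$ratio$L, surf$left,
                                  cfg$residual_bc_fwhm_mm),
        R = residual_bias_correct(sm$ratio$R, ref$ratio$R, surf$right,
                                  cfg$residual_bc_fwhm_mm))
      for (h in c("L", "R")) {
        maps$r1[[ses]][[h]] <- cbind(maps$r1[[ses]][[h]], sm$r1[[h]])
        maps$ratio_nonbc[[ses]][[h]] <- cbind(maps$ratio_nonbc[[ses]][[h]], sm$ratio[[h]])
        maps$ratio_bc[[ses]][[h]] <- cbind(maps$ratio_bc[[ses]][[h]], bc[[h]])
      }
    }
  }
  tick("pipelines")

  ## group averages and parcel means
  group <- list(); pmeans <- list()
  for (m in methods) {
    group[[m]] <- lapply(c(test = "test", retest = "retest"), function(ses)
      list(L = rowMeans(maps[[m]][[ses]]$L), R = rowMeans(maps[[m]][[ses]]$R)))
    pmeans[[m]] <- lapply(group[[m]], function(g)
      list(L = .parcel_means(g$L, labels_h), R = .parcel_means(g$R, labels_h)))
  }
  both <- function(pm) c(pm$L, pm$R)

  tr_reg <- lapply(methods, function(m)
    tr_regression(both(pmeans[[m]]$test), both(pmeans[[m]]$retest)))
  names(tr_reg) <- methods

  cross <- list(
    ratio_bc = tr_regression(both(pmeans$r1$test), both(pmeans$ratio_bc$test)),
    ratio_nonbc = tr_regression(both(pmeans$r1$test), both(pmeans$ratio_nonbc$test)))

  deviation <- lapply(methods, function(m) {
    tm <- rbind(maps[[m]]$test$L, maps[[m]]$test$R)
    rm_ <- rbind(maps[[m]]$retest$L, maps[[m]]$retest$R)
    deviation_map(tm, rm_)
  })
  names(deviation) <- methods

  ## per-subject parcel means (test) for cross-subject dispersion
  csd <- lapply(methods, function(m) {
    pm <- vapply(seq_len(nsub), function(s)
      c(.parcel_means(maps[[m]]$test$L[, s], labels_h),
        .parcel_means(maps[[m]]$test$R[, s], labels_h)),
      numeric(2 * surf$n_parcels))
    cross_subject_se(pm)
  })
  names(csd) <- methods

  pairs <- parcel_adjacency(surf$left, labels_h)
  effects <- list()
  for (m in methods) {
    g <- group[[m]]$test$L
    effects[[m]] <- lapply(seq_len(nrow(pairs)), function(k) {
      region_pair_test(g[labels_h == pairs[k, 1]], g[labels_h == pairs[k, 2]])
    })
  }

  lr <- lapply(methods, function(m)
    lr_correlation(pmeans[[m]]$test$L, pmeans[[m]]$test$R))
  names(lr) <- methods

  b1_surf <- lapply(list(L = surf$left, R = surf$right), function(mesh)
    map_volume_to_surface(study$fields$b1_tx, mesh, study$phantom_base$brain_mask,
                          study$phantom_base$voxel_size_mm,
                          smoothing_params(map_fwhm_mm = cfg$map_fwhm_mm)))
  asym <- lapply(methods, function(m)
    tryCatch(asymmetry_vs_b1(group[[m]]$test$L, group[[m]]$test$R,
                             b1_surf$L, b1_surf$R),
             error = function(e) NA_real_)) # exactly symmetric B1: undefined
  names(asym) <- methods
  tick("stats")

  res <- structure(list(
    tr_regression = tr_reg, cross_method = cross, deviation = deviation,
    cross_subject_se = csd, effects = effects, pairs = pairs, lr = lr,
    asymmetry_vs_b1 = asym, parcel_means = pmeans, group_maps = group,
    maps = maps, b1_surface = b1_surf, labels = labels_h,
    n_subjects = nsub, config = cfg, timings = timings),
    class = "mp2r_comparison")
  if (!is.null(out_dir)) res$report <- build_report(res, out_dir)
  res
}

.fmt <- function(x) formatC(x, digits = 10, format = "g")

#' Write the comparison report (CSV tables + JSON summary)
#'
#' Deterministic output: stable row ordering and fixed float formatting, so
#' identical inputs produce byte-identical files.
#'
#' @param res an `mp2r_comparison` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return list of class `mp2r_report`: `files` (paths) and `hash`
#'   (MD5 of the concatenated tables).
#' @export
build_report <- function(res, out_dir) {
  required <- c("tr_regression", "cross_method", "deviation", "effects",
                "lr", "asymmetry_vs_b1", "parcel_means")
  missing <- required[!vapply(required, function(f)
    !is.null(res[[f]]) && length(res[[f]]) > 0, logical(1))]
  if (length(missing))
    stop("missing report inputs: ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  wr <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], .fmt)
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  methods <- names(res$tr_regression)

  reg_df <- function(lst) data.frame(
    method = names(lst),
    slope = vapply(lst, `[[`, numeric(1), "slope"),
    intercept = vapply(lst, `[[`, numeric(1), "intercept"),
    r_squared = vapply(lst, `[[`, numeric(1), "r_squared"),
    n_points = vapply(lst, `[[`, numeric(1), "n_points"), row.names = NULL)
  wr(reg_df(res$tr_regression), "tr_regression.csv")
  wr(reg_df(res$cross_method), "cross_method_regression.csv")
  wr(reg_df(res$lr), "lr_regression.csv")

  dev_df <- do.call(rbind, lapply(methods, function(m) {
    p <- res$deviation[[m]]$percentiles
    data.frame(method = m, p25 = p[["p25"]], p50 = p[["p50"]],
               p75 = p[["p75"]], p98 = p[["p98"]],
               range = res$deviation[[m]]$range)
  }))
  wr(dev_df, "deviation_percentiles.csv")

  eff_df <- do.call(rbind, lapply(methods, function(m) {
    do.call(rbind, lapply(seq_along(res$effects[[m]]), function(k) {
      e <- res$effects[[m]][[k]]
      data.frame(method = m, parcel_a = res$pairs[k, 1],
                 parcel_b = res$pairs[k, 2], t = e$t_statistic, dof = e$dof,
                 cohens_d = e$cohens_d, p_value = e$p_value,
                 size_class = e$size_class)
    }))
  }))
  wr(eff_df, "effect_sizes.csv")

  pm_df <- do.call(rbind, lapply(methods, function(m) {
    pm <- res$parcel_means[[m]]$test
    data.frame(method = m,
               hemi = rep(c("L", "R"), each = length(pm$L)),
               parcel = c(names(pm$L), names(pm$R)),
               mean_test = c(pm$L, pm$R),
               mean_retest = c(res$parcel_means[[m]]$retest$L,
                               res$parcel_means[[m]]$retest$R),
               se_across_subjects = res$cross_subject_se[[m]],
               row.names = NULL)
  }))
  wr(pm_df, "parcel_means.csv")

  asym_df <- data.frame(method = methods,
                        asym_vs_b1_r = unlist(res$asymmetry_vs_b1))
  wr(asym_df, "asymmetry_correlation.csv")

  summary <- list(
    n_subjects = res$n_subjects,
    config_hash = unname(tools::md5sum(
      {tmp <- tempfile(); writeLines(
        jsonlite::toJSON(.serializable_config(res$config), auto_unbox = TRUE,
                         digits = NA), tmp); tmp})),
    cross_method_r2 = lapply(res$cross_method, `[[`, "r_squared"),
    lr_r2 = lapply(res$lr, `[[`, "r_squared"),
    deviation_p50 = lapply(res$deviation, function(d) unname(d$percentiles[["p50"]])))
  ## timings stay on the in-memory object only: report files are byte-stable
  pj <- file.path(out_dir, "summary.json")
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA, pretty = TRUE), pj)
  files <- c(files, pj)

  hash <- unname(tools::md5sum({
    tmp <- tempfile()
    writeLines(unlist(lapply(sort(files), readLines)), tmp)
    tmp
  }))
  structure(list(files = files, hash = hash), class = "mp2r_report")
}

.serializable_config <- function(cfg) {
  rapply(unclass(cfg), function(x) x, how = "list")
}
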
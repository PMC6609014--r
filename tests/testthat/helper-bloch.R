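# Discrete-time Bloch-stepping oracle: pulse-by-pulse, interval-by-interval
# longitudinal evolution iterated to steady state. Independent of the
# package's closed-form fixed-point solution; used only in tests.
# Vectorized over (t1, b) combinations.

bloch_mp2rage <- function(t1, b, p, inv_eff = NULL, periods = 25) {
  tm <- block_timing(p)
  if (is.null(inv_eff)) inv_eff <- p$inv_eff
  n <- max(length(t1), length(b))
  t1 <- rep_len(t1, n); b <- rep_len(b, n); inv_eff <- rep_len(inv_eff, n)
  e1 <- exp(-p$tr_gre / t1)
  a1 <- b * p$alpha1 * pi / 180
  a2 <- b * p$alpha2 * pi / 180
  rec <- function(mz, t) 1 - (1 - mz) * exp(-t / t1)
  mz <- rep(1, n); s1 <- s2 <- rep(NA_real_, n)
  ntot <- p$n_before + p$n_after
  for (it in seq_len(periods)) {
    mz <- -inv_eff * mz
    mz <- rec(mz, tm$TA)
    for (k in seq_len(ntot)) {
      if (k == p$n_before + 1) s1 <- sin(a1) * mz
      mz <- mz * cos(a1) * e1 + (1 - e1)
    }
    mz <- rec(mz, tm$TB)
    for (k in seq_len(ntot)) {
      if (k == p$n_before + 1) s2 <- sin(a2) * mz
      mz <- mz * cos(a2) * e1 + (1 - e1)
    }
    mz <- rec(mz, tm$TC)
  }
  list(s1 = s1, s2 = s2)
}

bloch_mprage <- function(t1, pd, b, p, periods = 25) {
  n <- max(length(t1), length(b))
  t1 <- rep_len(t1, n); b <- rep_len(b, n); pd <- rep_len(pd, n)
  e1 <- exp(-p$tr_gre / t1)
  al <- b * p$alpha * pi / 180
  ta <- p$ti - p$n_before * p$tr_gre
  td <- p$tr - p$ti - p$n_after * p$tr_gre
  rec <- function(mz, t) 1 - (1 - mz) * exp(-t / t1)
  mz <- rep(1, n); s <- rep(NA_real_, n)
  for (it in seq_len(periods)) {
    mz <- -p$inv_eff * mz
    mz <- rec(mz, ta)
    for (k in seq_len(p$n_before + p$n_after)) {
      if (k == p$n_before + 1) s <- sin(al) * mz
      mz <- mz * cos(al) * e1 + (1 - e1)
    }
    mz <- rec(mz, td)
  }
  pd * s
}

# relative error of a signal pair against the oracle, on the pair scale
# (s2 crosses zero inside the tested grid, so a pointwise relative error
# is undefined there)
pair_rel_err <- function(cf, bl) {
  sqrt((cf$s1 - bl$s1)^2 + (cf$s2 - bl$s2)^2) / sqrt(bl$s1^2 + bl$s2^2)
}
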
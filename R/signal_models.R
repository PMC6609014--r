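DEG2RAD <- pi / 180

#' Gaussian kernel width conversions
#'
#' Convert between the full width at half maximum (FWHM) and the standard
#' deviation of a Gaussian kernel, `sigma = FWHM / (2 * sqrt(2 * log(2)))`.
#' A 4 mm FWHM corresponds to sigma ~ 1.698 mm, 1 mm FWHM to ~ 0.425 mm.
#'
#' @param fwhm,sigma kernel width in any length unit.
#' @return the converted width, same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_sigma
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

#' Excitation bookkeeping under partial Fourier slice encoding
#'
#' With `n_encodes` nominal slice encodes and a partial Fourier fraction
#' `pf`, only `n_encodes * pf` excitations are played out, starting from the
#' early edge of k-space, and the k-space centre sits at encode
#' `n_encodes / 2`. The number of excitations before the centre therefore is
#' `n_encodes * pf - n_encodes / 2` (e.g. 256 encodes at 6/8 give 64 before
#' and 128 after the centre). This number fixes the effective inversion time
#' of a magnetization-prepared readout with linear encoding order.
#'
#' @param n_encodes nominal number of slice encodes (even integer).
#' @param pf partial Fourier fraction in (0.5, 1].
#' @return list with `before` and `after` excitation counts.
#' @export
partial_fourier_excitations <- function(n_encodes, pf) {
  stopifnot(length(n_encodes) == 1, length(pf) == 1)
  if (n_encodes <= 0 || n_encodes %% 2 != 0)
    stop("n_encodes must be a positive even integer")
  if (pf <= 0.5 || pf > 1)
    stop("partial Fourier fraction must be in (0.5, 1]")
  acquired <- round(n_encodes * pf)
  after <- n_encodes / 2
  before <- acquired - after
  list(before = before, after = after)
}

## ---------------------------------------------------------------------------
## Protocol constructors
## ---------------------------------------------------------------------------

#' MP2RAGE protocol parameters
#'
#' Defaults reproduce a 3T protocol with TR/TI1/TI2 = 5.5/0.7/2.5 s, flip
#' angles 6/4 degrees, 7.5 ms echo spacing and 64/128 excitations before and
#' after the k-space centre (256 slice encodes with 6/8 partial Fourier).
#'
#' @param tr_mp2rage full sequence repetition time (s).
#' @param ti1,ti2 inversion times of the two gradient-echo blocks (s),
#'   defined at the k-space centre.
#' @param alpha1,alpha2 excitation flip angles (degrees).
#' @param tr_gre echo spacing between excitations within a block (s).
#' @param n_before,n_after excitations before/after the k-space centre.
#' @param inv_eff inversion efficiency in (0, 1].
#' @return object of class `mp2rage_protocol`.
#' @export
mp2rage_protocol <- function(tr_mp2rage = 5.5, ti1 = 0.7, ti2 = 2.5,
                             alpha1 = 6, alpha2 = 4, tr_gre = 0.0075,
                             n_before = 64, n_after = 128, inv_eff = 0.96) {
  p <- list(tr_mp2rage = tr_mp2rage, ti1 = ti1, ti2 = ti2,
            alpha1 = alpha1, alpha2 = alpha2, tr_gre = tr_gre,
            n_before = as.integer(n_before), n_after = as.integer(n_after),
            inv_eff = inv_eff)
  with(p, {
    stopifnot(tr_mp2rage > 0, ti1 > 0, ti2 > ti1, tr_gre > 0)
    if (n_before + n_after < 1) stop("need at least one excitation per block")
    if (inv_eff <= 0 || inv_eff > 1) stop("inv_eff must be in (0, 1]")
  })
  structure(p, class = "mp2rage_protocol")
}

#' MPRAGE protocol parameters
#'
#' Defaults follow an HCP-style T1w protocol: TR = 2.2 s, TI = 1.1 s,
#' 11 degree flip angle, 9.3 ms echo spacing, 88 excitations on either side
#' of the k-space centre (linear encoding assumed).
#'
#' @inheritParams mp2rage_protocol
#' @param tr repetition time of the full inversion cycle (s).
#' @param ti inversion time at the k-space centre (s).
#' @param alpha excitation flip angle (degrees).
#' @return object of class `mprage_protocol`.
#' @export
mprage_protocol <- function(tr = 2.2, ti = 1.1, alpha = 11, tr_gre = 0.0093,
                            n_before = 88, n_after = 88, inv_eff = 0.96) {
  p <- list(tr = tr, ti = ti, alpha = alpha, tr_gre = tr_gre,
            n_before = as.integer(n_before), n_after = as.integer(n_after),
            inv_eff = inv_eff)
  stopifnot(p$tr > 0, p$ti > 0, p$tr_gre > 0)
  if (p$inv_eff <= 0 || p$inv_eff > 1) stop("inv_eff must be in (0, 1]")
  ta <- p$ti - p$n_before * p$tr_gre
  td <- p$tr - p$ti - p$n_after * p$tr_gre
  if (ta < 0) stop("infeasible MPRAGE timing: ti - n_before*tr_gre < 0")
  if (td < 0) stop("infeasible MPRAGE timing: tr - ti - n_after*tr_gre < 0")
  structure(p, class = "mprage_protocol")
}

#' SPACE (T2w turbo spin echo) protocol parameters
#'
#' Phenomenological model of a variable-flip-angle 3D turbo spin echo:
#' `signal = pd * (1 - exp(-(tr - te_eff)/t1)) * exp(-te_eff/t2) * b^tx_exponent`.
#' `te_eff` acts as a contrast-equivalent echo time; `tx_exponent` isolates a
#' switchable residual transmit (B1+) dependence of the T2w image.
#'
#' @param tr repetition time (s).
#' @param te_eff effective echo time (s).
#' @param tx_exponent phenomenological transmit-field exponent.
#' @return object of class `space_protocol`.
#' @export
space_protocol <- function(tr = 3.2, te_eff = 0.569, tx_exponent = 1.0) {
  stopifnot(tr > 0, te_eff >= 0, te_eff < tr)
  structure(list(tr = tr, te_eff = te_eff, tx_exponent = tx_exponent),
            class = "space_protocol")
}

#' Free-recovery block timing of an MP2RAGE period
#'
#' Splits one MP2RAGE repetition into the three free-recovery gaps that
#' surround the two gradient-echo blocks: `TA` before the first block, `TB`
#' between blocks, `TC` after the second block. The inversion times are
#' defined at the k-space centre, i.e. `n_before` excitations into each block.
#'
#' @param protocol an [mp2rage_protocol()].
#' @return list with elements `TA`, `TB`, `TC` (seconds).
#' @export
block_timing <- function(protocol) {
  stopifnot(inherits(protocol, "mp2rage_protocol"))
  n <- protocol$n_before + protocol$n_after
  ta <- protocol$ti1 - protocol$n_before * protocol$tr_gre
  tb <- protocol$ti2 - protocol$ti1 - n * protocol$tr_gre
  tc <- protocol$tr_mp2rage - protocol$ti2 - protocol$n_after * protocol$tr_gre
  if (ta < 0) stop("infeasible protocol: TA = ti1 - n_before*tr_gre is negative")
  if (tb < 0) stop("infeasible protocol: TB = ti2 - ti1 - n*tr_gre is negative")
  if (tc < 0) stop("infeasible protocol: TC = tr - ti2 - n_after*tr_gre is negative")
  list(TA = ta, TB = tb, TC = tc)
}

## ---------------------------------------------------------------------------
## Closed-form steady-state signals
##
## Longitudinal magnetization evolves through affine maps Mz -> a*Mz + c
## (M0 = 1). Composing the maps of one period and solving the fixed point
## gives the steady state exactly. All helpers are vectorized over t1, b and
## inv_eff so whole volumes can be simulated in one call.
## ---------------------------------------------------------------------------

## affine map of a GRE train: k pulses of cos(b*alpha) rotation + tr_gre decay
.gre_map <- function(k, cosa, e1) {
  a <- (cosa * e1)^k
  ## geometric series; A -> 1 limit handled for degenerate (t1 = Inf) input
  den <- 1 - cosa * e1
  c_ <- ifelse(abs(den) < 1e-14, k * (1 - e1), (1 - e1) * (1 - a) / den)
  list(a = a, c = c_)
}

.recovery_map <- function(t, t1) {
  e <- exp(-t / t1)
  list(a = e, c = 1 - e)
}

.compose <- function(f, g) { # apply f, then g
  list(a = g$a * f$a, c = g$a * f$c + g$c)
}

#' Steady-state MP2RAGE signals
#'
#' Closed-form longitudinal steady state of the MP2RAGE period: inversion
#' (`Mz -> -inv_eff * Mz`), recovery `TA`, first gradient-echo block
#' (effective flip `b * alpha1`), recovery `TB`, second block (`b * alpha2`),
#' recovery `TC`. Each pulse maps
#' `Mz -> Mz cos(b a) E1 + (1 - E1)`, `E1 = exp(-tr_gre/t1)`. The returned
#' signals are `s_i = sin(b * alpha_i) * Mz` read out immediately before the
#' `(n_before + 1)`-th pulse of block i (the k-space centre), with M0 = 1.
#'
#' @param t1 longitudinal relaxation time (s); vectorized.
#' @param b transmit field scaling (dimensionless); vectorized.
#' @param protocol an [mp2rage_protocol()].
#' @param inv_eff optional per-element inversion efficiency override
#'   (e.g. when coupling to a B0 offset); defaults to `protocol$inv_eff`.
#' @return list with numeric vectors `s1`, `s2`.
#' @export
mp2rage_signal <- function(t1, b, protocol, inv_eff = NULL) {
  stopifnot(inherits(protocol, "mp2rage_protocol"))
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (any(b <= 0)) stop("b must be positive")
  tm <- block_timing(protocol)
  if (is.null(inv_eff)) inv_eff <- protocol$inv_eff
  n <- length(t1) # recycle b / inv_eff against t1
  b <- rep_len(b, n); inv_eff <- rep_len(inv_eff, n)

  e1 <- exp(-protocol$tr_gre / t1)
  cos1 <- cos(b * protocol$alpha1 * DEG2RAD)
  cos2 <- cos(b * protocol$alpha2 * DEG2RAD)
  nb <- protocol$n_before; na <- protocol$n_after; ntot <- nb + na

  inv <- list(a = -inv_eff, c = 0 * inv_eff)
  recA <- .recovery_map(tm$TA, t1)
  blk1 <- .gre_map(ntot, cos1, e1)
  recB <- .recovery_map(tm$TB, t1)
  blk2 <- .gre_map(ntot, cos2, e1)
  recC <- .recovery_map(tm$TC, t1)

  per <- .compose(.compose(.compose(.compose(.compose(inv, recA), blk1), recB), blk2), recC)
  mz0 <- per$c / (1 - per$a) # steady state just before inversion

  to_c1 <- .compose(.compose(inv, recA), .gre_map(nb, cos1, e1))
  s1 <- sin(b * protocol$alpha1 * DEG2RAD) * (to_c1$a * mz0 + to_c1$c)
  to_c2 <- .compose(.compose(.compose(.compose(inv, recA), blk1), recB),
                    .gre_map(nb, cos2, e1))
  s2 <- sin(b * protocol$alpha2 * DEG2RAD) * (to_c2$a * mz0 + to_c2$c)
  list(s1 = s1, s2 = s2)
}

#' Combine the two MP2RAGE signals into the UNI contrast
#'
#' `uni = s1 * s2 / (s1^2 + s2^2)`, bounded in \[-0.5, 0.5\]; independent of
#' proton density and receive bias, which multiply both signals.
#'
#' @param s1,s2 signal vectors.
#' @param undefined what to do where both signals are zero: `"error"`
#'   (default) or `"zero"`.
#' @return numeric vector of UNI values.
#' @export
uni_combine <- function(s1, s2, undefined = c("error", "zero")) {
  undefined <- match.arg(undefined)
  den <- s1^2 + s2^2
  bad <- den == 0
  if (any(bad)) {
    if (undefined == "error") stop("undefined UNI contrast: both signals are zero")
    den[bad] <- 1
  }
  u <- s1 * s2 / den
  u[bad] <- 0
  u
}

#' Steady-state MPRAGE signal
#'
#' Same evolution contract as [mp2rage_signal()] with a single gradient-echo
#' block: inversion, recovery `ti - n_before*tr_gre`, block of
#' `n_before + n_after` pulses at effective flip `b * alpha`, recovery
#' `tr - ti - n_after*tr_gre`. Returns
#' `pd * sin(b*alpha) * Mz` at the k-space centre pulse.
#'
#' @inheritParams mp2rage_signal
#' @param pd proton density (arbitrary units); vectorized.
#' @param protocol an [mprage_protocol()].
#' @return numeric signal vector.
#' @export
mprage_signal <- function(t1, pd, b, protocol, inv_eff = NULL) {
  stopifnot(inherits(protocol, "mprage_protocol"))
  if (any(t1 <= 0)) stop("t1 must be positive")
  if (any(b <= 0)) stop("b must be positive")
  if (is.null(inv_eff)) inv_eff <- protocol$inv_eff
  n <- length(t1)
  b <- rep_len(b, n); pd <- rep_len(pd, n); inv_eff <- rep_len(inv_eff, n)

  ta <- protocol$ti - protocol$n_before * protocol$tr_gre
  td <- protocol$tr - protocol$ti - protocol$n_after * protocol$tr_gre
  e1 <- exp(-protocol$tr_gre / t1)
  cosa <- cos(b * protocol$alpha * DEG2RAD)
  ntot <- protocol$n_before + protocol$n_after

  inv <- list(a = -inv_eff, c = 0 * inv_eff)
  recA <- .recovery_map(ta, t1)
  blk <- .gre_map(ntot, cosa, e1)
  recD <- .recovery_map(td, t1)
  per <- .compose(.compose(.compose(inv, recA), blk), recD)
  mz0 <- per$c / (1 - per$a)
  to_c <- .compose(.compose(inv, recA), .gre_map(protocol$n_before, cosa, e1))
  pd * sin(b * protocol$alpha * DEG2RAD) * (to_c$a * mz0 + to_c$c)
}

#' Phenomenological SPACE (T2w) signal
#'
#' `pd * (1 - exp(-(tr - te_eff)/t1)) * exp(-te_eff/t2) * b^tx_exponent`.
#' No echo-train simulation is attempted; `te_eff` is an apparent echo time
#' and `tx_exponent` a switchable residual transmit dependence.
#'
#' @inheritParams mprage_signal
#' @param t2 (apparent) transverse relaxation time (s); vectorized.
#' @param protocol a [space_protocol()].
#' @return numeric signal vector.
#' @export
space_signal <- function(t1, t2, pd, b, protocol) {
  stopifnot(inherits(protocol, "space_protocol"))
  if (any(t1 <= 0) || any(t2 <= 0)) stop("t1 and t2 must be positive")
  if (any(b <= 0)) stop("b must be positive")
  pd * (1 - exp(-(protocol$tr - protocol$te_eff) / t1)) *
    exp(-protocol$te_eff / t2) * b^protocol$tx_exponent
}

#' Inversion efficiency degraded by B0 offset
#'
#' Optional coupling `eff(b0) = inv_eff * max(0, 1 - kappa * |b0| / b0_ref)`
#' emulating the loss of adiabatic inversion efficiency in regions of large
#' static field offset. `kappa = 0` (default elsewhere) disables the effect.
#'
#' @param b0 static field offset (Hz); vectorized.
#' @param inv_eff nominal inversion efficiency.
#' @param kappa dimensionless coupling strength.
#' @param b0_ref reference offset (Hz) at which the fractional loss is kappa.
#' @return efficiency vector.
#' @export
inv_eff_b0 <- function(b0, inv_eff = 0.96, kappa = 0, b0_ref = 100) {
  stopifnot(b0_ref > 0, kappa >= 0)
  inv_eff * pmax(0, 1 - kappa * abs(b0) / b0_ref)
}
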
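# Spoiled gradient-recalled-echo steady-state signal model.
#
# S(alpha) = M0 (1 - E1) e^(-TE/T2) sin(alpha) / (1 - cos(alpha) E1),
# with E1 = e^(-TR/T1). When TE << T2 the T2 factor is ~1 and drops out
# (the T1-weighted regime); since it is independent of flip angle it only
# rescales the signal, which the VFA fit is invariant to.

deg2rad <- function(deg) deg * pi / 180

# sin/cos of an angle in degrees, exact at the quadrant points
# (cospi(0.5) == 0, so tan(90 deg) never enters a division)
sin_deg <- function(deg) sinpi(deg / 180)
cos_deg <- function(deg) cospi(deg / 180)

#' Spoiled-GRE steady-state signal
#'
#' Evaluates the spoiled gradient-echo signal equation for given proton
#' density, relaxation times and flip angle. When `t2_ms` is `NULL` the
#' T1-weighted simplification (TE << T2, so the T2 decay factor is taken
#' as 1) is used.
#'
#' Vectorized over `alpha_deg` and over `m0`/`t1_ms` (lengths recycled by
#' ordinary R rules).
#'
#' @param m0 Equilibrium magnetization / proton density (arbitrary units, >= 0).
#' @param t1_ms Longitudinal relaxation time, ms (> 0).
#' @param alpha_deg Flip angle(s), degrees, in (0, 90].
#' @param acq An [acquisition_params()] supplying TR and TE.
#' @param t2_ms Transverse relaxation time, ms; `NULL` for the TE << T2
#'   simplification.
#' @return Signal in the units of `m0`.
#' @export
gre_signal <- function(m0, t1_ms, alpha_deg, acq = acquisition_params(),
                       t2_ms = NULL) {
  if (any(m0 < 0)) stop("m0 must be >= 0", call. = FALSE)
  if (any(t1_ms <= 0)) stop("t1_ms must be > 0", call. = FALSE)
  if (acq$tr_ms <= 0) stop("tr_ms must be > 0", call. = FALSE)
  if (any(alpha_deg <= 0 | alpha_deg > 90)) {
    stop("alpha_deg must lie in (0, 90]", call. = FALSE)
  }
  e1 <- exp(-acq$tr_ms / t1_ms)
  s <- m0 * (1 - e1) * sin_deg(alpha_deg) / (1 - cos_deg(alpha_deg) * e1)
  if (!is.null(t2_ms)) {
    if (any(t2_ms <= 0)) stop("t2_ms must be > 0", call. = FALSE)
    s <- s * exp(-acq$te_ms / t2_ms)
  }
  s
}

#' Ernst angle
#'
#' Flip angle maximizing the spoiled-GRE signal for a given T1 and TR:
#' `acos(exp(-TR/T1))`, in degrees.
#'
#' @param t1_ms T1, ms (> 0).
#' @param tr_ms TR, ms (> 0).
#' @return Angle in degrees.
#' @export
ernst_angle <- function(t1_ms, tr_ms) {
  stopifnot(all(t1_ms > 0), all(tr_ms > 0))
  acos(exp(-tr_ms / t1_ms)) * 180 / pi
}
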
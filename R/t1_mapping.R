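#' Variable-flip-angle configuration
#'
#' Two spoiled-GRE flip angles and the repetition time; the preset
#' \code{"paper_vfa"} is 4 and 24 degrees at TR = 16.4 ms. \code{b1Scale}
#' multiplies the nominal flip angles per voxel (actual/nominal flip from a
#' measured B1 map); the default 1 assumes a homogeneous transmit field.
#'
#' @param fa1,fa2 flip angles, degrees (0 < fa1 < fa2 < 90).
#' @param tr repetition time, s.
#' @param b1Scale scalar or 3D array of relative flip-angle scaling.
#' @return Configuration list.
#' @export
vfaConfig <- function(fa1 = 4, fa2 = 24, tr = 0.0164, b1Scale = 1) {
  if (!(fa1 > 0 && fa1 < fa2 && fa2 < 90)) stop("need 0 < fa1 < fa2 < 90")
  if (tr <= 0) stop("tr must be > 0")
  list(fa1 = fa1, fa2 = fa2, tr = tr, b1Scale = b1Scale)
}

#' Spoiled gradient-echo signal
#'
#' Ideal-spoiling SPGR signal equation:
#' \deqn{S = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha},\quad
#'       E_1 = e^{-TR/T_1}}
#'
#' @param m0 equilibrium magnetization (arbitrary units); scalar or array.
#' @param t1 longitudinal relaxation time, s (> 0).
#' @param fa flip angle, degrees.
#' @param tr repetition time, s.
#' @return Signal in the units of \code{m0}.
#' @export
spgrSignal <- function(m0, t1, fa, tr) {
  if (any(t1 <= 0)) stop("t1 must be > 0")
  a <- fa * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Two-point variable-flip-angle T1 fit
#'
#' Per-voxel linearization of the SPGR equation: with
#' \eqn{y = S/\sin\alpha} and \eqn{x = S/\tan\alpha} the two flip angles
#' give a line of slope \eqn{E_1 = e^{-TR/T_1}}, so
#' \eqn{T_1 = -TR/\log(\mathrm{slope})} and \eqn{M_0} follows from the
#' intercept. Voxels with a slope outside (0, 1) (non-physical), or with a
#' degenerate signal pair, are masked (NA).
#'
#' @param s1,s2 GRE magnitude volumes (arrays or vectors) at \code{fa1} and
#'   \code{fa2}.
#' @param config a [vfaConfig()]; \code{b1Scale} is applied to both nominal
#'   flip angles before inversion.
#' @return list with \code{t1} (s), \code{m0} and logical \code{valid},
#'   all shaped like \code{s1}.
#' @examples
#' s1 <- spgrSignal(1, 1.0, 4, 0.0164)
#' s2 <- spgrSignal(1, 1.0, 24, 0.0164)
#' vfaFit(s1, s2)$t1  # 1.0
#' @export
vfaFit <- function(s1, s2, config = vfaConfig()) {
  stopifnot(identical(dim(s1), dim(s2)), length(s1) == length(s2))
  a1 <- config$fa1 * pi / 180 * config$b1Scale
  a2 <- config$fa2 * pi / 180 * config$b1Scale
  if (any((a2 - a1) == 0)) stop("effective flip angles must be distinct")
  y1 <- s1 / sin(a1); x1 <- s1 / tan(a1)
  y2 <- s2 / sin(a2); x2 <- s2 / tan(a2)
  slope <- (y2 - y1) / (x2 - x1)
  valid <- is.finite(slope) & slope > 0 & slope < 1 & (s1 + s2) > 0
  t1 <- ifelse(valid, -config$tr / log(slope), NA_real_)
  e1 <- slope
  m0 <- ifelse(valid, (y1 - x1 * e1) / (1 - e1), NA_real_)
  out <- list(t1 = t1, m0 = m0, valid = valid)
  if (!is.null(dim(s1))) {
    dim(out$t1) <- dim(s1); dim(out$m0) <- dim(s1); dim(out$valid) <- dim(s1)
  }
  out
}
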
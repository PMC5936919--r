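# The recirculating two-reservoir extraction model: extraction factors,
# single-pass module efficiency, closed-form reservoir time course and
# mass-balance metrics.

#' Module extraction factor E
#'
#' E = P Q_s / Q_w: the partition-weighted flow ratio governing how far a
#' single pass through the module can go.
#'
#' @param P partition coefficient, > 0.
#' @param Q_s,Q_w organic and aqueous volumetric flows (any common unit).
#' @return dimensionless E.
#' @export
extraction_factor_E <- function(P, Q_s, Q_w) {
  stop_if_not_positive(P, "P")
  stop_if_not_positive(Q_s, "Q_s")
  stop_if_not_positive(Q_w, "Q_w")
  P * Q_s / Q_w
}

#' Reservoir extraction factor R
#'
#' R = P V_s / V_w: the partition-weighted reservoir-volume ratio that sets
#' the system equilibrium (c_w -> c_w0 / (1 + R)).
#'
#' @param P partition coefficient, > 0.
#' @param V_s,V_w organic and aqueous reservoir volumes (any common unit).
#' @return dimensionless R.
#' @export
reservoir_factor_R <- function(P, V_s, V_w) {
  stop_if_not_positive(P, "P")
  stop_if_not_positive(V_s, "V_s")
  stop_if_not_positive(V_w, "V_w")
  P * V_s / V_w
}

#' Single-pass module extraction efficiency
#'
#' With x = K_w A / Q_w and a = 1 - 1/E:
#' Phi = (1 - exp(-x a)) / (1 - (1/E) exp(-x a)),
#' evaluated in the numerically stable form
#' Phi = -expm1(-x a) / (-expm1(-x a) + a exp(-x a)), which carries the
#' E -> 1 analytic limit x / (1 + x) without branching on a tolerance.
#'
#' @param K_w overall aqueous-basis mass-transfer coefficient, m/s (0 allowed:
#'   Phi = 0).
#' @param A interfacial area, m2.
#' @param Q_w aqueous flow through the module, m3/s.
#' @param E module extraction factor ([extraction_factor_E()]); `Inf` gives
#'   the plug-extraction limit 1 - exp(-x).
#' @return efficiency Phi in [0, 1).
#' @export
module_efficiency_phi <- function(K_w, A, Q_w, E) {
  if (!is.numeric(K_w) || any(K_w < 0)) stop("`K_w` must be >= 0", call. = FALSE)
  stop_if_not_positive(A, "A")
  stop_if_not_positive(Q_w, "Q_w")
  if (!is.numeric(E) || is.na(E) || E <= 0) stop("`E` must be > 0", call. = FALSE)
  x <- K_w * A / Q_w
  a <- 1 - 1 / E                       # a = 0 at E = 1; a = 1 at E = Inf
  if (a == 0) return(x / (1 + x))
  num <- -expm1(-x * a)
  num / (num + a * exp(-x * a))
}

#' Overall coefficient from a measured module efficiency
#'
#' Inverts [module_efficiency_phi()] analytically: with a = 1 - 1/E,
#' exp(-x a) = (1 - Phi) / (1 - Phi/E), so x = -ln[(1 - Phi)/(1 - Phi/E)] / a
#' and K_w = x Q_w / A. At E = 1 the limit x = Phi / (1 - Phi) is used. The
#' attainable range is 0 < Phi < min(1, E); values at or beyond it are
#' rejected with an explanation.
#'
#' @param phi measured single-pass efficiency, in (0, 1).
#' @param A interfacial area, m2.
#' @param Q_w aqueous flow through the module, m3/s.
#' @param E module extraction factor.
#' @return K_w in m/s.
#' @export
kw_from_phi <- function(phi, A, Q_w, E) {
  stop_if_not_positive(A, "A")
  stop_if_not_positive(Q_w, "Q_w")
  if (!is.numeric(E) || is.na(E) || E <= 0) stop("`E` must be > 0", call. = FALSE)
  upper <- min(1, E)
  if (!is.finite(phi) || phi <= 0 || phi >= upper) {
    stop(sprintf(
      "`phi` = %.4g is outside the attainable range (0, %.4g) for E = %.4g: no finite K_w reproduces it",
      phi, upper, E), call. = FALSE)
  }
  a <- 1 - 1 / E
  x <- if (a == 0) phi / (1 - phi) else -log((1 - phi) / (1 - phi / E)) / a
  x * Q_w / A
}

#' Bundle the extraction factors of an operating point
#'
#' @param P partition coefficient.
#' @param operating [operating_point()] with reservoir volumes set.
#' @param phi optional single-pass efficiency to carry along.
#' @return list of class `extraction_factors`: `E`, `R`, `phi`, `P`.
#' @export
extraction_factors <- function(P, operating, phi = NA_real_) {
  stopifnot(inherits(operating, "operating_point"))
  structure(list(
    E = extraction_factor_E(P, operating$Q_s, operating$Q_w),
    R = reservoir_factor_R(P, operating$V_s, operating$V_w),
    phi = phi, P = P
  ), class = "extraction_factors")
}

#' Simulate the recirculating extraction time course
#'
#' Closed-form solution of the non-steady-state reservoir balance
#' dc_w/dt = -(Q_w Phi / V_w) (c_w (1 + 1/R) - c_w0 / R):
#' c_w(t) = c_w0 (1/R + exp(-(Q_w Phi / V_w)(1 + 1/R) t)) / (1 + 1/R),
#' with the organic reservoir by exact solute conservation
#' c_s(t) = (V_w / V_s)(c_w0 - c_w(t)).
#'
#' @param phi single-pass module efficiency, in (0, 1].
#' @param R reservoir extraction factor ([reservoir_factor_R()]).
#' @param Q_w aqueous flow, m3/s.
#' @param V_w,V_s reservoir volumes, m3.
#' @param c_w0 initial aqueous concentration, kg/m3.
#' @param times sampling times, s, non-negative and strictly increasing.
#' @return data.frame of class `timecourse` with columns `time`, `c_w`,
#'   `c_s`; attributes `c_w0`, `V_w`, `V_s`, `phi`, `R`.
#' @export
simulate_timecourse <- function(phi, R, Q_w, V_w, c_w0, V_s, times) {
  stop_if_not_positive(phi, "phi")
  if (phi > 1) stop("`phi` must be <= 1", call. = FALSE)
  stop_if_not_positive(R, "R")
  stop_if_not_positive(Q_w, "Q_w")
  stop_if_not_positive(V_w, "V_w")
  stop_if_not_positive(V_s, "V_s")
  if (!is.finite(c_w0) || c_w0 < 0) stop("`c_w0` must be >= 0", call. = FALSE)
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("`times` must be non-negative and strictly increasing", call. = FALSE)
  }
  rate <- (Q_w * phi / V_w) * (1 + 1 / R)
  c_w <- c_w0 * (1 / R + exp(-rate * times)) / (1 + 1 / R)
  c_s <- (V_w / V_s) * (c_w0 - c_w)
  structure(data.frame(time = times, c_w = c_w, c_s = c_s),
            class = c("timecourse", "data.frame"),
            c_w0 = c_w0, V_w = V_w, V_s = V_s, phi = phi, R = R)
}

#' Recovery, concentration factor and organic enrichment over time
#'
#' recovery(t) = (V_w c_w + V_s c_s) / (V_w c_w0): fraction of the dosed
#' solute accounted for in both reservoirs. concentration_factor(t) =
#' c_s / c_w0. enrichment(t) = V_s c_s / (V_w c_w0): fraction of the dosed
#' amount residing in the organic phase.
#'
#' @param course `timecourse` (or data.frame with `time`, `c_w`, `c_s`).
#' @param V_w,V_s reservoir volumes, m3 (default: the course attributes).
#' @param c_w0 initial aqueous concentration, kg/m3 (default: attribute).
#' @return data.frame with `time`, `recovery`, `concentration_factor`,
#'   `enrichment`.
#' @export
mass_balance_metrics <- function(course, V_w = attr(course, "V_w"),
                                 V_s = attr(course, "V_s"),
                                 c_w0 = attr(course, "c_w0")) {
  stopifnot(is.data.frame(course), all(c("time", "c_w", "c_s") %in% names(course)))
  stop_if_not_positive(V_w, "V_w")
  stop_if_not_positive(V_s, "V_s")
  if (is.null(c_w0) || !is.finite(c_w0) || c_w0 <= 0) {
    stop("`c_w0` must be a positive number", call. = FALSE)
  }
  data.frame(
    time = course$time,
    recovery = (V_w * course$c_w + V_s * course$c_s) / (V_w * c_w0),
    concentration_factor = course$c_s / c_w0,
    enrichment = V_s * course$c_s / (V_w * c_w0)
  )
}
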
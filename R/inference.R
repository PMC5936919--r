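# Fitting the module efficiency and overall mass-transfer coefficient from
# measured reservoir concentration time series via the linearised
# two-reservoir model.

#' Linearise an aqueous-reservoir time course
#'
#' Transforms c_w(t) to y(t) = ln[(1 + 1/R) c_w / c_w0 - 1/R], which the
#' recirculating-extraction model predicts to be linear in t through the
#' origin with slope -(Q_w Phi / V_w)(1 + 1/R). Points whose log argument is
#' non-positive (measurements at or below the equilibrium floor
#' c_w0 / (1 + R)) or missing are excluded and reported, never silently
#' dropped.
#'
#' @param course `timecourse` or data.frame with columns `time` (s) and
#'   `c_w` (kg/m3).
#' @param R reservoir extraction factor, > 0.
#' @param c_w0 initial aqueous concentration; defaults to the course
#'   attribute, else the concentration at the earliest time.
#' @return list of class `linearized_course`: `points` (data.frame `time`,
#'   `y`), `excluded` (data.frame `time`, `c_w`, `reason`).
#' @export
linearize <- function(course, R, c_w0 = NULL) {
  stopifnot(is.data.frame(course), all(c("time", "c_w") %in% names(course)))
  stop_if_not_positive(R, "R")
  if (is.null(c_w0)) c_w0 <- attr(course, "c_w0")
  if (is.null(c_w0)) c_w0 <- course$c_w[which.min(course$time)]
  stop_if_not_positive(c_w0, "c_w0")
  arg <- (1 + 1 / R) * course$c_w / c_w0 - 1 / R
  missing_pt <- !is.finite(course$c_w)
  floor_pt <- !missing_pt & arg <= 0
  keep <- !missing_pt & !floor_pt
  excluded <- data.frame(
    time = course$time[!keep],
    c_w = course$c_w[!keep],
    reason = ifelse(missing_pt[!keep], "missing/censored measurement",
                    "at equilibrium floor")
  )
  if (sum(keep) < 2L) {
    stop("fewer than 2 points usable after exclusions: cannot linearise",
         call. = FALSE)
  }
  structure(list(points = data.frame(time = course$time[keep], y = log(arg[keep])),
                 excluded = excluded),
            class = "linearized_course")
}

# through-origin least-squares slope; y(0) = 0 is exact in the model
.origin_slope <- function(t, y) sum(t * y) / sum(t * t)

#' Fit module efficiency and overall mass transfer from a time course
#'
#' Least-squares fit of the linearised model y = slope * t (through the
#' origin by default, since the model forces y(0) = 0; set
#' `intercept = TRUE` for a diagnostic free-intercept fit). Then
#' Phi = -slope V_w / (Q_w (1 + 1/R)) and K_w = [kw_from_phi()] at the
#' mode-consistent interfacial area (inner for aqueous-in-lumen, outer for
#' aqueous-in-shell; overridable via `area`). Optional seeded nonparametric
#' bootstrap over time points gives percentile confidence intervals.
#'
#' @param course `timecourse` or data.frame with `time` (s), `c_w` (kg/m3).
#' @param operating [operating_point()] with `V_w`, `V_s` set.
#' @param module [membrane_module()].
#' @param P partition coefficient (input, not fitted).
#' @param area interfacial area override, m2.
#' @param intercept fit a free intercept instead of forcing the origin.
#' @param nboot bootstrap resamples (0 = none; 1000 is a typical choice).
#' @param conf confidence level for the bootstrap intervals.
#' @param seed integer seed for the bootstrap resampling.
#' @return object of class `fit_result`: `phi`, `K_w` (m/s), `slope` (1/s),
#'   `intercept`, `r_squared`, `n_points_used`, `excluded_points`,
#'   `bootstrap_ci` (rows `phi`, `K_w`; NULL without bootstrap), `E`, `R`,
#'   `area`, `seed`.
#' @export
fit_phi_kw <- function(course, operating, module, P, area = NULL,
                       intercept = FALSE, nboot = 0L, conf = 0.95,
                       seed = 1L) {
  stopifnot(inherits(operating, "operating_point"),
            inherits(module, "membrane_module"))
  stop_if_not_positive(P, "P")
  if (!is.finite(operating$V_w) || !is.finite(operating$V_s)) {
    stop("operating point must carry reservoir volumes V_w, V_s", call. = FALSE)
  }
  E <- extraction_factor_E(P, operating$Q_s, operating$Q_w)
  R <- reservoir_factor_R(P, operating$V_s, operating$V_w)
  if (is.null(area)) {
    area <- if (operating$mode == "aqueous_in_lumen") module$inner_area else module$outer_area
  }
  lin <- linearize(course, R)
  t <- lin$points$time
  y <- lin$points$y

  slope_phi <- function(slope) -slope * operating$V_w / (operating$Q_w * (1 + 1 / R))
  if (intercept) {
    fit <- stats::lm(y ~ t)
    slope <- unname(stats::coef(fit)[["t"]])
    icept <- unname(stats::coef(fit)[["(Intercept)"]])
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  } else {
    slope <- .origin_slope(t, y)
    icept <- 0
    ss_res <- sum((y - slope * t)^2)
    ss_tot <- sum(y^2)                 # uncentered: the model passes the origin
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  }
  if (slope >= 0) {
    stop("no extraction detected: linearised slope is non-negative", call. = FALSE)
  }
  phi <- slope_phi(slope)
  K_w <- kw_from_phi(phi, area, operating$Q_w, E)

  ci <- NULL
  if (nboot > 0L) {
    set.seed(seed)
    n <- length(t)
    idx <- matrix(sample.int(n, n * nboot, replace = TRUE), nrow = nboot)
    tm <- matrix(t[idx], nrow = nboot)
    ym <- matrix(y[idx], nrow = nboot)
    slopes <- rowSums(tm * ym) / rowSums(tm * tm)
    phis <- slope_phi(slopes)
    ok <- is.finite(phis) & phis > 0 & phis < min(1, E)
    kws <- rep(NA_real_, nboot)
    kws[ok] <- vapply(phis[ok], kw_from_phi, numeric(1),
                      A = area, Q_w = operating$Q_w, E = E)
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    ci <- rbind(phi = stats::quantile(phis[ok], probs, names = FALSE),
                K_w = stats::quantile(kws[ok], probs, names = FALSE))
    colnames(ci) <- c("lower", "upper")
  }

  structure(list(phi = phi, K_w = K_w, slope = slope, intercept = icept,
                 r_squared = r2, n_points_used = length(t),
                 excluded_points = lin$excluded, bootstrap_ci = ci,
                 E = E, R = R, area = area, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Extraction fit: Phi = %.4f, K_w = %.3e m/s\n", x$phi, x$K_w))
  cat(sprintf("  slope = %.4e 1/s, R^2 = %.5f, n = %d (excluded: %d)\n",
              x$slope, x$r_squared, x$n_points_used, nrow(x$excluded_points)))
  if (!is.null(x$bootstrap_ci)) {
    cat(sprintf("  bootstrap CI (phi): [%.4f, %.4f]; (K_w): [%.3e, %.3e] m/s\n",
                x$bootstrap_ci["phi", "lower"], x$bootstrap_ci["phi", "upper"],
                x$bootstrap_ci["K_w", "lower"], x$bootstrap_ci["K_w", "upper"]))
  }
  invisible(x)
}
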
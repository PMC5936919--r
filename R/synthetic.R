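# Synthetic-data generators: equilibrium partition replicates and
# concentration time courses with known ground truth, stated noise models
# and seeds, plus the reference carvone/n-heptane study scenario.

apply_noise <- function(x, noise_model, sd) {
  if (sd < 0) stop("noise `sd` must be >= 0", call. = FALSE)
  switch(noise_model,
         "multiplicative-Gaussian" = x * (1 + stats::rnorm(length(x), 0, sd)),
         "additive-Gaussian" = x + stats::rnorm(length(x), 0, sd),
         stop(sprintf("unknown noise model '%s'", noise_model), call. = FALSE))
}

#' Synthetic two-phase equilibrium replicates
#'
#' Noiseless equilibrium from the dosed concentration and the mass balance:
#' c_w = c_total / (1 + r P), c_s = P c_w, with r = V_s/V_w the phase ratio
#' (1 for equal volumes). Noise is applied per the chosen model; the
#' noiseless output closes the mass balance exactly.
#'
#' @param logP true base-10 partition coefficient.
#' @param n_replicates number of replicates (default 3, the usual
#'   triplicate).
#' @param c_total dosed solute concentration referred to the aqueous volume,
#'   mg/ml (default 0.4).
#' @param phase_ratio organic-to-aqueous volume ratio V_s/V_w (default 1).
#' @param noise_model `"multiplicative-Gaussian"` (default) or
#'   `"additive-Gaussian"`.
#' @param sd noise standard deviation (relative for multiplicative, absolute
#'   for additive); default 0.02.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return data.frame with columns `c_s`, `c_w`; attributes `truth` (list
#'   with `logP`, `P`, `c_total`, `phase_ratio`) and `seed`.
#' @export
synth_partition_replicates <- function(logP, n_replicates = 3L, c_total = 0.4,
                                       phase_ratio = 1,
                                       noise_model = "multiplicative-Gaussian",
                                       sd = 0.02, seed = 1L) {
  stopifnot(is.finite(logP))
  stop_if_not_positive(n_replicates, "n_replicates")
  stop_if_not_positive(c_total, "c_total")
  stop_if_not_positive(phase_ratio, "phase_ratio")
  if (sd < 0) stop("noise `sd` must be >= 0", call. = FALSE)
  P <- 10^logP
  c_w <- c_total / (1 + phase_ratio * P)
  c_s <- P * c_w
  set.seed(seed)
  out <- data.frame(
    c_s = apply_noise(rep(c_s, n_replicates), noise_model, sd),
    c_w = apply_noise(rep(c_w, n_replicates), noise_model, sd)
  )
  out$c_s <- pmax(out$c_s, 0)
  out$c_w <- pmax(out$c_w, 0)
  attr(out, "truth") <- list(logP = logP, P = P, c_total = c_total,
                             phase_ratio = phase_ratio)
  attr(out, "seed") <- seed
  out
}

#' Synthetic extraction time course with known ground truth
#'
#' Wraps [simulate_timecourse()] and adds module inlet/outlet stream
#' concentrations from the single-pass balance (aqueous outlet
#' c_w (1 - Phi) + (Phi/P) c_s; organic outlet by the pass solute balance),
#' then applies measurement noise and lower-limit-of-quantification
#' censoring. Ground truth is stored alongside so downstream tests never
#' re-derive it from noisy data.
#'
#' @param phi true single-pass module efficiency.
#' @param P true partition coefficient.
#' @param operating [operating_point()] with reservoir volumes and `c_w0`.
#' @param times sampling times, s (default: 0-480 min schedule of an 8-h
#'   run).
#' @param noise_model,sd noise specification as in
#'   [synth_partition_replicates()]; `sd = 0` gives the exact model output.
#' @param loq lower limit of quantification, kg/m3; concentrations below it
#'   are reported `NA` (no censoring when `NA`).
#' @param seed integer seed.
#' @return data.frame of class `timecourse` with columns `time`, `c_w`,
#'   `c_s`, `c_w_outlet`, `c_s_outlet`; attributes `truth` (list with `phi`,
#'   `P`, `E`, `R`, `K_w_area_basis` slope inputs), `c_w0`, `V_w`, `V_s`,
#'   `seed`.
#' @export
synth_timecourse <- function(phi, P, operating,
                             times = min_to_s(c(0, 15, 30, 60, 120, 240, 360, 480)),
                             noise_model = "multiplicative-Gaussian", sd = 0.02,
                             loq = NA_real_, seed = 1L) {
  stopifnot(inherits(operating, "operating_point"))
  if (any(!is.finite(times))) stop("`times` must be finite", call. = FALSE)
  stop_if_not_positive(P, "P")
  R <- reservoir_factor_R(P, operating$V_s, operating$V_w)
  E <- extraction_factor_E(P, operating$Q_s, operating$Q_w)
  course <- simulate_timecourse(phi, R, operating$Q_w, operating$V_w,
                                operating$c_w0, operating$V_s, times)
  # single-pass module balance: aqueous outlet approaches the equilibrium
  # with the instantaneous organic stream; organic outlet by conservation
  c_w_out <- course$c_w * (1 - phi) + (phi / P) * course$c_s
  c_s_out <- course$c_s + (operating$Q_w / operating$Q_s) * (course$c_w - c_w_out)
  truth <- list(phi = phi, P = P, E = E, R = R,
                slope = -(operating$Q_w * phi / operating$V_w) * (1 + 1 / R))
  set.seed(seed)
  noisy <- function(x) if (sd > 0) apply_noise(x, noise_model, sd) else x
  out <- data.frame(time = times,
                    c_w = noisy(course$c_w), c_s = noisy(course$c_s),
                    c_w_outlet = noisy(c_w_out), c_s_outlet = noisy(c_s_out))
  if (!is.na(loq)) {
    stop_if_not_positive(loq, "loq")
    for (col in c("c_w", "c_s", "c_w_outlet", "c_s_outlet")) {
      out[[col]][out[[col]] < loq] <- NA_real_
    }
  }
  structure(out, class = c("timecourse", "data.frame"),
            truth = truth, c_w0 = operating$c_w0, V_w = operating$V_w,
            V_s = operating$V_s, seed = seed)
}

#' Reference carvone/n-heptane study scenario
#'
#' The complete fixture of the small-scale study this package models:
#' (S)-(+)-carvone extracted from water into n-heptane in a three-fibre PTFE
#' hollow-fibre contactor (3 mm ID, 20 cm, 56 cm2 inner area), lumen flow
#' 3 ml/min, shell flow 40 ml/min, aqueous:organic phase ratio 2:1
#' (V_w 100 ml, V_s 50 ml assumed), initial aqueous concentration
#' 0.15 mg/ml, 25 degC. Membrane wall parameters not reported for the module
#' (outer diameter, porosity, tortuosity, shell bore) carry documented
#' placeholder values (see the package vignette); the partition table is a
#' synthetic stand-in with carvone/n-heptane logP 2.778 (P approximately
#' 600).
#'
#' @return list with `module` ([membrane_module()]), `solute`
#'   ([solute_spec()]), `water`, `heptane` ([phase_spec()]), `P`, `logP`,
#'   `solvents` (property table as shipped in `inst/extdata`), `partition`
#'   (synthetic partition table), and `operating` — a list with elements
#'   `in_out` and `out_in` ([operating_point()]).
#' @export
synth_paper_fixture <- function() {
  module <- membrane_module(
    n_fibres = 3, d_i = 3e-3, d_o = 3.3e-3, length = 0.2,
    pore_size = 1e-6, porosity = 0.5, tortuosity = 2,
    shell_inner_diameter = 10e-3, beta = 5.8
  )
  solute <- solute_spec("(S)-(+)-carvone", "C10H14O", molar_mass = 150.22,
                        oxygen_context = "carbonyl")
  water <- phase_spec("water", molar_mass = 18.02, viscosity = 0.89,
                      density = 998, association_factor = 2.6)
  solvents <- read_solvent_table(
    system.file("extdata", "solvents.csv", package = "pertraction"))
  heptane <- solvents[["n-heptane"]]
  partition <- read_partition_table(
    system.file("extdata", "synthetic_partition_table.csv", package = "pertraction"))
  row <- partition[partition$solute == "(S)-(+)-carvone" &
                     partition$solvent == "n-heptane" &
                     partition$medium == "water", ]
  logP <- row$logP_pred[1]
  P <- 10^logP
  op <- function(mode) operating_point(
    mode = mode,
    Q_lumen = ml_min_to_m3_s(3), Q_shell = ml_min_to_m3_s(40),
    temperature = 298.15,
    V_w = ml_to_m3(100), V_s = ml_to_m3(50),
    c_w0 = mg_ml_to_kg_m3(0.15)
  )
  list(module = module, solute = solute, water = water, heptane = heptane,
       P = P, logP = logP, solvents = solvents, partition = partition,
       operating = list(in_out = op("in-out"), out_in = op("out-in")))
}
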
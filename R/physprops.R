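# Physical-property estimation: Le Bas molar volumes, Wilke-Chang
# diffusivities, partition coefficients, dimensionless groups.

# Le Bas additive atomic volume increments, cm3/mol. Oxygen depends on its
# bonding context; ring corrections are deliberately not applied (see
# vignette: the solutes of interest are treated by plain atomic additivity).
.le_bas_increments <- c(
  C = 14.8, H = 3.7, N = 15.6, S = 25.6,
  F = 8.7, Cl = 24.6, Br = 27.0, I = 37.0
)
.le_bas_oxygen <- c(
  carbonyl = 7.4,     # doubly bonded O (ketones, aldehydes)
  ether_ester = 11.0, # O in higher ethers and esters
  acid = 12.0         # O in carboxylic acids
)

#' Le Bas molar volume from elemental composition
#'
#' Additive atomic-increment estimate of the molar volume at the normal
#' boiling point, the conventional companion to the Wilke-Chang diffusivity
#' correlation. The oxygen increment depends on its bonding environment.
#'
#' @param formula named numeric vector or list of element counts, e.g.
#'   `c(C = 10, H = 14, O = 1)`, or a molecular-formula string such as
#'   `"C10H14O"`.
#' @param oxygen_context one of `"carbonyl"` (doubly bonded oxygen, the
#'   default), `"ether_ester"`, `"acid"`; selects the oxygen increment.
#' @return molar volume in cm3/mol.
#' @examples
#' le_bas_molar_volume(c(C = 10, H = 14, O = 1))  # carvone: 207.2
#' le_bas_molar_volume("C1H4")                    # methane: 29.6
#' @export
le_bas_molar_volume <- function(formula, oxygen_context = c("carbonyl", "ether_ester", "acid")) {
  oxygen_context <- match.arg(oxygen_context)
  formula <- parse_formula(formula)
  if (length(formula) == 0L) {
    stop("empty formula: at least one element count is required", call. = FALSE)
  }
  counts <- unlist(formula)
  if (any(counts <= 0) || any(counts != round(counts))) {
    stop("formula counts must be positive integers", call. = FALSE)
  }
  increments <- .le_bas_increments
  increments["O"] <- .le_bas_oxygen[[oxygen_context]]
  unknown <- setdiff(names(counts), names(increments))
  if (length(unknown) > 0L) {
    stop(sprintf("no Le Bas increment for element(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sum(counts * increments[names(counts)])
}

#' Parse a molecular-formula string into element counts
#'
#' @param formula string like `"C10H14O"`, or an already-named numeric
#'   vector/list (returned as a named numeric vector).
#' @return named numeric vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.list(formula)) formula <- unlist(formula)
  if (is.numeric(formula)) {
    if (length(formula) > 0L && is.null(names(formula))) {
      stop("numeric formula must be a named vector of element counts", call. = FALSE)
    }
    return(formula)
  }
  if (!is.character(formula) || length(formula) != 1L) {
    stop("`formula` must be a named count vector or a single string", call. = FALSE)
  }
  if (!nzchar(formula)) return(numeric(0))
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.numeric(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  tapply(counts, elements, sum)[unique(elements)]
}

#' Solute specification
#'
#' @param name solute name.
#' @param formula elemental composition (named counts or formula string);
#'   optional when `le_bas_volume` is given.
#' @param molar_mass g/mol.
#' @param le_bas_volume molar volume in cm3/mol; computed from `formula` via
#'   [le_bas_molar_volume()] when omitted.
#' @param oxygen_context oxygen bonding context for the Le Bas estimate.
#' @return object of class `solute_spec`.
#' @examples
#' carvone <- solute_spec("(S)-(+)-carvone", "C10H14O", molar_mass = 150.22)
#' @export
solute_spec <- function(name, formula = NULL, molar_mass,
                        le_bas_volume = NULL, oxygen_context = "carbonyl") {
  stop_if_not_positive(molar_mass, "molar_mass")
  if (is.null(le_bas_volume)) {
    if (is.null(formula)) {
      stop("supply either `formula` or `le_bas_volume`", call. = FALSE)
    }
    le_bas_volume <- le_bas_molar_volume(formula, oxygen_context)
  }
  stop_if_not_positive(le_bas_volume, "le_bas_volume")
  structure(list(name = name,
                 formula = if (is.null(formula)) NULL else parse_formula(formula),
                 molar_mass = molar_mass,
                 le_bas_volume = le_bas_volume),
            class = "solute_spec")
}

#' Solvent / phase specification
#'
#' Bulk-phase properties used by the diffusivity and film-coefficient
#' correlations. Viscosity is the tabulated mPa s value (numerically equal to
#' cP); the association factor is the Wilke-Chang solvent parameter (2.6 for
#' water, 1.0 for non-associated organics).
#'
#' @param name phase name.
#' @param molar_mass g/mol.
#' @param viscosity mPa s at the reference temperature.
#' @param density kg/m3.
#' @param vapour_pressure hPa (optional).
#' @param toxicity_class integer 1-3 per ICH Q3C (optional; 3 = least
#'   problematic).
#' @param association_factor dimensionless Wilke-Chang factor, >= 1.
#' @param miscible_with_water logical; `TRUE` for (partially) water-miscible
#'   solvents whose two-phase partition data are unreliable.
#' @return object of class `phase_spec`.
#' @examples
#' water <- phase_spec("water", 18.02, 0.89, 998, association_factor = 2.6)
#' @export
phase_spec <- function(name, molar_mass, viscosity, density,
                       vapour_pressure = NA_real_, toxicity_class = NA_integer_,
                       association_factor = 1.0, miscible_with_water = FALSE) {
  stop_if_not_positive(molar_mass, "molar_mass")
  stop_if_not_positive(viscosity, "viscosity")
  stop_if_not_positive(density, "density")
  if (!is.na(toxicity_class) && !toxicity_class %in% 1:3) {
    stop("toxicity_class must be 1, 2 or 3 (ICH Q3C)", call. = FALSE)
  }
  if (!is.finite(association_factor) || association_factor < 1) {
    stop("association_factor must be >= 1 (1.0 non-associated, 2.6 water)",
         call. = FALSE)
  }
  structure(list(name = name, molar_mass = molar_mass, viscosity = viscosity,
                 density = density, vapour_pressure = vapour_pressure,
                 toxicity_class = toxicity_class,
                 association_factor = association_factor,
                 miscible_with_water = isTRUE(miscible_with_water)),
            class = "phase_spec")
}

#' Wilke-Chang diffusion coefficient
#'
#' Estimates the molecular diffusivity of a dilute solute in a solvent phase:
#' D = 7.4e-8 (phi M)^0.5 T / (mu V^0.6) in cm2/s, with phi the solvent
#' association factor, M the solvent molar mass (g/mol), T in K, mu in cP and
#' V the solute Le Bas molar volume (cm3/mol). Returned in m2/s.
#'
#' @param solute [solute_spec()].
#' @param phase [phase_spec()]; its `association_factor` must be set.
#' @param temperature K (default 298.15).
#' @return object of class `diffusivity` with fields `value` (m2/s),
#'   `solute`, `phase`, `temperature`.
#' @export
wilke_chang_diffusivity <- function(solute, phase, temperature = 298.15) {
  stopifnot(inherits(solute, "solute_spec"), inherits(phase, "phase_spec"))
  stop_if_not_positive(temperature, "temperature")
  if (is.null(phase$association_factor) || is.na(phase$association_factor)) {
    stop("phase association factor missing: set `association_factor` ",
         "(1.0 for non-associated solvents, 2.6 for water)", call. = FALSE)
  }
  mu_cP <- mPa_s_to_cP(phase$viscosity)
  D_cm2_s <- 7.4e-8 * sqrt(phase$association_factor * phase$molar_mass) *
    temperature / (mu_cP * solute$le_bas_volume^0.6)
  diffusivity(D_cm2_s * 1e-4, solute = solute$name, phase = phase$name,
              temperature = temperature)
}

#' Diffusivity container
#'
#' @param value m2/s, > 0.
#' @param solute,phase text labels.
#' @param temperature K.
#' @return object of class `diffusivity`.
#' @export
diffusivity <- function(value, solute = NA_character_, phase = NA_character_,
                        temperature = 298.15) {
  stop_if_not_positive(value, "value")
  stop_if_not_positive(temperature, "temperature")
  structure(list(value = value, solute = solute, phase = phase,
                 temperature = temperature),
            class = "diffusivity")
}

# accept either a bare number or a diffusivity object
as_diffusivity_value <- function(D) {
  if (inherits(D, "diffusivity")) D$value else {
    stop_if_not_positive(D, "D")
    D
  }
}

#' Partition coefficient from two-phase concentrations
#'
#' P = c_s / c_w, the equilibrium ratio of the solute concentration in the
#' organic (solvent) phase to the aqueous phase.
#'
#' @param c_s organic-phase concentration (any mass/volume unit, same as
#'   `c_w`), >= 0.
#' @param c_w aqueous-phase concentration, > 0.
#' @return dimensionless partition coefficient (vectorised).
#' @export
partition_coefficient <- function(c_s, c_w) {
  if (any(!is.finite(c_s)) || any(c_s < 0)) {
    stop("`c_s` must be non-negative and finite", call. = FALSE)
  }
  if (any(!is.finite(c_w)) || any(c_w < 0)) {
    stop("`c_w` must be non-negative and finite", call. = FALSE)
  }
  if (any(c_w == 0)) {
    stop("`c_w` is zero: partition coefficient undefined", call. = FALSE)
  }
  c_s / c_w
}

#' Estimate a partition coefficient from equilibrium replicates
#'
#' Per-replicate log10 P with mean and sample SD, plus a mass-balance closure
#' check: the recovered amount (aqueous + phase-ratio-weighted organic)
#' relative to the dosed amount. Replicates with zero aqueous concentration
#' are excluded with a warning, never silently.
#'
#' @param replicates data.frame (or list of pairs) with columns `c_s`, `c_w`.
#' @param c_total_expected dosed solute concentration referred to the aqueous
#'   volume (same unit as the replicate concentrations); `NA` skips the
#'   closure check.
#' @param phase_ratio organic-to-aqueous volume ratio V_s/V_w (default 1,
#'   equal volumes).
#' @param closure_band length-2 numeric; closure outside this band is
#'   flagged.
#' @return list of class `partition_estimate`: `logP_mean`, `logP_sd`,
#'   `P_mean` (10^logP_mean), `n_used`, `excluded`, `closure` (per replicate),
#'   `closure_ok`, `per_replicate` data.frame.
#' @export
estimate_partition <- function(replicates, c_total_expected = NA_real_,
                               phase_ratio = 1,
                               closure_band = c(0.85, 1.15)) {
  if (is.list(replicates) && !is.data.frame(replicates)) {
    replicates <- do.call(rbind, lapply(replicates, function(p) {
      data.frame(c_s = p[[1]], c_w = p[[2]])
    }))
  }
  stopifnot(is.data.frame(replicates), all(c("c_s", "c_w") %in% names(replicates)))
  if (nrow(replicates) < 1L) stop("at least one replicate required", call. = FALSE)
  if (any(replicates$c_s < 0) || any(replicates$c_w < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  stop_if_not_positive(phase_ratio, "phase_ratio")
  bad <- replicates$c_w == 0
  if (any(bad)) {
    warning(sprintf("%d replicate(s) with zero aqueous concentration excluded",
                    sum(bad)), call. = FALSE)
  }
  kept <- replicates[!bad, , drop = FALSE]
  if (nrow(kept) < 1L) stop("no usable replicates (all c_w = 0)", call. = FALSE)
  P <- partition_coefficient(kept$c_s, kept$c_w)
  logP <- log10(P)
  closure <- if (is.na(c_total_expected)) rep(NA_real_, nrow(kept)) else {
    (kept$c_w + phase_ratio * kept$c_s) / c_total_expected
  }
  closure_ok <- is.na(closure) | (closure >= closure_band[1] & closure <= closure_band[2])
  if (any(!closure_ok)) {
    warning(sprintf("mass-balance closure outside [%.2f, %.2f] for %d replicate(s)",
                    closure_band[1], closure_band[2], sum(!closure_ok)),
            call. = FALSE)
  }
  structure(list(
    logP_mean = mean(logP),
    logP_sd = if (nrow(kept) > 1L) stats::sd(logP) else 0,
    P_mean = 10^mean(logP),
    n_used = nrow(kept),
    excluded = which(bad),
    closure = closure,
    closure_ok = all(closure_ok),
    per_replicate = data.frame(c_s = kept$c_s, c_w = kept$c_w, P = P, logP = logP,
                               closure = closure)
  ), class = "partition_estimate")
}

#' Reynolds, Schmidt and Graetz numbers for a stream
#'
#' Re = rho v d / mu with v = flow / flow_area; Sc = mu / (rho D);
#' Gz = Re Sc d / L when a length is supplied.
#'
#' @param flow volumetric flow, m3/s.
#' @param characteristic_diameter m.
#' @param flow_area cross-section carrying the flow, m2.
#' @param phase [phase_spec()] for density and viscosity.
#' @param D diffusivity (m2/s or [diffusivity()] object).
#' @param length optional tube length L (m) for the Graetz number.
#' @return list of class `dimensionless_groups`: `reynolds`, `schmidt`,
#'   `graetz` (NA without `length`), `velocity` (m/s).
#' @export
reynolds_schmidt <- function(flow, characteristic_diameter, flow_area, phase, D,
                             length = NA_real_) {
  stop_if_not_positive(flow, "flow")
  stop_if_not_positive(characteristic_diameter, "characteristic_diameter")
  if (!is.finite(flow_area) || flow_area <= 0) {
    stop("`flow_area` must be positive", call. = FALSE)
  }
  stopifnot(inherits(phase, "phase_spec"))
  Dv <- as_diffusivity_value(D)
  mu <- phase$viscosity * 1e-3  # mPa.s -> Pa.s
  v <- flow / flow_area
  Re <- phase$density * v * characteristic_diameter / mu
  Sc <- mu / (phase$density * Dv)
  Gz <- if (is.na(length)) NA_real_ else Re * Sc * characteristic_diameter / length
  structure(list(reynolds = Re, schmidt = Sc, graetz = Gz, velocity = v),
            class = "dimensionless_groups")
}

#' @export
print.partition_estimate <- function(x, ...) {
  cat(sprintf("Partition estimate: logP = %.3f (SD %.3f, n = %d)\n",
              x$logP_mean, x$logP_sd, x$n_used))
  if (length(x$excluded)) {
    cat(sprintf("  excluded replicates: %s\n", paste(x$excluded, collapse = ", ")))
  }
  if (!all(is.na(x$closure))) {
    cat(sprintf("  mass-balance closure: %s (ok: %s)\n",
                paste(sprintf("%.3f", x$closure), collapse = ", "), x$closure_ok))
  }
  invisible(x)
}

#' @export
print.diffusivity <- function(x, ...) {
  cat(sprintf("D(%s in %s) = %.3e m2/s at %.2f K\n",
              x$solute, x$phase, x$value, x$temperature))
  invisible(x)
}
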
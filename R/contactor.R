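# Hollow-fibre module geometry and the individual/overall mass-transfer
# coefficients of the resistance-in-series model.

#' Hollow-fibre membrane module geometry
#'
#' Bundles the geometric and membrane parameters of a hollow-fibre contactor
#' and derives the quantities the film correlations need: inner/outer
#' membrane areas, log-mean fibre diameter, shell packing fraction
#' theta = n d_o^2 / D_shell^2 and hydraulic diameter
#' d_h = (D_shell^2 - n d_o^2) / (n d_o) (wetted-perimeter definition for a
#' fibre bundle in a circular shell).
#'
#' @param n_fibres number of fibres.
#' @param d_i,d_o fibre inner and outer diameter, m.
#' @param length fibre (module) length, m.
#' @param pore_size nominal pore size, m (informational).
#' @param porosity membrane porosity, in (0, 1).
#' @param tortuosity membrane pore tortuosity, >= 1.
#' @param shell_inner_diameter housing inner diameter, m.
#' @param beta shell-correlation coefficient (5.8 for hydrophobic membranes).
#' @return object of class `membrane_module` with the inputs plus
#'   `inner_area`, `outer_area`, `d_lm`, `packing_fraction`,
#'   `hydraulic_diameter`, `shell_free_area`, `lumen_area_per_fibre`.
#' @examples
#' m <- membrane_module(n_fibres = 3, d_i = 3e-3, d_o = 3.3e-3, length = 0.2,
#'                      pore_size = 1e-6, porosity = 0.5, tortuosity = 2,
#'                      shell_inner_diameter = 10e-3)
#' m$inner_area * 1e4  # ~56 cm2
#' @export
membrane_module <- function(n_fibres, d_i, d_o, length, pore_size = NA_real_,
                            porosity, tortuosity, shell_inner_diameter,
                            beta = 5.8) {
  stop_if_not_positive(n_fibres, "n_fibres")
  stop_if_not_positive(d_i, "d_i")
  stop_if_not_positive(d_o, "d_o")
  stop_if_not_positive(length, "length")
  stop_if_not_positive(shell_inner_diameter, "shell_inner_diameter")
  stop_if_not_positive(beta, "beta")
  if (d_o <= d_i) stop("`d_o` must exceed `d_i`", call. = FALSE)
  if (!is.finite(porosity) || porosity <= 0 || porosity >= 1) {
    stop("`porosity` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.finite(tortuosity) || tortuosity < 1) {
    stop("`tortuosity` must be >= 1", call. = FALSE)
  }
  theta <- n_fibres * d_o^2 / shell_inner_diameter^2
  if (theta >= 1) {
    stop("fibre bundle does not fit the shell (packing fraction >= 1)",
         call. = FALSE)
  }
  structure(list(
    n_fibres = n_fibres, d_i = d_i, d_o = d_o, length = length,
    pore_size = pore_size, porosity = porosity, tortuosity = tortuosity,
    shell_inner_diameter = shell_inner_diameter, beta = beta,
    inner_area = n_fibres * pi * d_i * length,
    outer_area = n_fibres * pi * d_o * length,
    d_lm = log_mean_diameter(d_i, d_o),
    packing_fraction = theta,
    hydraulic_diameter = (shell_inner_diameter^2 - n_fibres * d_o^2) /
      (n_fibres * d_o),
    shell_free_area = pi / 4 * (shell_inner_diameter^2 - n_fibres * d_o^2),
    lumen_area_per_fibre = pi * d_i^2 / 4
  ), class = "membrane_module")
}

#' @export
print.membrane_module <- function(x, ...) {
  cat(sprintf("Hollow-fibre module: %d fibre(s), d_i %.2f mm, d_o %.2f mm, L %.1f cm\n",
              x$n_fibres, x$d_i * 1e3, x$d_o * 1e3, x$length * 1e2))
  cat(sprintf("  inner area %.1f cm2, outer area %.1f cm2, d_lm %.3f mm\n",
              x$inner_area * 1e4, x$outer_area * 1e4, x$d_lm * 1e3))
  cat(sprintf("  packing fraction %.3f, hydraulic diameter %.2f mm, beta %.1f\n",
              x$packing_fraction, x$hydraulic_diameter * 1e3, x$beta))
  invisible(x)
}

#' Log-mean diameter of a cylindrical membrane wall
#'
#' (d_o - d_i) / ln(d_o / d_i); continuous limit d at d_o = d_i. Always lies
#' strictly between the two diameters.
#'
#' @param d_i,d_o inner and outer diameter, m, with `d_o >= d_i > 0`.
#' @return log-mean diameter, m.
#' @export
log_mean_diameter <- function(d_i, d_o) {
  stop_if_not_positive(d_i, "d_i")
  stop_if_not_positive(d_o, "d_o")
  if (d_o < d_i) stop("`d_o` must be >= `d_i`", call. = FALSE)
  if (d_o == d_i) return(d_i)
  (d_o - d_i) / log(d_o / d_i)
}

#' Tube-side (lumen) film coefficient by the Leveque solution
#'
#' k = 1.62 (D/d_i) (d_i^2 v / (L D))^(1/3) with v the mean linear velocity
#' from the per-fibre volumetric flow over the circular cross-section. This
#' is Sh = 1.62 Gz^(1/3) with Gz = Re Sc d_i / L = v d_i^2 / (L D); a warning
#' is emitted when Gz < 4, below which the Leveque solution loses accuracy.
#'
#' @param D lumen-phase diffusivity (m2/s or [diffusivity()]).
#' @param d_i fibre inner diameter, m.
#' @param flow_per_fibre volumetric flow per fibre, m3/s.
#' @param length module length L, m.
#' @return list of class `film_coefficient`: `k` (m/s), `graetz`,
#'   `velocity` (m/s), `side = "lumen"`.
#' @export
k_fibre_leveque <- function(D, d_i, flow_per_fibre, length) {
  Dv <- as_diffusivity_value(D)
  stop_if_not_positive(d_i, "d_i")
  stop_if_not_positive(flow_per_fibre, "flow_per_fibre")
  stop_if_not_positive(length, "length")
  v <- flow_per_fibre / (pi * d_i^2 / 4)
  Gz <- v * d_i^2 / (length * Dv)
  if (Gz < 4) {
    warning(sprintf(
      "Graetz number %.3g < 4: Leveque solution may be inaccurate here", Gz),
      call. = FALSE)
  }
  k <- 1.62 * (Dv / d_i) * Gz^(1 / 3)
  structure(list(k = k, graetz = Gz, velocity = v, side = "lumen"),
            class = "film_coefficient")
}

#' Shell-side film coefficient for flow parallel to the fibres
#'
#' k = beta (D/d_h) (1 - theta) (d_h/L) Re^0.6 Sc^0.33, with the Reynolds
#' number built on the hydraulic diameter and the superficial velocity
#' through the shell free cross-section. beta defaults to the module's value
#' (5.8 for hydrophobic membranes).
#'
#' @param D shell-phase diffusivity (m2/s or [diffusivity()]).
#' @param module [membrane_module()].
#' @param shell_flow shell-side volumetric flow, m3/s.
#' @param phase [phase_spec()] of the shell-side fluid.
#' @return list of class `film_coefficient`: `k` (m/s), `reynolds`,
#'   `schmidt`, `velocity`, `side = "shell"`.
#' @export
k_shell_parallel_flow <- function(D, module, shell_flow, phase) {
  stopifnot(inherits(module, "membrane_module"))
  Dv <- as_diffusivity_value(D)
  stop_if_not_positive(shell_flow, "shell_flow")
  groups <- reynolds_schmidt(shell_flow, module$hydraulic_diameter,
                             module$shell_free_area, phase, Dv)
  k <- module$beta * (Dv / module$hydraulic_diameter) *
    (1 - module$packing_fraction) *
    (module$hydraulic_diameter / module$length) *
    groups$reynolds^0.6 * groups$schmidt^0.33
  structure(list(k = k, reynolds = groups$reynolds, schmidt = groups$schmidt,
                 velocity = groups$velocity, side = "shell"),
            class = "film_coefficient")
}

#' Membrane film coefficient of an organic-wetted porous wall
#'
#' k = 2 eps D / (tau (d_o - d_i)), with D the solute diffusivity in the
#' pore-wetting phase (the organic solvent for a hydrophobic membrane).
#'
#' @param D_wetting diffusivity in the wetting phase (m2/s or
#'   [diffusivity()]).
#' @param module [membrane_module()].
#' @return membrane coefficient, m/s.
#' @export
k_membrane <- function(D_wetting, module) {
  stopifnot(inherits(module, "membrane_module"))
  Dv <- as_diffusivity_value(D_wetting)
  if (module$d_o == module$d_i) stop("zero wall thickness", call. = FALSE)
  2 * module$porosity * Dv / (module$tortuosity * (module$d_o - module$d_i))
}

# normalise the operation-mode argument
match_mode <- function(mode) {
  mode <- tolower(mode)
  mode <- switch(mode,
                 "in-out" = , "in_out" = , "aqueous_in_lumen" = "aqueous_in_lumen",
                 "out-in" = , "out_in" = , "aqueous_in_shell" = "aqueous_in_shell",
                 stop(sprintf("unknown operation mode '%s' (use 'in-out'/'aqueous_in_lumen' or 'out-in'/'aqueous_in_shell')", mode), call. = FALSE))
  mode
}

#' Overall aqueous-basis mass-transfer coefficient (resistance in series)
#'
#' For an organic-wetted (hydrophobic) membrane the aqueous-basis overall
#' coefficient obeys
#' 1/(K_w d_basis) = 1/(P k_o d_other) + 1/(P k_m d_lm) + 1/(k_w d_basis),
#' where d_basis is the diameter on the aqueous side of the membrane (d_i
#' when the aqueous phase flows in the lumen, d_o when in the shell) and
#' d_other the opposite one. The organic-film and membrane resistances are
#' divided by the partition coefficient P.
#'
#' @param P partition coefficient (organic/aqueous), > 0.
#' @param k_w aqueous film coefficient, m/s (or `film_coefficient`).
#' @param k_o organic film coefficient, m/s (or `film_coefficient`).
#' @param k_m membrane coefficient, m/s.
#' @param module [membrane_module()].
#' @param mode `"aqueous_in_lumen"` (`"in-out"`) or `"aqueous_in_shell"`
#'   (`"out-in"`).
#' @return object of class `mass_transfer_breakdown`: `K_w` (m/s), the three
#'   film coefficients, `resistance_fractions` (aqueous, membrane, organic;
#'   sum to 1), `area_basis` (`"inner"`/`"outer"`), `mode`.
#' @export
overall_kw <- function(P, k_w, k_o, k_m, module, mode) {
  stopifnot(inherits(module, "membrane_module"))
  stop_if_not_positive(P, "P")
  kw <- if (inherits(k_w, "film_coefficient")) k_w$k else k_w
  ko <- if (inherits(k_o, "film_coefficient")) k_o$k else k_o
  stop_if_not_positive(kw, "k_w")
  stop_if_not_positive(ko, "k_o")
  stop_if_not_positive(k_m, "k_m")
  mode <- match_mode(mode)
  if (mode == "aqueous_in_lumen") {
    d_basis <- module$d_i; d_other <- module$d_o; basis <- "inner"
  } else {
    d_basis <- module$d_o; d_other <- module$d_i; basis <- "outer"
  }
  r_org <- 1 / (P * ko * d_other)
  r_mem <- 1 / (P * k_m * module$d_lm)
  r_aq <- 1 / (kw * d_basis)
  r_tot <- r_org + r_mem + r_aq
  structure(list(
    K_w = 1 / (r_tot * d_basis),
    k_w = kw, k_o = ko, k_m = k_m, P = P,
    resistance_fractions = c(aqueous = r_aq, membrane = r_mem, organic = r_org) / r_tot,
    area_basis = basis,
    mode = mode
  ), class = "mass_transfer_breakdown")
}

#' @export
print.mass_transfer_breakdown <- function(x, ...) {
  cat(sprintf("Overall mass transfer (aqueous basis, %s mode): K_w = %.3e m/s\n",
              ifelse(x$mode == "aqueous_in_lumen", "in-out", "out-in"), x$K_w))
  cat(sprintf("  k_w = %.3e, k_o = %.3e, k_m = %.3e m/s (P = %.3g)\n",
              x$k_w, x$k_o, x$k_m, x$P))
  fr <- x$resistance_fractions * 100
  cat(sprintf("  resistance: aqueous %.1f%%, membrane %.2f%%, organic %.2f%% (%s-diameter basis)\n",
              fr[["aqueous"]], fr[["membrane"]], fr[["organic"]], x$area_basis))
  invisible(x)
}

#' Operating point of the contactor loop
#'
#' @param mode operation mode (`"in-out"`/`"aqueous_in_lumen"` or
#'   `"out-in"`/`"aqueous_in_shell"`).
#' @param Q_lumen,Q_shell volumetric flows of the lumen- and shell-side
#'   streams, m3/s.
#' @param temperature K.
#' @param V_w,V_s aqueous and organic reservoir volumes, m3 (optional until a
#'   time-course simulation or fit is requested).
#' @param c_w0 initial aqueous solute concentration, kg/m3.
#' @return object of class `operating_point` with the inputs plus `Q_w`,
#'   `Q_s` (aqueous/organic flows resolved by mode).
#' @export
operating_point <- function(mode, Q_lumen, Q_shell, temperature = 298.15,
                            V_w = NA_real_, V_s = NA_real_, c_w0 = NA_real_) {
  mode <- match_mode(mode)
  stop_if_not_positive(Q_lumen, "Q_lumen")
  stop_if_not_positive(Q_shell, "Q_shell")
  stop_if_not_positive(temperature, "temperature")
  if (!is.na(c_w0) && c_w0 < 0) stop("`c_w0` must be >= 0", call. = FALSE)
  aqueous_in_lumen <- mode == "aqueous_in_lumen"
  structure(list(mode = mode, Q_lumen = Q_lumen, Q_shell = Q_shell,
                 temperature = temperature, V_w = V_w, V_s = V_s, c_w0 = c_w0,
                 Q_w = if (aqueous_in_lumen) Q_lumen else Q_shell,
                 Q_s = if (aqueous_in_lumen) Q_shell else Q_lumen),
            class = "operating_point")
}

#' Predicted overall coefficient for a module and operating point
#'
#' The full "calculated" chain: Wilke-Chang diffusivities of the solute in
#' both phases, Leveque lumen coefficient (total lumen flow split over the
#' fibres), parallel-flow shell coefficient, organic-wetted membrane
#' coefficient, assembled by [overall_kw()] with the film roles assigned by
#' the operation mode (aqueous film = lumen film in in-out mode, shell film
#' in out-in mode).
#'
#' @param module [membrane_module()].
#' @param operating [operating_point()].
#' @param solute [solute_spec()].
#' @param aqueous,organic [phase_spec()] of the two phases; the organic phase
#'   is taken as membrane-wetting.
#' @param P partition coefficient (organic/aqueous).
#' @return `mass_transfer_breakdown` (see [overall_kw()]), with the lumen
#'   Graetz number attached as attribute `graetz`.
#' @export
predict_kw <- function(module, operating, solute, aqueous, organic, P) {
  stopifnot(inherits(module, "membrane_module"),
            inherits(operating, "operating_point"))
  temperature <- operating$temperature
  D_aq <- wilke_chang_diffusivity(solute, aqueous, temperature)
  D_org <- wilke_chang_diffusivity(solute, organic, temperature)
  aqueous_in_lumen <- operating$mode == "aqueous_in_lumen"
  lumen_phase_D <- if (aqueous_in_lumen) D_aq else D_org
  shell_phase_D <- if (aqueous_in_lumen) D_org else D_aq
  shell_phase <- if (aqueous_in_lumen) organic else aqueous
  k_lumen <- k_fibre_leveque(lumen_phase_D, module$d_i,
                             operating$Q_lumen / module$n_fibres, module$length)
  k_shell <- k_shell_parallel_flow(shell_phase_D, module, operating$Q_shell,
                                   shell_phase)
  k_m <- k_membrane(D_org, module)
  breakdown <- if (aqueous_in_lumen) {
    overall_kw(P, k_w = k_lumen, k_o = k_shell, k_m = k_m,
               module = module, mode = operating$mode)
  } else {
    overall_kw(P, k_w = k_shell, k_o = k_lumen, k_m = k_m,
               module = module, mode = operating$mode)
  }
  attr(breakdown, "graetz") <- k_lumen$graetz
  breakdown
}
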
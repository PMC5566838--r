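#' Henry's law parameters for a dissolved gas
#'
#' Bundles a reference Henry's law solubility constant with its van 't Hoff
#' temperature-dependence coefficient and a Setchenow (salting-out)
#' correction. The constant is in the concentration/pressure convention,
#' mol m-3 Pa-1, so that multiplying by a partial pressure in Pa yields
#' mol m-3 (equivalently mM).
#'
#' @param k_ref Henry constant at the reference temperature
#'   (mol m-3 Pa-1, > 0).
#' @param t_ref_k Reference temperature (K, default 298.15).
#' @param vant_hoff_k Temperature-dependence coefficient
#'   `-d(ln k)/d(1/T)` in kelvin (default 0 = no adjustment). Positive for
#'   gases whose solubility decreases on warming.
#' @param setchenow_l_mol Setchenow salting-out coefficient (L mol-1,
#'   default 0).
#' @param salinity_mol_l Effective salt concentration (mol L-1, default 0).
#'
#' @return Object of class `henry_params`.
#' @export
henry_params <- function(k_ref, t_ref_k = 298.15, vant_hoff_k = 0,
                         setchenow_l_mol = 0, salinity_mol_l = 0) {
  if (k_ref <= 0) stop("k_ref must be positive", call. = FALSE)
  if (t_ref_k <= 0) stop("t_ref_k must be positive", call. = FALSE)
  structure(list(
    k_ref = k_ref, t_ref_k = t_ref_k, vant_hoff_k = vant_hoff_k,
    setchenow_l_mol = setchenow_l_mol, salinity_mol_l = salinity_mol_l
  ), class = "henry_params")
}

#' Default Henry's law parameterisation for methane
#'
#' Standard-compilation values for CH4 in water: 1.4e-5 mol m-3 Pa-1 at
#' 298.15 K with a van 't Hoff coefficient of 1750 K; the Setchenow
#' coefficient 0.13 L mol-1 and a seawater-like salinity can be supplied to
#' add salting-out.
#'
#' @param salinity_mol_l Effective salt concentration (mol L-1, default 0,
#'   i.e. fresh water).
#'
#' @return A [henry_params()] object.
#' @export
ch4_henry_params <- function(salinity_mol_l = 0) {
  henry_params(k_ref = 1.4e-5, t_ref_k = 298.15, vant_hoff_k = 1750,
               setchenow_l_mol = 0.13, salinity_mol_l = salinity_mol_l)
}

#' Temperature- and salinity-adjusted Henry's law constant
#'
#' Van 't Hoff temperature dependence combined with Setchenow salting-out:
#' `k = k_ref * exp(B * (1/T - 1/T_ref)) * 10^(-ks * S)`.
#'
#' @param p A [henry_params()].
#' @param temperature_k Temperature in kelvin (> 0).
#'
#' @return Adjusted Henry constant (mol m-3 Pa-1).
#' @export
#' @examples
#' henry_constant_adjusted(ch4_henry_params(), 277)
henry_constant_adjusted <- function(p, temperature_k) {
  stopifnot(inherits(p, "henry_params"))
  if (any(temperature_k <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  p$k_ref * exp(p$vant_hoff_k * (1 / temperature_k - 1 / p$t_ref_k)) *
    10^(-p$setchenow_l_mol * p$salinity_mol_l)
}

#' Equilibrium dissolved concentration from a headspace partial pressure
#'
#' Henry's law: concentration (mol m-3, which is numerically mM) equals the
#' (adjusted) constant times the partial pressure. A pre-adjusted constant
#' such as 5.7e-6 mol m-3 Pa-1 for methane at seep-incubation conditions
#' can be passed directly.
#'
#' @param k Henry constant (mol m-3 Pa-1, > 0) — either a number or a
#'   [henry_params()] together with `temperature_k`.
#' @param partial_pressure_pa Partial pressure (Pa, >= 0).
#' @param temperature_k Required when `k` is a [henry_params()].
#'
#' @return Dissolved concentration in mM.
#' @export
#' @examples
#' dissolved_concentration(5.7e-6, 2e5) # about 1.1 mM
dissolved_concentration <- function(k, partial_pressure_pa,
                                    temperature_k = NULL) {
  if (inherits(k, "henry_params")) {
    if (is.null(temperature_k)) {
      stop("temperature_k is required with henry_params", call. = FALSE)
    }
    k <- henry_constant_adjusted(k, temperature_k)
  }
  if (any(k <= 0)) stop("Henry constant must be positive", call. = FALSE)
  if (any(partial_pressure_pa < 0)) {
    stop("partial pressure must be nonnegative", call. = FALSE)
  }
  k * partial_pressure_pa
}
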
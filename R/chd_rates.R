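#' Describe an incubation experiment
#'
#' Captures the geometry and tracer composition of one incubation: the
#' aqueous volume that buffers released deuterium, the volume of inoculum
#' (consolidated sediment, carbonate rock or liquid culture) used as the
#' rate denominator, the fraction of the methane headspace that is CH3D,
#' and the removed-and-replaced sampling events.
#'
#' @param incubation_id Identifier.
#' @param water_volume_l Aqueous volume in liters (> 0).
#' @param inoculum_volume_cm3 Inoculum volume in cubic centimeters (> 0);
#'   rates are expressed per cm3 of this volume.
#' @param f_ch3d Fraction of the methane headspace that is CH3D, in (0, 1].
#'   A 50:50 CH3D:CH4 headspace gives 0.5.
#' @param headspace_pa Named numeric vector of headspace partial pressures in
#'   Pa (e.g. `c(ch4 = 2e5)`); optional metadata.
#' @param is_killed_control Logical; autoclaved control incubation.
#' @param replicate_group Grouping label for biological replicates.
#' @param sampled_aliquots Tibble (or data.frame) of removed-and-replaced
#'   sampling events with columns `time_h` and `volume_l`; may be empty.
#'
#' @return An object of class `incubation_spec`.
#' @export
#' @examples
#' incubation_spec("anx1", water_volume_l = 0.02, inoculum_volume_cm3 = 10,
#'                 f_ch3d = 0.5, headspace_pa = c(ch4 = 2e5))
incubation_spec <- function(incubation_id,
                            water_volume_l,
                            inoculum_volume_cm3,
                            f_ch3d,
                            headspace_pa = c(ch4 = 2e5),
                            is_killed_control = FALSE,
                            replicate_group = incubation_id,
                            sampled_aliquots = NULL) {
  stopifnot(length(incubation_id) == 1)
  if (!is.numeric(water_volume_l) || water_volume_l <= 0) {
    stop("water_volume_l must be positive", call. = FALSE)
  }
  if (!is.numeric(inoculum_volume_cm3) || inoculum_volume_cm3 <= 0) {
    stop("inoculum_volume_cm3 must be positive", call. = FALSE)
  }
  if (!is.numeric(f_ch3d) || f_ch3d <= 0 || f_ch3d > 1) {
    stop("f_ch3d must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(sampled_aliquots)) {
    sampled_aliquots <- tibble::tibble(time_h = numeric(), volume_l = numeric())
  }
  sampled_aliquots <- tibble::as_tibble(sampled_aliquots)
  if (any(sampled_aliquots$volume_l >= water_volume_l)) {
    stop("a sampled aliquot cannot remove the whole water volume",
         call. = FALSE)
  }
  structure(list(
    incubation_id = incubation_id,
    water_volume_l = water_volume_l,
    inoculum_volume_cm3 = inoculum_volume_cm3,
    f_ch3d = f_ch3d,
    headspace_pa = headspace_pa,
    is_killed_control = isTRUE(is_killed_control),
    replicate_group = replicate_group,
    sampled_aliquots = sampled_aliquots
  ), class = "incubation_spec")
}

#' @export
print.incubation_spec <- function(x, ...) {
  cat(sprintf(
    "<incubation_spec> %s: %.4g L water, %.4g cm3 inoculum, f(CH3D) = %.3g%s\n",
    x$incubation_id, x$water_volume_l, x$inoculum_volume_cm3, x$f_ch3d,
    if (x$is_killed_control) " [killed control]" else ""))
  invisible(x)
}

#' Moles of hydrogen in the incubation water
#'
#' Water carries 55.5 mol of water per liter and two hydrogen atoms per
#' molecule, so the aqueous hydrogen inventory is
#' `water_volume_l * 55.5 * 2` moles. This inventory converts a change in
#' the aqueous D/H ratio into moles of newly arrived deuterium.
#'
#' @param spec An [incubation_spec()] or a numeric water volume in liters.
#'
#' @return Moles of hydrogen atoms.
#' @export
#' @examples
#' hydrogen_inventory(1)        # 111 mol
#' hydrogen_inventory(0.00944)  # a 9.44 ml culture
hydrogen_inventory <- function(spec) {
  v <- if (inherits(spec, "incubation_spec")) spec$water_volume_l else spec
  if (!is.numeric(v) || any(v <= 0)) {
    stop("water volume must be positive", call. = FALSE)
  }
  v * H_MOL_PER_L
}

#' New aqueous deuterium between two time points
#'
#' The deuterium mass balance: new moles of aqueous D between T1 and T2 are
#' `(D/H(T2) - D/H(T1)) * H`, where `H` is the (approximately constant)
#' hydrogen inventory. The sign is preserved — small negative values arise
#' from measurement noise and are reported as such.
#'
#' @param dh_t1,dh_t2 Dimensionless aqueous D/H ratios at the two times
#'   (> 0).
#' @param h_moles Moles of hydrogen in the incubation water (> 0), from
#'   [hydrogen_inventory()].
#'
#' @return Moles of new aqueous deuterium.
#' @export
#' @examples
#' d_new(1.40e-4, 1.45e-4, hydrogen_inventory(0.00944))
d_new <- function(dh_t1, dh_t2, h_moles) {
  if (any(dh_t1 <= 0) || any(dh_t2 <= 0)) {
    stop("D/H ratios must be positive", call. = FALSE)
  }
  if (any(h_moles <= 0)) stop("hydrogen inventory must be positive",
                              call. = FALSE)
  (dh_t2 - dh_t1) * h_moles
}

#' Maximum moles of methane activated from new deuterium
#'
#' CH3D carries one deuterium among four hydrogen positions. If only one
#' methane-derived hydrogen enters a water-exchangeable product per
#' activated molecule, the observed aqueous deuterium must be multiplied by
#' 4 to count activated methane molecules — the end-member that yields the
#' maximum consumption estimate. The factor is exposed because metabolisms
#' in which several hydrogens exchange call for a smaller factor (4/n for n
#' exchanging hydrogens).
#'
#' @param d_new_mol Moles of new aqueous deuterium.
#' @param stoichiometric_factor Multiplier (default 4).
#' @param alpha Pass-through fractionation multiplier applied to the
#'   observed deuterium (default 1, i.e. no fractionation correction);
#'   provided for sensitivity analysis only.
#'
#' @return Moles of methane activated (the maximum-consumption estimate).
#' @export
methane_activated <- function(d_new_mol, stoichiometric_factor = 4,
                              alpha = 1) {
  if (stoichiometric_factor < 1) {
    stop("stoichiometric_factor must be >= 1", call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  d_new_mol * stoichiometric_factor / alpha
}

#' Correct activated methane for the CH3D headspace fraction
#'
#' Only the CH3D fraction of the methane headspace contributes deuterium,
#' so the activated-methane estimate is scaled up by dividing by that
#' fraction.
#'
#' @param c_mol Moles of methane activated (from [methane_activated()]).
#' @param f_ch3d Fraction of methane headspace that is CH3D, in (0, 1].
#'
#' @return Corrected moles of methane activated.
#' @export
headspace_correct <- function(c_mol, f_ch3d) {
  if (!is.numeric(f_ch3d) || any(f_ch3d <= 0) || any(f_ch3d > 1)) {
    stop("f_ch3d must lie in (0, 1] (zero means no tracer present)",
         call. = FALSE)
  }
  c_mol / f_ch3d
}

#' Methane activation rate from corrected consumption
#'
#' Converts corrected moles of activated methane into the conventional rate
#' units, nanomoles per cubic centimeter of inoculum per day.
#'
#' @param c_corr_mol Corrected moles of methane activated.
#' @param time_days Incubation interval in days (> 0).
#' @param volume_cm3 Inoculum volume in cm3 (> 0).
#' @param se_c_corr_mol Standard error of `c_corr_mol` (default 0).
#' @param incubation_id Optional identifier carried into the result.
#' @param t_start_h Interval start in hours (default 0).
#'
#' @return A one-row rate-estimate tibble with columns `incubation_id`,
#'   `t_start_h`, `t_end_h`, `rate_nmol_cm3_d`, `se`, `cumulative_nmol`,
#'   `method` (`"CH3D"`).
#' @export
#' @examples
#' rate_chd(4.19136e-5, time_days = 8, volume_cm3 = 10)
rate_chd <- function(c_corr_mol, time_days, volume_cm3,
                     se_c_corr_mol = 0, incubation_id = NA_character_,
                     t_start_h = 0) {
  if (any(time_days <= 0)) stop("incubation time must be positive",
                                call. = FALSE)
  if (any(volume_cm3 <= 0)) stop("inoculum volume must be positive",
                                 call. = FALSE)
  tibble::tibble(
    incubation_id = incubation_id,
    t_start_h = t_start_h,
    t_end_h = t_start_h + time_days * 24,
    rate_nmol_cm3_d = c_corr_mol * 1e9 / (time_days * volume_cm3),
    se = se_c_corr_mol * 1e9 / (time_days * volume_cm3),
    cumulative_nmol = c_corr_mol * 1e9,
    method = "CH3D"
  )
}

#' Adjust a D/H series for removed-and-replaced sampling aliquots
#'
#' Each sampling event removes an aliquot of incubation water (carrying some
#' of the released deuterium) and replaces it with medium at the background
#' D/H ratio. Two accounting modes are offered. `"approximate"` treats the
#' hydrogen inventory as constant and ignores removed deuterium, which is
#' the conventional approximation (the inventory change is negligible for
#' ml-scale aliquots). `"exact"` additionally credits the deuterium carried
#' away by each aliquot — `volume_l * 111 * (D/H at removal - baseline)`
#' moles — back to the cumulative new-deuterium series, interpolating the
#' series linearly at aliquot times.
#'
#' @param series Tibble with columns `time_h` (strictly increasing) and
#'   `d_h` (> 0); optionally `se`.
#' @param spec An [incubation_spec()] whose `sampled_aliquots` fall within
#'   the series time span.
#' @param mode `"approximate"` (default) or `"exact"`.
#' @param baseline_d_h Background D/H of the replacement medium; defaults to
#'   the series' first observation.
#'
#' @return Tibble `time_h`, `d_new_mol`: cumulative new aqueous deuterium
#'   relative to the first time point, after the chosen accounting.
#' @export
sampling_replacement_adjust <- function(series, spec,
                                        mode = c("approximate", "exact"),
                                        baseline_d_h = NULL) {
  mode <- match.arg(mode)
  series <- tibble::as_tibble(series)
  stopifnot(all(c("time_h", "d_h") %in% names(series)))
  if (any(diff(series$time_h) <= 0)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  if (any(series$d_h <= 0)) stop("D/H ratios must be positive", call. = FALSE)
  h <- hydrogen_inventory(spec)
  if (is.null(baseline_d_h)) baseline_d_h <- series$d_h[1]

  out <- tibble::tibble(
    time_h = series$time_h,
    d_new_mol = (series$d_h - series$d_h[1]) * h
  )
  if (mode == "approximate" || nrow(spec$sampled_aliquots) == 0) {
    return(out)
  }
  alq <- spec$sampled_aliquots
  if (any(alq$time_h < min(series$time_h)) ||
      any(alq$time_h > max(series$time_h))) {
    stop("sampled aliquot times fall outside the series span", call. = FALSE)
  }
  dh_at <- approx(series$time_h, series$d_h, xout = alq$time_h)$y
  credit <- alq$volume_l * H_MOL_PER_L * (dh_at - baseline_d_h)
  for (i in seq_along(credit)) {
    later <- out$time_h >= alq$time_h[i]
    out$d_new_mol[later] <- out$d_new_mol[later] + credit[i]
  }
  out
}

#' Methane activation rates from a calibrated D/H time series
#'
#' Applies the full deuterium mass-balance chain — hydrogen inventory, new
#' deuterium, stoichiometric scaling, CH3D headspace correction, and
#' conversion to nmol cm-3 d-1 — to every interval of a calibrated D/H
#' series. By default each rate is cumulative from the first time point
#' (matching the maximum-consumption reading); `intervals = "consecutive"`
#' instead differences consecutive time points. Standard errors are
#' propagated from the per-time-point D/H standard errors (independence
#' assumed, so SE of a difference adds in quadrature) through the linear
#' chain.
#'
#' @inheritParams sampling_replacement_adjust
#' @param spec An [incubation_spec()].
#' @param stoichiometric_factor,alpha See [methane_activated()].
#' @param intervals `"from_t0"` (default) or `"consecutive"`.
#' @param aliquot_mode Accounting mode passed to
#'   [sampling_replacement_adjust()].
#'
#' @return Rate-estimate tibble with one row per interval (columns as in
#'   [rate_chd()]).
#' @export
chd_rate_series <- function(series, spec, stoichiometric_factor = 4,
                            alpha = 1,
                            intervals = c("from_t0", "consecutive"),
                            aliquot_mode = c("approximate", "exact")) {
  intervals <- match.arg(intervals)
  aliquot_mode <- match.arg(aliquot_mode)
  series <- tibble::as_tibble(series)
  if (!"se" %in% names(series)) series$se <- 0
  if (nrow(series) < 2) {
    stop("need at least two time points to compute a rate", call. = FALSE)
  }
  dnew <- sampling_replacement_adjust(series, spec, mode = aliquot_mode)
  n <- nrow(series)
  i1 <- if (intervals == "from_t0") rep(1L, n - 1L) else seq_len(n - 1L)
  i2 <- seq(2L, n)

  h <- hydrogen_inventory(spec)
  dn <- dnew$d_new_mol[i2] - dnew$d_new_mol[i1]
  se_dn <- sqrt(series$se[i1]^2 + series$se[i2]^2) * h
  scale <- stoichiometric_factor / alpha / spec$f_ch3d
  c_corr <- dn * scale
  se_c <- se_dn * scale
  t_days <- (series$time_h[i2] - series$time_h[i1]) / 24

  tibble::tibble(
    incubation_id = spec$incubation_id,
    t_start_h = series$time_h[i1],
    t_end_h = series$time_h[i2],
    rate_nmol_cm3_d = c_corr * 1e9 / (t_days * spec$inoculum_volume_cm3),
    se = se_c * 1e9 / (t_days * spec$inoculum_volume_cm3),
    cumulative_nmol = c_corr * 1e9,
    method = "CH3D"
  )
}

#' Subtract the mean killed-control rate from a sample rate
#'
#' Killed (autoclaved) control incubations quantify abiotic signal; their
#' mean rate is subtracted from each live sample's rate. The standard error
#' of the control mean (replicate scatter for n >= 2 controls, the single
#' control's own SE otherwise) is combined with the sample SE in
#' quadrature. Negative corrected rates are retained — sub-zero scatter is
#' diagnostic, not an error.
#'
#' @param sample A rate-estimate tibble (one or more rows).
#' @param killed A rate-estimate tibble of killed-control estimates with the
#'   same `method` tag.
#'
#' @return `sample` with corrected `rate_nmol_cm3_d`, `cumulative_nmol` and
#'   `se`.
#' @export
subtract_killed_control <- function(sample, killed) {
  killed <- tibble::as_tibble(killed)
  sample <- tibble::as_tibble(sample)
  if (nrow(killed) == 0) stop("no killed-control estimates", call. = FALSE)
  if (!all(killed$method == sample$method[1]) ||
      length(unique(sample$method)) != 1) {
    stop("method tags of sample and killed controls must match",
         call. = FALSE)
  }
  km <- mean(killed$rate_nmol_cm3_d)
  k_se <- if (nrow(killed) > 1) {
    sd(killed$rate_nmol_cm3_d) / sqrt(nrow(killed))
  } else {
    killed$se[1]
  }
  kc <- mean(killed$cumulative_nmol)
  sample$rate_nmol_cm3_d <- sample$rate_nmol_cm3_d - km
  sample$cumulative_nmol <- sample$cumulative_nmol - kc
  sample$se <- sqrt(sample$se^2 + k_se^2)
  sample
}

#' Aggregate rate estimates across biological replicates
#'
#' Mean rate and standard error (n-1 variance, SE = sd/sqrt(n)) across
#' replicate estimates sharing an interval and method. A single estimate is
#' returned unchanged with SE 0 and a warning.
#'
#' @param estimates Rate-estimate tibble, one row per replicate.
#'
#' @return A one-row rate-estimate tibble with `n_replicates` added.
#' @export
aggregate_replicates <- function(estimates) {
  estimates <- tibble::as_tibble(estimates)
  if (nrow(estimates) == 0) stop("no estimates to aggregate", call. = FALSE)
  if (length(unique(estimates$method)) != 1) {
    stop("cannot aggregate estimates with mixed method tags", call. = FALSE)
  }
  if (length(unique(estimates$t_start_h)) != 1 ||
      length(unique(estimates$t_end_h)) != 1) {
    stop("cannot aggregate estimates over mixed intervals", call. = FALSE)
  }
  n <- nrow(estimates)
  if (n == 1) {
    warning("single replicate: SE set to 0", call. = FALSE)
  }
  tibble::tibble(
    incubation_id = paste(unique(estimates$incubation_id), collapse = "+"),
    t_start_h = estimates$t_start_h[1],
    t_end_h = estimates$t_end_h[1],
    rate_nmol_cm3_d = mean(estimates$rate_nmol_cm3_d),
    se = if (n > 1) sd(estimates$rate_nmol_cm3_d) / sqrt(n) else 0,
    cumulative_nmol = mean(estimates$cumulative_nmol),
    method = estimates$method[1],
    n_replicates = n
  )
}
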
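spec_seep <- function(...) {
  incubation_spec("anx", water_volume_l = 0.02, inoculum_volume_cm3 = 10,
                  f_ch3d = 0.5, ...)
}

test_that("hydrogen inventory follows the 55.5 x 2 water stoichiometry", {
  expect_equal(hydrogen_inventory(1), 111)
  expect_equal(hydrogen_inventory(0.00944), 1.04784, tolerance = 1e-12)
  sp <- spec_seep()
  expect_equal(hydrogen_inventory(sp), 0.02 * 111)
  expect_error(hydrogen_inventory(0), "positive")
})

test_that("deuterium mass balance and stoichiometric chain match hand arithmetic", {
  h <- hydrogen_inventory(0.00944)
  expect_equal(d_new(1.40e-4, 1.40e-4, h), 0)
  expect_equal(d_new(1.40e-4, 1.45e-4, h), 5.2392e-6, tolerance = 1e-9)
  # sign symmetry: a drop in D/H gives the mirrored negative value
  expect_equal(d_new(1.45e-4, 1.40e-4, h), -5.2392e-6, tolerance = 1e-9)

  expect_equal(methane_activated(5.2392e-6), 2.09568e-5, tolerance = 1e-12)
  expect_equal(methane_activated(0), 0)
  expect_equal(methane_activated(5.2392e-6, stoichiometric_factor = 1),
               5.2392e-6)

  expect_equal(headspace_correct(2.09568e-5, 0.5), 4.19136e-5,
               tolerance = 1e-12)
  expect_equal(headspace_correct(3, 1), 3)
  expect_error(headspace_correct(1, 0), "0, 1")
})

test_that("rate conversion to nmol cm-3 d-1 is correct and invertible", {
  r <- rate_chd(4.19136e-5, time_days = 8, volume_cm3 = 10)
  expect_equal(r$rate_nmol_cm3_d, 523.92, tolerance = 1e-6)
  expect_equal(r$method, "CH3D")
  expect_equal(rate_chd(1e-6, 4, 10)$rate_nmol_cm3_d, 25)
  expect_equal(rate_chd(0, 4, 10)$rate_nmol_cm3_d, 0)
  expect_error(rate_chd(1e-6, 0, 10), "time")
  # unit consistency: rate x t x v x 1e-9 returns the input moles
  for (c_corr in c(1e-7, 3.3e-5, 2e-3)) {
    r <- rate_chd(c_corr, 8, 10)
    expect_equal(r$rate_nmol_cm3_d * 8 * 10 * 1e-9, c_corr,
                 tolerance = 1e-12)
  }
})

test_that("rate series is linear in the D/H change and in water volume", {
  sp <- spec_seep()
  base <- 1.40e-4
  mk <- function(delta) tibble::tibble(time_h = c(0, 192),
                                       d_h = c(base, base + delta), se = 0)
  r1 <- chd_rate_series(mk(1e-6), sp)
  r2 <- chd_rate_series(mk(2e-6), sp)
  expect_equal(r2$rate_nmol_cm3_d, 2 * r1$rate_nmol_cm3_d)

  sp2 <- incubation_spec("anx2", water_volume_l = 0.04,
                         inoculum_volume_cm3 = 10, f_ch3d = 0.5)
  r3 <- chd_rate_series(mk(1e-6), sp2)
  expect_equal(r3$cumulative_nmol, 2 * r1$cumulative_nmol)

  # constant series -> exactly zero rate on every interval
  flat <- tibble::tibble(time_h = c(0, 48, 96, 192), d_h = base, se = 0)
  expect_true(all(chd_rate_series(flat, sp)$rate_nmol_cm3_d == 0))
  expect_true(all(chd_rate_series(flat, sp,
                                  intervals = "consecutive")$rate_nmol_cm3_d == 0))
})

test_that("aliquot bookkeeping credits removed deuterium", {
  sp <- incubation_spec("c", water_volume_l = 1, inoculum_volume_cm3 = 10,
                        f_ch3d = 0.5,
                        sampled_aliquots = tibble::tibble(time_h = 100,
                                                          volume_l = 0.001))
  series <- tibble::tibble(time_h = c(0, 100, 200),
                           d_h = c(1.40e-4, 1.45e-4, 1.50e-4), se = 0)
  approxed <- sampling_replacement_adjust(series, sp, "approximate")
  exact <- sampling_replacement_adjust(series, sp, "exact")
  # credit = 0.001 L x 111 mol/L x (1.45e-4 - 1.40e-4) = 5.55e-7 mol D
  # applied from t >= 100
  expect_equal(exact$d_new_mol[2] - approxed$d_new_mol[2], 5.55e-7,
               tolerance = 1e-12)
  expect_equal(exact$d_new_mol[1], approxed$d_new_mol[1])
  # enriched aliquots only ever increase the exact-mode cumulative D
  expect_true(all(exact$d_new_mol >= approxed$d_new_mol))

  # no aliquots -> both modes identical
  sp0 <- incubation_spec("c0", water_volume_l = 1, inoculum_volume_cm3 = 10,
                         f_ch3d = 0.5)
  expect_identical(sampling_replacement_adjust(series, sp0, "approximate"),
                   sampling_replacement_adjust(series, sp0, "exact"))
})

test_that("killed-control subtraction recentres rates without clamping", {
  mk_rate <- function(v, se = 0, id = "x") tibble::tibble(
    incubation_id = id, t_start_h = 0, t_end_h = 192,
    rate_nmol_cm3_d = v, se = se, cumulative_nmol = v * 80, method = "CH3D")
  killed <- dplyr::bind_rows(mk_rate(1.5), mk_rate(2.0), mk_rate(2.5))
  out <- subtract_killed_control(mk_rate(52.4), killed)
  expect_equal(out$rate_nmol_cm3_d, 50.4)
  # negative corrected rates are reported, not clamped
  neg <- subtract_killed_control(mk_rate(1.0), killed)
  expect_equal(neg$rate_nmol_cm3_d, -1.0)
  # zero controls leave the sample unchanged
  zero <- dplyr::bind_rows(mk_rate(0), mk_rate(0))
  expect_equal(subtract_killed_control(mk_rate(7), zero)$rate_nmol_cm3_d, 7)
  # SEs combine in quadrature with the control-mean SE
  k_se <- sd(c(1.5, 2, 2.5)) / sqrt(3)
  out_se <- subtract_killed_control(mk_rate(52.4, se = 3), killed)
  expect_equal(out_se$se, sqrt(9 + k_se^2))
  # mixing methods is an error
  c14 <- mk_rate(1); c14$method <- "C14"
  expect_error(subtract_killed_control(mk_rate(5), c14), "method")
})

test_that("replicate aggregation uses sd/sqrt(n) with n-1 variance", {
  mk <- function(v, id) tibble::tibble(
    incubation_id = id, t_start_h = 0, t_end_h = 192,
    rate_nmol_cm3_d = v, se = 0, cumulative_nmol = v, method = "CH3D")
  reps <- dplyr::bind_rows(mk(9, "a"), mk(10, "b"), mk(11, "c"))
  agg <- aggregate_replicates(reps)
  expect_equal(agg$rate_nmol_cm3_d, 10)
  expect_equal(agg$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(agg$n_replicates, 3)

  same <- dplyr::bind_rows(mk(10, "a"), mk(10, "b"), mk(10, "c"))
  expect_equal(aggregate_replicates(same)$se, 0)

  expect_warning(one <- aggregate_replicates(mk(5, "a")), "single replicate")
  expect_equal(one$rate_nmol_cm3_d, 5)

  bad <- dplyr::bind_rows(mk(9, "a"), mk(10, "b"))
  bad$t_end_h[2] <- 100
  expect_error(aggregate_replicates(bad), "mixed intervals")
})
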
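test_that("last-five retention keeps the expected injection counts", {
  run <- make_run(list(S1 = -30, S2 = -40))
  kept <- qc_filter(run)
  # 2 samples x 2 rounds x 5 + 2 standards x 1 round x 5
  expect_equal(nrow(kept), 30)
  per_sample <- table(kept$sample_id)
  expect_equal(unname(per_sample[c("S1", "S2")]), c(10L, 10L),
               ignore_attr = TRUE)
  # only the final five of each round survive
  expect_true(all(kept$injection >= 6))

  # a full clean 4 x 10 analyte keeps 20
  inj <- dplyr::bind_rows(
    make_rounds("std_hi", 0.5, 1), make_rounds("std_lo", -73.4, 1, start_pos = 10),
    make_rounds("A", -25, 4, start_pos = 20)
  )
  run4 <- analysis_run(inj, two_standards())
  expect_equal(sum(qc_filter(run4)$sample_id == "A"), 20)
})

test_that("diagnostic exclusions remove flagged injections and log reasons", {
  inj <- dplyr::bind_rows(
    make_rounds("std_hi", 0.5, 1), make_rounds("std_lo", -73.4, 1, start_pos = 10),
    make_rounds("A", -25, 2, start_pos = 20)
  )
  # round 1 of A: all injections drifting too warm; one pressure flag in round 2
  inj$temp_change_rate[inj$sample_id == "A" & inj$round == 1] <- 0.4
  inj$pressure_rising[inj$sample_id == "A" & inj$round == 2 &
                        inj$injection == 10] <- TRUE
  run <- analysis_run(inj, two_standards())
  kept <- qc_filter(run)
  expect_equal(sum(kept$sample_id == "A" & kept$round == 1), 0)
  expect_equal(sum(kept$sample_id == "A"), 4)
  log <- attr(kept, "excluded")
  expect_setequal(unique(log$reason),
                  c("memory_window", "temperature_drift", "pressure_rising"))
  # exactly one pressure exclusion, recorded once
  expect_equal(sum(log$reason == "pressure_rising"), 1)

  # an analyte losing every injection is a hard error, not a silent drop
  inj2 <- inj
  inj2$temp_change_rate[inj2$sample_id == "A"] <- 0.4
  expect_error(qc_filter(analysis_run(inj2, two_standards())),
               "no injections retained.*A")
})

test_that("rounds shorter than the retention window keep all injections", {
  inj <- dplyr::bind_rows(
    make_rounds("std_hi", 0.5, 1), make_rounds("std_lo", -73.4, 1, start_pos = 10),
    make_rounds("A", -25, 1, per_round = 3, start_pos = 20)
  )
  kept <- qc_filter(analysis_run(inj, two_standards()))
  expect_equal(sum(kept$sample_id == "A"), 3)
})

test_that("calibration segments partition the run and demand both standards", {
  # 120 injections -> 3 segments of 40, each with its own standards
  std <- two_standards()
  blocks <- lapply(0:2, function(b) {
    blk <- dplyr::bind_rows(
      make_rounds("std_hi", 0.5 + b, 1, start_pos = 40 * b),
      make_rounds("std_lo", -73.4 + b, 1, start_pos = 40 * b + 10),
      make_rounds(paste0("S", b), -30, 2, start_pos = 40 * b + 20)
    )
    # each re-measurement of a standard is its own analysis round
    blk$round[blk$sample_id %in% c("std_hi", "std_lo")] <- b + 1
    blk
  })
  run <- analysis_run(dplyr::bind_rows(blocks), std)
  segs <- build_calibration_segments(run)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start_position, c(1, 41, 81))
  expect_equal(segs$end_position, c(41, 81, 121))

  # 45 injections -> 2 segments; the 5-injection tail has no standards
  inj45 <- dplyr::bind_rows(
    make_rounds("std_hi", 0.5, 1), make_rounds("std_lo", -73.4, 1, start_pos = 10),
    make_rounds("A", -30, 2, start_pos = 20),
    make_rounds("B", -31, 1, per_round = 5, start_pos = 40)
  )
  expect_error(build_calibration_segments(analysis_run(inj45, std)),
               "segment 2.*missing standard")

  # a single 40-injection span is one segment
  run40 <- make_run(list(A = -30))
  expect_equal(nrow(build_calibration_segments(run40)), 1)
})

test_that("two-point calibration reproduces the hand-computed map", {
  run <- make_run(list(A = -34), std_measured = c(2.0, -70.0))
  segs <- build_calibration_segments(run)
  expect_equal(segs$slope, 73.9 / 72.0, tolerance = 1e-12)
  expect_equal(calibrate_delta(-34, segs[1, ]), -36.45, tolerance = 1e-10)
  # anchors map to their known values exactly
  expect_equal(calibrate_delta(2.0, segs[1, ]), 0.5, tolerance = 1e-12)
  expect_equal(calibrate_delta(-70.0, segs[1, ]), -73.4, tolerance = 1e-12)
  # identity anchors give the identity map
  run_id <- make_run(list(A = -10), std_measured = c(0.5, -73.4))
  seg_id <- build_calibration_segments(run_id)
  expect_equal(calibrate_delta(-10, seg_id[1, ]), -10, tolerance = 1e-12)
})

test_that("calibration anchor exactness holds under noise and drift", {
  cfg <- simulation_config(seed = 21)
  ex <- simulate_experiment(cfg)
  segs <- build_calibration_segments(ex$run)
  kept <- qc_filter(ex$run)
  std <- ex$run$standards
  for (k in seq_len(nrow(segs))) {
    in_seg <- kept[kept$position >= segs$start_position[k] &
                     kept$position < segs$end_position[k] &
                     kept$sample_id %in% std$standard_id, ]
    means <- tapply(in_seg$raw_delta_d, in_seg$sample_id, mean)
    for (id in names(means)) {
      expect_equal(calibrate_delta(unname(means[[id]]), segs[k, ]),
                   std$known_delta_d[std$standard_id == id],
                   tolerance = 1e-12)
    }
  }
  # calibration is strictly increasing in raw when the slope is positive
  expect_true(all(segs$slope > 0))
  expect_true(all(diff(calibrate_delta(seq(-100, 10, 5), segs[1, ])) > 0))
})

test_that("delta/ratio conversion matches the reference scale and round-trips", {
  expect_equal(delta_to_ratio(0), 155.76e-6, tolerance = 1e-12)
  expect_equal(delta_to_ratio(0.5), 155.838e-6, tolerance = 1e-6)
  expect_equal(delta_to_ratio(-73.4), 155.76e-6 * 0.9266, tolerance = 1e-6)
  deltas <- seq(-900, 500, length.out = 31)
  expect_equal(ratio_to_delta(delta_to_ratio(deltas)), deltas,
               tolerance = 1e-10)
  expect_error(delta_to_ratio(-1000), "nonphysical")
  expect_error(ratio_to_delta(0), "positive")
})

test_that("per-analyte summaries use n-1 variance and flag degenerate n", {
  x <- c(2.05, 2.01, 1.96, 2.08, 1.86)
  cal <- tibble::tibble(sample_id = "A", delta_vsmow = x, d_h = x)
  s <- summarize_samples(cal)
  expect_equal(s$mean_d_h, 1.992, tolerance = 1e-12)
  expect_equal(s$se_d_h, 0.03865, tolerance = 1e-3)
  expect_equal(s$n_used, 5)

  # identical values -> zero SE
  cal0 <- tibble::tibble(sample_id = "B", delta_vsmow = rep(1, 20),
                         d_h = rep(1.4e-4, 20))
  expect_equal(summarize_samples(cal0)$se_d_h, 0)

  cal1 <- tibble::tibble(sample_id = "C", delta_vsmow = 1, d_h = 1.4e-4)
  expect_warning(s1 <- summarize_samples(cal1), "single retained injection")
  expect_equal(s1$se_d_h, 0)
})

test_that("missing diagnostics are treated as passing with a warning", {
  inj <- dplyr::bind_rows(
    make_rounds("A", -30, 2),
    make_rounds("std_hi", 0.5, 1, start_pos = 20),
    make_rounds("std_lo", -73.4, 1, start_pos = 30)
  )
  inj$temp_change_rate <- NULL
  inj$pressure_rising <- NULL
  expect_warning(
    expect_warning(
      run <- analysis_run(inj, two_standards()),
      "temp_change_rate"),
    "pressure_rising")
  expect_equal(sum(qc_filter(run)$sample_id == "A"), 10)
})
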
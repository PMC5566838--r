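read_checked_csv <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(label, " file not found: ", path, call. = FALSE)
  }
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop(label, " file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d
}

#' Read LWIA injection data and standards from CSV
#'
#' `read_injections()` expects columns `sample_id, round, injection,
#' raw_delta_d, position`; the diagnostics `temp_change_rate` and
#' `pressure_rising` are optional (absent diagnostics are treated as
#' passing, with a warning). `read_standards()` expects
#' `standard_id, known_delta_d_permil`.
#'
#' @param path Path to the injections CSV.
#' @param standards_path Path to the standards CSV.
#'
#' @return An [analysis_run()].
#' @export
read_injections <- function(path, standards_path) {
  inj <- read_checked_csv(
    path, c("sample_id", "round", "injection", "raw_delta_d", "position"),
    "injections")
  std <- read_standards(standards_path)
  bad <- which(!is.finite(inj$raw_delta_d))
  if (length(bad) > 0) {
    stop("unparseable raw_delta_d in ", path, " at data row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  analysis_run(inj, std)
}

#' @rdname read_injections
#' @export
read_standards <- function(standards_path) {
  std <- read_checked_csv(standards_path,
                          c("standard_id", "known_delta_d_permil"),
                          "standards")
  tibble::tibble(standard_id = std$standard_id,
                 known_delta_d = std$known_delta_d_permil)
}

#' Read incubation metadata from CSV
#'
#' Expects columns `incubation_id, water_volume_l, inoculum_volume_cm3,
#' f_ch3d, is_killed_control, replicate_group`.
#'
#' @param path Path to the metadata CSV.
#'
#' @return Named list of [incubation_spec()] objects.
#' @export
read_incubations <- function(path) {
  d <- read_checked_csv(
    path, c("incubation_id", "water_volume_l", "inoculum_volume_cm3",
            "f_ch3d", "is_killed_control", "replicate_group"),
    "incubations")
  specs <- lapply(seq_len(nrow(d)), function(i) {
    incubation_spec(
      d$incubation_id[i], d$water_volume_l[i], d$inoculum_volume_cm3[i],
      d$f_ch3d[i], is_killed_control = isTRUE(as.logical(d$is_killed_control[i])),
      replicate_group = d$replicate_group[i]
    )
  })
  setNames(specs, d$incubation_id)
}

#' Read a calibrated D/H time-series CSV
#'
#' Expects columns `incubation_id, time_h, d_h, se`.
#'
#' @param path Path to the series CSV.
#'
#' @return Named list of per-incubation tibbles (`time_h`, `d_h`, `se`).
#' @export
read_dh_series <- function(path) {
  d <- read_checked_csv(path, c("incubation_id", "time_h", "d_h", "se"),
                        "D/H series")
  out <- split(tibble::tibble(time_h = d$time_h, d_h = d$d_h, se = d$se),
               d$incubation_id)
  lapply(out, function(x) dplyr::arrange(x, .data$time_h))
}

#' Read radiotracer measurements from CSV
#'
#' Expects columns `incubation_id, activity_14co2_bq,
#' activity_14ch4_vial1_bq, activity_14ch4_vial2_bq, time_d,
#' inoculum_volume_cm3, total_ch4_mol`.
#'
#' @param path Path to the radiocarbon CSV.
#'
#' @return The measurements tibble (one row per sample).
#' @export
read_radiocarbon <- function(path) {
  read_checked_csv(
    path, c("incubation_id", "activity_14co2_bq", "activity_14ch4_vial1_bq",
            "activity_14ch4_vial2_bq", "time_d", "inoculum_volume_cm3",
            "total_ch4_mol"),
    "radiocarbon")
}

#' Write a rate-estimate table to CSV
#'
#' @param rates Rate-estimate tibble.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  readr::write_csv(rates, path)
  invisible(path)
}

default_pipeline_config <- function() {
  list(
    calibration = list(segment_size = 40, keep_last = 5,
                       temp_limit = TEMP_DRIFT_LIMIT_C_PER_H,
                       r_vsmow = R_VSMOW),
    rates = list(stoichiometric_factor = 4, alpha = 1,
                 intervals = "from_t0", aliquot_mode = "approximate",
                 subtract_killed = FALSE),
    interpretation = list(scaling_factor = 1.5,
                          exchange_model = "full_oxidation_complement")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration file and
#' merges it over the package defaults (segment size 40, keep-last 5,
#' temperature threshold 0.3 degrees C per hour, stoichiometric factor 4).
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for defaults.
#'
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Run the full dual-tracer rate pipeline
#'
#' Ties the stages together: LWIA QC + calibration + per-analyte summary
#' (when raw injections are supplied) or a ready calibrated D/H series;
#' the CH3D rate calculus per incubation with optional killed-control
#' subtraction; radiotracer rates; and per-incubation D/14C tracer ratios
#' with both hydrogen-exchange interpretations. All outputs are written as
#' CSV to `output_dir` (rates, tracer ratios, calibration segments and the
#' QC exclusion log), and the run is deterministic given inputs and
#' configuration.
#'
#' @param config Configuration list from [read_pipeline_config()] (or a
#'   path to one). Input paths live under `paths:` with keys `injections`
#'   + `standards` and/or `dh_series`, plus `incubations` and optionally
#'   `radiocarbon`.
#' @param output_dir Directory for output CSVs (created if needed);
#'   `NULL` writes nothing.
#'
#' @return List with `measurements`, `chd_rates`, `c14_rates`,
#'   `tracer_ratios`, `segments`, `qc_log`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- merge_config(default_pipeline_config(), config)
  paths <- cfg$paths
  if (is.null(paths)) stop("config has no 'paths' block", call. = FALSE)

  measurements <- NULL
  segments <- NULL
  qc_log <- NULL
  if (!is.null(paths$injections)) {
    run <- read_injections(paths$injections, paths$standards)
    processed <- process_lwia_run(
      run, segment_size = cfg$calibration$segment_size,
      keep_last = cfg$calibration$keep_last,
      temp_limit = cfg$calibration$temp_limit,
      r_vsmow = cfg$calibration$r_vsmow)
    measurements <- processed$measurements
    segments <- processed$segments
    qc_log <- processed$excluded[, c("sample_id", "round", "injection",
                                     "position", "reason")]
    series <- dh_series_from_measurements(measurements)
  } else if (!is.null(paths$dh_series)) {
    series <- read_dh_series(paths$dh_series)
  } else {
    stop("config paths must provide either injections+standards or dh_series",
         call. = FALSE)
  }

  specs <- read_incubations(paths$incubations)
  missing_series <- setdiff(names(specs), names(series))
  if (length(missing_series) > 0) {
    stop("no D/H series for incubation(s): ",
         paste(missing_series, collapse = ", "), call. = FALSE)
  }

  chd <- dplyr::bind_rows(lapply(specs, function(sp) {
    chd_rate_series(series[[sp$incubation_id]], sp,
                    stoichiometric_factor = cfg$rates$stoichiometric_factor,
                    alpha = cfg$rates$alpha,
                    intervals = cfg$rates$intervals,
                    aliquot_mode = cfg$rates$aliquot_mode)
  }))
  killed_ids <- names(specs)[vapply(specs, function(s) s$is_killed_control,
                                    TRUE)]
  if (isTRUE(cfg$rates$subtract_killed) && length(killed_ids) > 0) {
    killed <- chd[chd$incubation_id %in% killed_ids, ]
    live <- chd[!chd$incubation_id %in% killed_ids, ]
    live <- dplyr::bind_rows(lapply(
      split(live, list(live$t_start_h, live$t_end_h), drop = TRUE),
      function(g) {
        kg <- killed[killed$t_start_h == g$t_start_h[1] &
                       killed$t_end_h == g$t_end_h[1], ]
        if (nrow(kg) == 0) g else subtract_killed_control(g, kg)
      }))
    chd <- dplyr::bind_rows(live, killed)
  }

  c14 <- NULL
  ratios <- NULL
  if (!is.null(paths$radiocarbon)) {
    rc <- read_radiocarbon(paths$radiocarbon)
    c14 <- dplyr::bind_rows(lapply(seq_len(nrow(rc)), function(i) {
      m <- radiocarbon_measurement(
        rc$incubation_id[i], rc$activity_14co2_bq[i],
        rc$activity_14ch4_vial1_bq[i], rc$activity_14ch4_vial2_bq[i],
        incubation_time_d = rc$time_d[i],
        inoculum_volume_cm3 = rc$inoculum_volume_cm3[i])
      rate_14c(m, rc$total_ch4_mol[i])
    }))
    ratios <- tracer_ratio_table(chd, c14)
  }

  out <- list(measurements = measurements, chd_rates = chd, c14_rates = c14,
              tracer_ratios = ratios, segments = segments, qc_log = qc_log)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_rates(chd, file.path(output_dir, "rates_chd.csv"))
    if (!is.null(c14)) write_rates(c14, file.path(output_dir, "rates_14c.csv"))
    if (!is.null(ratios)) {
      readr::write_csv(ratios, file.path(output_dir, "tracer_ratios.csv"))
    }
    if (!is.null(segments)) {
      readr::write_csv(segments, file.path(output_dir,
                                           "calibration_segments.csv"))
    }
    if (!is.null(qc_log)) {
      readr::write_csv(qc_log, file.path(output_dir, "qc_exclusions.csv"))
    }
  }
  out
}

#' Per-incubation D/14C tracer ratios from matched rate tables
#'
#' Pairs each incubation's end-point CH3D rate with its radiotracer rate at
#' the closest sampling time and computes the tracer ratio with
#' delta-method error propagation, plus both hydrogen-exchange
#' interpretations of the ratio.
#'
#' @param chd_rates,c14_rates Rate-estimate tibbles from the two methods.
#'
#' @return Tibble with columns `incubation_id`, `ratio`, `se`,
#'   `n_exchange_activation`, `n_exchange_complement`.
#' @export
tracer_ratio_table <- function(chd_rates, c14_rates) {
  ids <- intersect(unique(chd_rates$incubation_id),
                   unique(c14_rates$incubation_id))
  rows <- lapply(ids, function(id) {
    ch <- chd_rates[chd_rates$incubation_id == id, ]
    ch <- ch[nrow(ch), ]
    rc <- c14_rates[c14_rates$incubation_id == id, ]
    rc <- rc[which.min(abs(rc$t_end_h - ch$t_end_h)), ]
    if (rc$rate_nmol_cm3_d == 0) return(NULL)
    tr <- tracer_ratio(ch$rate_nmol_cm3_d, rc$rate_nmol_cm3_d,
                       se_chd = ch$se, se_14c = rc$se)
    na <- suppressWarnings(
      exchangeable_hydrogens(tr$ratio, "activation_stoichiometric"))
    nc <- suppressWarnings(
      exchangeable_hydrogens(tr$ratio, "full_oxidation_complement"))
    tibble::tibble(incubation_id = id, ratio = tr$ratio, se = tr$se,
                   n_exchange_activation = na$n_exchange,
                   n_exchange_complement = nc$n_exchange)
  })
  dplyr::bind_rows(rows)
}

#' Write a simulated experiment as pipeline input files
#'
#' Materialises a [simulate_experiment()] bundle as the CSV families the
#' pipeline reads — injections, standards, incubation metadata and
#' radiocarbon measurements — plus a `truth.csv` sidecar for testing.
#'
#' @param exper A `synthetic_experiment`.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_simulated_inputs <- function(exper, dir) {
  stopifnot(inherits(exper, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(exper$run$injections, file.path(dir, "injections.csv"))
  readr::write_csv(
    tibble::tibble(standard_id = exper$run$standards$standard_id,
                   known_delta_d_permil = exper$run$standards$known_delta_d),
    file.path(dir, "standards.csv"))
  sp <- exper$config$incubation
  ks <- exper$killed_spec
  readr::write_csv(tibble::tibble(
    incubation_id = c(sp$incubation_id, ks$incubation_id),
    water_volume_l = c(sp$water_volume_l, ks$water_volume_l),
    inoculum_volume_cm3 = c(sp$inoculum_volume_cm3, ks$inoculum_volume_cm3),
    f_ch3d = c(sp$f_ch3d, ks$f_ch3d),
    is_killed_control = c(sp$is_killed_control, ks$is_killed_control),
    replicate_group = c(sp$replicate_group, ks$replicate_group)
  ), file.path(dir, "incubations.csv"))
  readr::write_csv(dplyr::bind_rows(exper$radiocarbon,
                                    exper$killed_radiocarbon),
                   file.path(dir, "radiocarbon.csv"))
  readr::write_csv(exper$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
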
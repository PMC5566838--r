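#' Assemble a liquid water isotope analyzer (LWIA) run
#'
#' An analysis run is the ordered sequence of individual injections produced
#' by a cavity-spectroscopy water isotope analyzer, with samples and
#' calibration standards interleaved, plus the table of standards of known
#' isotopic composition measured alongside the samples.
#'
#' @param injections Tibble with one row per injection and columns
#'   `sample_id` (analyte identifier; standards appear under their
#'   `standard_id`), `round` (analysis round, >= 1), `injection` (position
#'   within the round, >= 1), `raw_delta_d` (instrument-scale delta-D,
#'   permil), `position` (strictly increasing global position in the run),
#'   and optionally the instrument diagnostics `temp_change_rate`
#'   (internal temperature drift, degrees C per hour) and `pressure_rising`
#'   (logical; measurement-cell pressure rising during the analysis).
#' @param standards Tibble with columns `standard_id` and `known_delta_d`
#'   (permil VSMOW). At least two distinct standards are required for
#'   two-point calibration.
#'
#' @return An object of class `analysis_run`: a list with elements
#'   `injections` and `standards`.
#' @export
#' @examples
#' inj <- tibble::tibble(
#'   sample_id = "S1", round = 1, injection = 1:10,
#'   raw_delta_d = rnorm(10, -100, 0.5), position = 1:10
#' )
#' std <- tibble::tibble(
#'   standard_id = c("deep_blue", "cit"),
#'   known_delta_d = c(0.5, -73.4)
#' )
#' analysis_run(inj, std)
analysis_run <- function(injections, standards) {
  injections <- tibble::as_tibble(injections)
  standards <- tibble::as_tibble(standards)
  required <- c("sample_id", "round", "injection", "raw_delta_d", "position")
  missing_cols <- setdiff(required, names(injections))
  if (length(missing_cols) > 0) {
    stop("injection table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(c("standard_id", "known_delta_d") %in% names(standards))) {
    stop("standards table needs columns standard_id and known_delta_d",
         call. = FALSE)
  }
  if (!all(is.finite(standards$known_delta_d))) {
    stop("standard known_delta_d values must be finite", call. = FALSE)
  }
  if (anyDuplicated(standards$standard_id)) {
    stop("duplicated standard_id in standards table", call. = FALSE)
  }
  injections <- dplyr::arrange(injections, .data$position)
  if (any(diff(injections$position) <= 0)) {
    stop("global injection positions must be strictly increasing",
         call. = FALSE)
  }
  if (!"temp_change_rate" %in% names(injections)) {
    warning("no temp_change_rate diagnostic in injection table; ",
            "treating all injections as passing the temperature check",
            call. = FALSE)
    injections$temp_change_rate <- 0
  }
  if (!"pressure_rising" %in% names(injections)) {
    warning("no pressure_rising diagnostic in injection table; ",
            "treating all injections as passing the pressure check",
            call. = FALSE)
    injections$pressure_rising <- FALSE
  }
  structure(list(injections = injections, standards = standards),
            class = "analysis_run")
}

#' @export
print.analysis_run <- function(x, ...) {
  cat("<analysis_run> ", nrow(x$injections), " injections, ",
      dplyr::n_distinct(x$injections$sample_id), " analytes, ",
      nrow(x$standards), " standards\n", sep = "")
  invisible(x)
}

#' Quality-filter raw injections
#'
#' Applies the two LWIA quality rules: within each (analyte, round) only the
#' final `keep_last` injections are retained, discarding early injections
#' affected by memory carry-over from the previous analyte; any injection
#' whose internal temperature changed faster than `temp_limit` (degrees C
#' per hour) or whose measurement-cell pressure was rising is then excluded.
#' Rounds shorter than `keep_last` keep all their injections (the rule is
#' positional, not proportional).
#'
#' @param run An [analysis_run()].
#' @param keep_last Number of final injections per round to retain
#'   (default 5, out of the usual 10).
#' @param temp_limit Exclusion threshold on `temp_change_rate`
#'   (default 0.3 degrees C per hour).
#'
#' @return Tibble of retained injections (original order preserved), with an
#'   `excluded` attribute tabulating every excluded injection and the rule
#'   that triggered its exclusion.
#' @export
qc_filter <- function(run, keep_last = 5,
                      temp_limit = TEMP_DRIFT_LIMIT_C_PER_H) {
  stopifnot(inherits(run, "analysis_run"), keep_last >= 1)
  inj <- run$injections
  if (nrow(inj) == 0) stop("analysis run has no injections", call. = FALSE)

  inj <- dplyr::group_by(inj, .data$sample_id, .data$round)
  inj <- dplyr::mutate(inj, .from_end = dplyr::n() - dplyr::row_number())
  inj <- dplyr::ungroup(inj)

  early <- inj$.from_end >= keep_last
  temp <- !early & !is.na(inj$temp_change_rate) &
    inj$temp_change_rate > temp_limit
  pres <- !early & !temp & !is.na(inj$pressure_rising) & inj$pressure_rising

  reason <- rep(NA_character_, nrow(inj))
  reason[early] <- "memory_window"
  reason[temp] <- "temperature_drift"
  reason[pres] <- "pressure_rising"

  excluded <- inj[!is.na(reason), ]
  excluded$reason <- reason[!is.na(reason)]
  retained <- inj[is.na(reason), ]
  retained$.from_end <- NULL
  excluded$.from_end <- NULL

  lost <- setdiff(unique(inj$sample_id), unique(retained$sample_id))
  if (length(lost) > 0) {
    stop("no injections retained for analyte(s): ",
         paste(lost, collapse = ", "),
         " (all excluded by quality rules)", call. = FALSE)
  }
  attr(retained, "excluded") <- excluded
  retained
}

#' Build segment-wise two-point calibration from interleaved standards
#'
#' Instrumental drift is handled by re-deriving the calibration after every
#' `segment_size` injections: the run's global positions are partitioned
#' into consecutive spans of at most `segment_size`, and within each span
#' the retained injections of the two (or more) water standards are averaged
#' and a linear map from measured to known delta-D is fitted. With exactly
#' two standards this is the classic two-point calibration; additional
#' standards enter an ordinary least-squares line.
#'
#' @inheritParams qc_filter
#' @param segment_size Number of injections per calibration segment
#'   (default 40).
#'
#' @return Tibble with one row per segment: `segment`, `start_position`,
#'   `end_position` (half-open span `[start, end)` of global positions),
#'   `slope` and `intercept` (permil).
#' @export
build_calibration_segments <- function(run, segment_size = 40,
                                       keep_last = 5,
                                       temp_limit = TEMP_DRIFT_LIMIT_C_PER_H) {
  stopifnot(inherits(run, "analysis_run"), segment_size >= 2)
  retained <- qc_filter(run, keep_last = keep_last, temp_limit = temp_limit)
  std_ids <- run$standards$standard_id
  max_pos <- max(run$injections$position)
  starts <- seq(1L, max_pos, by = segment_size)
  ends <- pmin(starts + segment_size, max_pos + 1L)

  std_inj <- retained[retained$sample_id %in% std_ids, ]
  segs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    in_seg <- std_inj[std_inj$position >= starts[k] &
                        std_inj$position < ends[k], ]
    means <- tapply(in_seg$raw_delta_d, in_seg$sample_id, mean)
    have <- names(means)
    absent <- setdiff(std_ids, have)
    if (length(absent) > 0) {
      stop(sprintf(
        "calibration segment %d (positions %d-%d) is missing standard(s): %s",
        k, starts[k], ends[k] - 1L, paste(absent, collapse = ", ")),
        call. = FALSE)
    }
    known <- run$standards$known_delta_d[match(have, std_ids)]
    measured <- as.numeric(means)
    if (length(measured) == 2) {
      slope <- diff(known) / diff(measured)
      intercept <- known[1] - slope * measured[1]
    } else {
      fit <- coef(lm(known ~ measured))
      intercept <- unname(fit[1])
      slope <- unname(fit[2])
    }
    if (!is.finite(slope) || slope == 0) {
      stop(sprintf("degenerate calibration in segment %d (slope %g)",
                   k, slope), call. = FALSE)
    }
    segs[[k]] <- tibble::tibble(
      segment = k, start_position = starts[k], end_position = ends[k],
      slope = slope, intercept = intercept
    )
  }
  dplyr::bind_rows(segs)
}

#' Apply a segment's two-point calibration to raw delta-D values
#'
#' Linear normalisation to the VSMOW scale: `intercept + slope * raw`. The
#' map reproduces each standard's segment-mean measured value exactly when
#' two standards define the segment.
#'
#' @param raw Numeric vector of instrument-scale delta-D values (permil).
#' @param segment A single row of the tibble returned by
#'   [build_calibration_segments()] (or any list with `slope` and
#'   `intercept`).
#'
#' @return Calibrated delta-D (permil VSMOW).
#' @export
calibrate_delta <- function(raw, segment) {
  stopifnot(is.numeric(raw))
  segment$intercept + segment$slope * raw
}

#' Calibrate all retained sample injections of a run
#'
#' Runs [qc_filter()] and [build_calibration_segments()], assigns each
#' retained non-standard injection to the calibration segment covering its
#' global position, and returns the retained injections with calibrated
#' `delta_vsmow` (permil) and absolute `d_h` ratio columns.
#'
#' @inheritParams build_calibration_segments
#' @param r_vsmow Reference VSMOW D/H ratio used for the delta-to-ratio
#'   conversion (default 155.76e-6).
#'
#' @return Tibble of retained, calibrated sample injections; the calibration
#'   segment table is attached as attribute `segments` and the QC exclusion
#'   log as attribute `excluded`.
#' @export
calibrate_run <- function(run, segment_size = 40, keep_last = 5,
                          temp_limit = TEMP_DRIFT_LIMIT_C_PER_H,
                          r_vsmow = R_VSMOW) {
  retained <- qc_filter(run, keep_last = keep_last, temp_limit = temp_limit)
  segments <- build_calibration_segments(run, segment_size = segment_size,
                                         keep_last = keep_last,
                                         temp_limit = temp_limit)
  samples <- retained[!retained$sample_id %in% run$standards$standard_id, ]
  idx <- findInterval(samples$position, segments$start_position)
  samples$segment <- segments$segment[idx]
  samples$delta_vsmow <- segments$intercept[idx] +
    segments$slope[idx] * samples$raw_delta_d
  samples$d_h <- delta_to_ratio(samples$delta_vsmow, r_vsmow = r_vsmow)
  attr(samples, "segments") <- segments
  attr(samples, "excluded") <- attr(retained, "excluded")
  samples
}

#' Convert between delta-D and absolute D/H ratio
#'
#' `delta_to_ratio()` maps a permil delta-D on the VSMOW scale to the
#' absolute (dimensionless) D/H ratio, `r_vsmow * (1 + delta/1000)`;
#' `ratio_to_delta()` is its inverse. Deltas at or below -1000 permil would
#' imply a nonpositive ratio and are rejected.
#'
#' @param delta Delta-D in permil VSMOW (must exceed -1000).
#' @param ratio Dimensionless D/H ratio (must be positive).
#' @param r_vsmow Reference VSMOW D/H ratio (default 155.76e-6).
#'
#' @return Numeric vector: D/H ratio, or delta-D in permil.
#' @export
#' @examples
#' delta_to_ratio(0)     # the VSMOW reference ratio
#' delta_to_ratio(-73.4) # the depleted working standard
#' ratio_to_delta(delta_to_ratio(0.5))
delta_to_ratio <- function(delta, r_vsmow = R_VSMOW) {
  if (any(delta <= -1000)) {
    stop("delta-D <= -1000 permil is nonphysical (D/H ratio would be <= 0)",
         call. = FALSE)
  }
  r_vsmow * (1 + delta / 1000)
}

#' @rdname delta_to_ratio
#' @export
ratio_to_delta <- function(ratio, r_vsmow = R_VSMOW) {
  if (any(ratio <= 0)) stop("D/H ratio must be positive", call. = FALSE)
  (ratio / r_vsmow - 1) * 1000
}

#' Summarise calibrated injections per analyte
#'
#' Aggregates the retained, calibrated injections of each analyte into a
#' mean delta-D, mean D/H ratio and standard error of the D/H ratio
#' (n-1 variance, SE = sd/sqrt(n)). Analytes measured by a single retained
#' injection get SE 0 by convention, with a warning.
#'
#' @param calibrated Tibble from [calibrate_run()] (columns `sample_id`,
#'   `delta_vsmow`, `d_h`).
#'
#' @return Tibble with columns `sample_id`, `mean_delta_d`, `mean_d_h`,
#'   `se_d_h`, `n_used`.
#' @export
summarize_samples <- function(calibrated) {
  stopifnot(all(c("sample_id", "delta_vsmow", "d_h") %in% names(calibrated)))
  if (nrow(calibrated) == 0) stop("no calibrated injections", call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(calibrated, .data$sample_id),
    mean_delta_d = mean(.data$delta_vsmow),
    mean_d_h = mean(.data$d_h),
    se_d_h = if (dplyr::n() > 1) sd(.data$d_h) / sqrt(dplyr::n()) else 0,
    n_used = dplyr::n(),
    .groups = "drop"
  )
  if (any(out$n_used == 1)) {
    warning("analyte(s) with a single retained injection: SE set to 0 for ",
            paste(out$sample_id[out$n_used == 1], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Full LWIA processing: QC, calibration, per-analyte summary
#'
#' Convenience wrapper chaining [qc_filter()],
#' [build_calibration_segments()], [calibrate_run()] and
#' [summarize_samples()].
#'
#' @inheritParams calibrate_run
#'
#' @return List with elements `measurements` (per-analyte summary tibble),
#'   `calibrated` (per-injection tibble), `segments`, and `excluded`
#'   (QC exclusion log).
#' @export
process_lwia_run <- function(run, segment_size = 40, keep_last = 5,
                             temp_limit = TEMP_DRIFT_LIMIT_C_PER_H,
                             r_vsmow = R_VSMOW) {
  calibrated <- calibrate_run(run, segment_size = segment_size,
                              keep_last = keep_last, temp_limit = temp_limit,
                              r_vsmow = r_vsmow)
  list(
    measurements = summarize_samples(calibrated),
    calibrated = calibrated,
    segments = attr(calibrated, "segments"),
    excluded = attr(calibrated, "excluded")
  )
}
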
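#' Read and write beat-series files
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{two_column_csv}{comma-separated columns `t_s`, `rr_ms` and an
#'     optional `valid` column (0/1 or TRUE/FALSE), with a header;}
#'   \item{rr_per_line}{one RR interval in ms per line — the lowest common
#'     denominator of HRV tooling. Onset times are reconstructed by
#'     cumulative summation of `rr / 1000` starting at 0, so the first beat
#'     sits at time 0 and each interval starts at its beat's onset.}
#' }
#' `"auto"` detects the dialect from the first line.
#'
#' @param path File path.
#' @param dialect `"auto"`, `"two_column_csv"` or `"rr_per_line"`.
#'
#' @return A [beat_series()].
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("800", "810", "790"), f)
#' read_beats(f)
#' @export
read_beats <- function(path, dialect = c("auto", "two_column_csv", "rr_per_line")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) rlang::abort(paste0("empty file: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl(",", lines[1])) "two_column_csv" else "rr_per_line"
  }
  if (dialect == "rr_per_line") {
    rr <- suppressWarnings(as.numeric(trimws(lines)))
    if (anyNA(rr)) {
      rlang::abort(sprintf("non-numeric RR value on line %d of %s",
                           which(is.na(rr))[1], path))
    }
    if (any(rr <= 0)) {
      rlang::abort(sprintf("non-positive RR value on line %d of %s",
                           which(rr <= 0)[1], path))
    }
    times <- c(0, cumsum(rr[-length(rr)]) / 1000)
    return(beat_series(times, rr, meta = list(source = path)))
  }
  # two-column CSV
  has_header <- !grepl("^[0-9.+-]", lines[1])
  body <- if (has_header) lines[-1] else lines
  offset <- if (has_header) 1L else 0L
  parts <- strsplit(body, ",")
  ncol <- lengths(parts)
  if (any(ncol < 2)) {
    rlang::abort(sprintf("malformed row on line %d of %s",
                         which(ncol < 2)[1] + offset, path))
  }
  t_s <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  rr <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(t_s) || anyNA(rr)) {
    rlang::abort(sprintf("non-numeric value on line %d of %s",
                         which(is.na(t_s) | is.na(rr))[1] + offset, path))
  }
  if (any(rr <= 0)) {
    rlang::abort(sprintf("non-positive RR value on line %d of %s",
                         which(rr <= 0)[1] + offset, path))
  }
  valid <- if (all(ncol >= 3)) {
    v <- trimws(vapply(parts, `[`, "", 3))
    v %in% c("1", "TRUE", "true", "T")
  } else TRUE
  beat_series(t_s, rr, valid, meta = list(source = path))
}

#' @rdname read_beats
#' @param b A [beat_series()].
#' @param include_valid Write the validity flag column (CSV dialect only).
#' @export
write_beats <- function(b, path, dialect = c("two_column_csv", "rr_per_line"),
                        include_valid = FALSE) {
  b <- as_beat_series(b)
  dialect <- match.arg(dialect)
  if (dialect == "rr_per_line") {
    writeLines(sprintf("%.3f", b$rr_ms), path)
  } else if (include_valid) {
    writeLines(c("t_s,rr_ms,valid",
                 sprintf("%.3f,%.3f,%d", b$time_s, b$rr_ms, as.integer(b$valid))),
               path)
  } else {
    writeLines(c("t_s,rr_ms", sprintf("%.3f,%.3f", b$time_s, b$rr_ms)), path)
  }
  invisible(path)
}

#' Protocol phase windows
#'
#' Half-open `[start, end)` windows, in seconds from record start, for the
#' baseline / intervention / recovery protocol (defaults 30 min / 15 min /
#' 30 min).
#'
#' @param baseline_s,intervention_s,recovery_s Phase durations in seconds.
#' @return A tibble with columns `phase`, `start_s`, `end_s`.
#' @export
protocol_phases <- function(baseline_s = 1800, intervention_s = 900,
                            recovery_s = 1800) {
  tibble::tibble(
    phase = c("baseline", "intervention", "recovery"),
    start_s = c(0, baseline_s, baseline_s + intervention_s),
    end_s = c(baseline_s, baseline_s + intervention_s,
              baseline_s + intervention_s + recovery_s))
}

#' Split a record into protocol phases
#'
#' Assigns beats to phases by onset time using half-open `[start, end)`
#' windows, so a beat exactly on a boundary belongs to the later phase.
#' A window whose end overshoots the record by more than one median beat
#' interval is an error naming the phase; a window containing no beats is
#' flagged and excluded.
#'
#' @param b A [beat_series()].
#' @param phases A phase table as from [protocol_phases()].
#'
#' @return A tibble with columns `phase`, `start_s`, `end_s`, `n_beats` and
#'   a `beats` list-column of beat-series tibbles (empty phases dropped,
#'   recorded in attribute `"empty_phases"`).
#' @export
phase_split <- function(b, phases = protocol_phases()) {
  b <- as_beat_series(b)
  last <- b$time_s[nrow(b)]
  tol <- stats::median(b$rr_ms) / 1000
  over <- phases$end_s > last + tol | phases$start_s > last
  if (any(over)) {
    rlang::abort(sprintf("phase window '%s' extends beyond the record (%.1f s)",
                         phases$phase[which(over)[1]], last))
  }
  out <- phases |>
    dplyr::mutate(
      beats = purrr::map2(.data$start_s, .data$end_s, function(s, e) {
        dplyr::filter(tibble::as_tibble(b), .data$time_s >= s, .data$time_s < e)
      }),
      n_beats = purrr::map_int(.data$beats, nrow))
  empty <- out$phase[out$n_beats == 0]
  if (length(empty) > 0) {
    rlang::warn(paste0("empty phase(s) excluded: ", paste(empty, collapse = ", ")))
  }
  structure(dplyr::filter(out, .data$n_beats > 0), empty_phases = empty)
}

#' Protocol record constructor
#'
#' Bundles a subject's beat series with its protocol metadata for batch
#' analysis.
#'
#' @param beats A [beat_series()].
#' @param subject_id Opaque subject label.
#' @param group Intervention group label (e.g. `"CTR"`, `"OA-D"`, `"taVNS"`).
#' @param day Study day (1-3 in the canonical protocol).
#' @param phases Phase table, see [protocol_phases()].
#' @return A list of class `protocol_record`.
#' @export
protocol_record <- function(beats, subject_id, group = "CTR", day = 1,
                            phases = protocol_phases()) {
  structure(list(beats = as_beat_series(beats), subject_id = subject_id,
                 group = group, day = day, phases = phases),
            class = "protocol_record")
}

#' Batch per-phase HRV table
#'
#' Runs the full pipeline on every record: splits each record into its
#' protocol phases, computes mean heart rate, the time-domain summary and
#' the spectral summary per phase, and appends one recovery-minus-baseline
#' delta row per record. Records that fail are reported with a warning and
#' skipped; the rest are still processed. Rows are emitted in input order
#' (permuting the input permutes rows only).
#'
#' @param records A list of [protocol_record()] objects.
#' @param ... Passed to [hrv_time()] and [hrv_spectral()] (shared arguments:
#'   `rel_threshold`, `window`, `clean`).
#'
#' @return A long-format tibble, one row per record x phase plus one
#'   `recovery_minus_baseline` row per record, with columns `subject_id`,
#'   `day`, `group`, `phase`, `mean_hr_bpm`, `sdnn_ms`, `rmssd_ms`,
#'   `lf_hp_ms2`, `hf_hp_ms2`, `lf_hr_bpm2`, `hf_hr_bpm2`, `ratio_hp`,
#'   `ratio_hr`, `ratio_cross`, `n_segments_time`, `n_segments_spec`,
#'   `pct_interpolated`.
#' @export
batch_table <- function(records, ...) {
  stopifnot(length(records) >= 1)
  one_record <- function(rec) {
    ph <- phase_split(rec$beats, rec$phases)
    rows <- purrr::map2_dfr(ph$phase, ph$beats, function(phase, beats) {
      tm <- hrv_time(beats, ...)
      sp <- hrv_spectral(beats, ...)
      tibble::tibble(
        subject_id = rec$subject_id, day = rec$day, group = rec$group,
        phase = phase,
        mean_hr_bpm = mean(hp_to_hr(beats$rr_ms)),
        sdnn_ms = tm$sdnn_ms, rmssd_ms = tm$rmssd_ms,
        lf_hp_ms2 = sp$lf_hp, hf_hp_ms2 = sp$hf_hp,
        lf_hr_bpm2 = sp$lf_hr, hf_hr_bpm2 = sp$hf_hr,
        ratio_hp = sp$ratio_hp, ratio_hr = sp$ratio_hr,
        ratio_cross = sp$ratio_cross,
        n_segments_time = tm$n_segments, n_segments_spec = sp$n_segments,
        pct_interpolated = tm$pct_interpolated)
    })
    metrics <- c("mean_hr_bpm", "sdnn_ms", "rmssd_ms", "lf_hp_ms2",
                 "hf_hp_ms2", "lf_hr_bpm2", "hf_hr_bpm2", "ratio_hp",
                 "ratio_hr", "ratio_cross")
    if (all(c("baseline", "recovery") %in% rows$phase)) {
      delta <- rows[rows$phase == "recovery", metrics] -
        rows[rows$phase == "baseline", metrics]
      rows <- dplyr::bind_rows(rows, dplyr::bind_cols(
        tibble::tibble(subject_id = rec$subject_id, day = rec$day,
                       group = rec$group, phase = "recovery_minus_baseline"),
        delta))
    }
    rows
  }
  purrr::map_dfr(records, function(rec) {
    tryCatch(one_record(rec), error = function(e) {
      rlang::warn(sprintf("record '%s' failed: %s; skipped",
                          rec$subject_id, conditionMessage(e)))
      tibble::tibble()
    })
  })
}

#' Read a configuration file of model and pipeline settings
#'
#' YAML (or JSON, a YAML subset) key-value configuration. Recognized model
#' keys: `tsys_ms`, `th_mV`, `MP_mV`, `m_mV_per_ms`, `dMP_mV`,
#' `dm_mV_per_ms`. Any further keys are returned as-is so callers can carry
#' pipeline settings (band edges, segment lengths, thresholds, seeds) in
#' the same file.
#'
#' @param path Path to the YAML/JSON file.
#' @return A list with `params` (a [sinus_params()] tibble, if model keys
#'   are present) and `config` (the raw key-value list).
#' @export
read_hrv_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  keys <- c(tsys_ms = "tsys", th_mV = "th", MP_mV = "mp",
            m_mV_per_ms = "m", dMP_mV = "dmp", dm_mV_per_ms = "dm")
  present <- intersect(names(keys), names(cfg))
  params <- NULL
  if (length(present) > 0) {
    args <- stats::setNames(cfg[present], keys[present])
    params <- do.call(sinus_params, args)
  }
  list(params = params, config = cfg)
}
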
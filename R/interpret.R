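#' Build a table of metric direction changes
#'
#' Helper for assembling the input to [infer_autonomic()]: one row per HRV
#' metric with its direction of change between two conditions (e.g.,
#' recovery vs. baseline) and whether that change is statistically
#' significant. Significance is judged upstream (the engine makes no
#' statistical decisions); a non-significant or `"unchanged"` direction
#' contributes no evidence.
#'
#' @param ... Named directions, e.g. `RMSSD = "up"`, `LF_HR = "down"`.
#'   Metrics: SDNN, RMSSD, LF_HP, HF_HP, LF_HR, HF_HR, RATIO_CROSS.
#' @param significant Logical, recycled across metrics (default TRUE).
#'
#' @return A tibble with columns `metric`, `direction`, `significant`.
#' @examples
#' metric_deltas(RMSSD = "up", HF_HP = "up", RATIO_CROSS = "down")
#' @export
metric_deltas <- function(..., significant = TRUE) {
  d <- list(...)
  tibble::tibble(metric = names(d),
                 direction = unlist(d, use.names = FALSE),
                 significant = rep_len(significant, length(d)))
}

hrv_metrics <- function() {
  c("SDNN", "RMSSD", "LF_HP", "HF_HP", "LF_HR", "HF_HR", "RATIO_CROSS")
}

#' Infer autonomic tone changes from HRV metric changes
#'
#' Rule engine mapping directional changes in HRV metrics — each computed
#' from the series representation in which it monotonically tracks its
#' autonomic branch — to conclusions about sympathetic (SNA) and
#' parasympathetic (PNA) tone. The rules, applied in order:
#'
#' \describe{
#'   \item{R1}{HF_HP up (or RMSSD up) implies PNA increase; HF_HP (or RMSSD)
#'     down implies PNA decrease. HF variability of the heart-period series
#'     is the monotone parasympathetic marker.}
#'   \item{R2}{LF_HR up implies SNA increase; down implies SNA decrease.
#'     LF variability of the heart-rate series is the monotone sympathetic
#'     marker.}
#'   \item{R3}{LF_HP up while HF_HP and RMSSD are unchanged implies SNA
#'     decrease with PNA unchanged: LF heart-period variability rises when
#'     sympathetic tone falls, and the silent parasympathetic markers pin
#'     PNA.}
#'   \item{R4}{SDNN up with RMSSD unchanged: as R3, at lower confidence
#'     (SDNN is an overall-variability surrogate for LF_HP).}
#'   \item{R5}{RATIO_CROSS (LF_HR / HF_HP) down corroborates a balance shift
#'     toward PNA; it is never the sole basis for a conclusion.}
#' }
#'
#' Opposing firings on the same branch yield `"indeterminate"` for that
#' branch, with both firings retained in the rationale. HF_HP and HF_HR
#' moving in the same direction contradicts the model (they should move
#' oppositely), so PNA is flagged indeterminate. Metrics with direction
#' `"unchanged"` or `significant = FALSE` contribute no evidence.
#'
#' @param deltas A data frame with columns `metric`, `direction`
#'   (`"up"`, `"down"`, `"unchanged"`) and optionally `significant`
#'   (default TRUE); at most one row per metric. See [metric_deltas()].
#'
#' @return An object of class `autonomic_inference`: a list with `sna` and
#'   `pna` (each `"increase"`, `"decrease"`, `"no_change"` or
#'   `"indeterminate"`) and a `rationale` tibble (`rule`, `metric`, `axis`,
#'   `implication`, `note`). [tidy()] returns the rationale.
#' @examples
#' # vagal-stimulation signature
#' infer_autonomic(metric_deltas(RMSSD = "up", HF_HP = "up",
#'                               LF_HP = "up", RATIO_CROSS = "down"))
#' @export
infer_autonomic <- function(deltas) {
  deltas <- tibble::as_tibble(deltas)
  if (!all(c("metric", "direction") %in% names(deltas))) {
    rlang::abort("deltas needs columns metric and direction")
  }
  if (anyDuplicated(deltas$metric)) {
    rlang::abort("duplicate metric entries in deltas")
  }
  bad <- setdiff(deltas$metric, hrv_metrics())
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown metric(s): ", paste(bad, collapse = ", ")))
  }
  if (is.null(deltas$significant)) deltas$significant <- TRUE

  dir_of <- function(metric) {
    row <- deltas[deltas$metric == metric, ]
    if (nrow(row) == 0) return(NA_character_)
    if (!isTRUE(row$significant) || row$direction == "unchanged") {
      return("unchanged")
    }
    row$direction
  }
  flat <- function(d) is.na(d) || d == "unchanged"  # absent or no evidence

  fires <- list()
  add <- function(rule, metric, axis, implication, note = "") {
    fires[[length(fires) + 1]] <<- tibble::tibble(
      rule = rule, metric = metric, axis = axis,
      implication = implication, note = note)
  }

  # R1: parasympathetic markers (HF of heart period; RMSSD as its
  # time-domain proxy)
  for (mk in c("HF_HP", "RMSSD")) {
    d <- dir_of(mk)
    if (!flat(d)) {
      add("R1", mk, "pna", if (d == "up") "increase" else "decrease")
    }
  }
  # R2: sympathetic marker (LF of heart rate)
  d <- dir_of("LF_HR")
  if (!flat(d)) {
    add("R2", "LF_HR", "sna", if (d == "up") "increase" else "decrease")
  }
  # R3: LF of heart period rises with PNA markers silent
  if (identical(dir_of("LF_HP"), "up") &&
      flat(dir_of("HF_HP")) && flat(dir_of("RMSSD"))) {
    add("R3", "LF_HP", "sna", "decrease",
        "LF_HP up with parasympathetic markers unchanged")
    add("R3", "LF_HP", "pna", "no_change",
        "parasympathetic markers unchanged")
  }
  # R4: SDNN as overall-variability surrogate, lower confidence
  if (identical(dir_of("SDNN"), "up") && flat(dir_of("RMSSD"))) {
    add("R4", "SDNN", "sna", "decrease",
        "SDNN up with RMSSD unchanged (lower confidence)")
  }
  # R5: cross ratio, corroborating only
  d <- dir_of("RATIO_CROSS")
  if (identical(d, "down")) {
    add("R5", "RATIO_CROSS", "balance", "toward_pna",
        "corroborating only, never sole evidence")
  } else if (identical(d, "up")) {
    add("R5", "RATIO_CROSS", "balance", "toward_sna",
        "corroborating only, never sole evidence")
  }

  rationale <- if (length(fires) > 0) dplyr::bind_rows(fires) else
    tibble::tibble(rule = character(), metric = character(),
                   axis = character(), implication = character(),
                   note = character())

  conclude <- function(axis) {
    imp <- rationale$implication[rationale$axis == axis]
    imp <- setdiff(unique(imp), "no_change")
    if (length(imp) == 0) {
      if (any(rationale$axis == axis)) "no_change" else "no_change"
    } else if (length(imp) == 1) {
      imp
    } else {
      "indeterminate"
    }
  }
  sna <- conclude("sna")
  pna <- conclude("pna")

  # model-consistency check: HF_HP and HF_HR should move oppositely
  d_hp <- dir_of("HF_HP"); d_hr <- dir_of("HF_HR")
  if (!flat(d_hp) && !flat(d_hr) && identical(d_hp, d_hr)) {
    pna <- "indeterminate"
    rationale <- dplyr::bind_rows(rationale, tibble::tibble(
      rule = "consistency", metric = "HF_HP+HF_HR", axis = "pna",
      implication = "indeterminate",
      note = "HF_HP and HF_HR moved in the same direction; the model predicts opposite signs"))
  }

  structure(list(sna = sna, pna = pna, rationale = rationale),
            class = "autonomic_inference")
}

#' @export
print.autonomic_inference <- function(x, ...) {
  cat(sprintf("Autonomic inference\n  sympathetic tone:     %s\n  parasympathetic tone: %s\n",
              x$sna, x$pna))
  if (nrow(x$rationale) > 0) {
    cat("  rationale:\n")
    apply(x$rationale, 1, function(r) {
      cat(sprintf("    [%s] %s -> %s %s%s\n", r["rule"], r["metric"],
                  r["axis"], r["implication"],
                  if (nzchar(r["note"])) paste0(" (", r["note"], ")") else ""))
    })
  }
  invisible(x)
}

#' @export
tidy.autonomic_inference <- function(x, ...) x$rationale

#' @export
glance.autonomic_inference <- function(x, ...) {
  tibble::tibble(sna = x$sna, pna = x$pna, n_rules_fired = nrow(x$rationale))
}

#' Compare two analyzed conditions and classify the change
#'
#' Closes the loop between the pipeline and the rule engine: given time- and
#' frequency-domain summaries of two conditions of the same subject (e.g.,
#' baseline and recovery), compute the direction of change of each metric
#' (relative change beyond `threshold` counts as a move) and feed the
#' deltas to [infer_autonomic()].
#'
#' @param time_a,time_b `hrv_time` objects for conditions A (reference) and B.
#' @param spec_a,spec_b `hrv_spectral` objects for conditions A and B.
#' @param threshold Relative change below which a metric counts as
#'   unchanged (default 0.05).
#' @return An `autonomic_inference`.
#' @export
classify_change <- function(time_a, time_b, spec_a, spec_b, threshold = 0.05) {
  vals <- function(tm, sp) c(
    SDNN = tm$sdnn_ms, RMSSD = tm$rmssd_ms,
    LF_HP = sp$lf_hp, HF_HP = sp$hf_hp,
    LF_HR = sp$lf_hr, HF_HR = sp$hf_hr,
    RATIO_CROSS = sp$ratio_cross)
  a <- vals(time_a, spec_a)
  b <- vals(time_b, spec_b)
  rel <- (b - a) / ifelse(a == 0, 1, abs(a))
  direction <- dplyr::case_when(
    is.na(rel) ~ "unchanged",
    rel > threshold ~ "up",
    rel < -threshold ~ "down",
    TRUE ~ "unchanged")
  infer_autonomic(tibble::tibble(metric = names(a), direction = direction,
                                 significant = TRUE))
}
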
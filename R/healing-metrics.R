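#' Du Bois body surface area
#'
#' Classical anthropometric estimate of whole-body skin area:
#' `BSA (m^2) = 0.007184 * W^0.425 * H^0.725` with weight in kilograms and
#' height in centimetres. Used to normalise 3D-measured wound areas to
#' TBSA-scale percentages.
#'
#' @param weight_kg Body weight (kg), `> 0`. Vectorised.
#' @param height_cm Body height (cm), `> 0`. Vectorised.
#' @return BSA in m^2.
#' @examples
#' du_bois_bsa(100, 183)  # ~2.22 m^2
#' @export
du_bois_bsa <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    bp_abort("weight and height must be positive.", "bp_error_domain")
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Absolute wound area reduction
#'
#' `delta A = A0 - At` in cm^2. Negative values (wound growth between scans)
#' are allowed and propagate with sign — clamping would hide non-monotone
#' series, which do occur clinically.
#'
#' @param a0 Baseline wound area (cm^2), `>= 0`.
#' @param at Wound area at time t (cm^2), `>= 0`.
#' @return `a0 - at` (cm^2). Vectorised.
#' @export
absolute_reduction <- function(a0, at) {
  if (any(a0 < 0) || any(at < 0)) {
    bp_abort("areas must be non-negative.", "bp_error_domain")
  }
  a0 - at
}

#' Percentage wound area reduction
#'
#' `(A0 - At) / A0 * 100`: the primary relative healing metric. Scale
#' invariant in the areas; may be negative if the wound grew; never exceeds
#' 100.
#'
#' @inheritParams absolute_reduction
#' @return Percent reduction. Vectorised.
#' @export
percent_reduction <- function(a0, at) {
  if (any(a0 <= 0)) {
    bp_abort("baseline area must be positive for a percent reduction.",
             "bp_error_domain")
  }
  if (any(at < 0)) bp_abort("areas must be non-negative.", "bp_error_domain")
  (a0 - at) / a0 * 100
}

#' Wound area as a TBSA-scale percentage
#'
#' Expresses a wound area (or an area reduction) as a percentage of the
#' patient's whole-body surface: `area_cm2 / (bsa_m2 * 1e4) * 100`.
#'
#' @param area_cm2 Wound area or area change (cm^2).
#' @param bsa_m2 Body surface area (m^2), `> 0`; see [du_bois_bsa()].
#' @return TBSA percentage. Vectorised.
#' @export
tbsa_percent <- function(area_cm2, bsa_m2) {
  if (any(bsa_m2 <= 0)) {
    bp_abort("BSA must be positive.", "bp_error_domain")
  }
  area_cm2 / (bsa_m2 * 1e4) * 100
}

#' Time-ordered scan series for one wound
#'
#' A wound series is the unit of longitudinal analysis: the area
#' observations of one wound (one patient, one anatomical location) across
#' its scans, ordered by study day. Days follow the convention that the
#' baseline scan is day 1.
#'
#' @param patient_id Patient identifier.
#' @param location Wound location (e.g. `"Torso"`, `"RUL"`, `"LUL"`,
#'   `"RLL"`, `"LLL"`).
#' @param day Integer study days, all `>= 1`, no duplicates.
#' @param area_cm2 Measured wound areas (cm^2), `>= 0`.
#' @return An object of class `wound_series`: a list with the observation
#'   tibble plus `baseline` and `last` observation rows.
#' @export
wound_series <- function(patient_id, location, day, area_cm2) {
  day <- as.integer(day)
  if (length(day) == 0L) {
    bp_abort("a wound series needs at least one observation.",
             "bp_error_input")
  }
  if (anyNA(day) || any(day < 1L)) {
    bp_abort("study days must be integers >= 1 (baseline scan = day 1).",
             "bp_error_input")
  }
  if (anyDuplicated(day)) {
    bp_abort("duplicate study day in wound series.", "bp_error_input")
  }
  if (any(area_cm2 < 0)) {
    bp_abort("areas must be non-negative.", "bp_error_domain")
  }
  if (length(unique(patient_id)) > 1L || length(unique(location)) > 1L) {
    bp_abort("a wound series spans exactly one (patient, location).",
             "bp_error_input")
  }
  ord <- order(day)
  obs <- tibble(
    patient_id = rep(patient_id[1], length(day)),
    location = rep(location[1], length(day)),
    day = day[ord],
    area_cm2 = as.numeric(area_cm2)[ord]
  )
  structure(
    list(observations = obs,
         baseline = obs[1, ],
         last = obs[nrow(obs), ]),
    class = "wound_series"
  )
}

#' Convert an observation data frame into wound series
#'
#' `as_wound_series()` builds a single [wound_series()] from a data frame
#' holding one wound; `split_wound_series()` splits a whole observation
#' table into a named list of series, one per `(patient_id, location)`.
#'
#' @param observations Data frame with columns `patient_id`, `location`,
#'   `day`, `area_cm2`.
#' @return A `wound_series`, or a named list of them.
#' @export
as_wound_series <- function(observations) {
  check_columns(observations, c("patient_id", "location", "day", "area_cm2"))
  wound_series(observations$patient_id, observations$location,
               observations$day, observations$area_cm2)
}

#' @rdname as_wound_series
#' @export
split_wound_series <- function(observations) {
  check_columns(observations, c("patient_id", "location", "day", "area_cm2"))
  parts <- split(
    observations,
    paste(observations$patient_id, observations$location, sep = "/"))
  lapply(parts, as_wound_series)
}

check_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    bp_abort(sprintf("missing required column(s): %s.",
                     paste(missing, collapse = ", ")), "bp_error_schema")
  }
  invisible(df)
}

#' @export
print.wound_series <- function(x, ...) {
  cat(sprintf("<wound_series> %s / %s: %d scans, days %d-%d, A0 %.2f cm^2\n",
              x$baseline$patient_id, x$baseline$location,
              nrow(x$observations), x$baseline$day, x$last$day,
              x$baseline$area_cm2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.wound_series <- function(x, ...) x$observations

#' @exportS3Method generics::glance
glance.wound_series <- function(x, ...) wound_metrics(x)

#' Early-phase percentage reduction
#'
#' Percent reduction between baseline and the first follow-up scan — the
#' early post-injury interval during which epithelialisation dynamics
#' differ most across burn depths.
#'
#' @param series A [wound_series()] with at least two observations.
#' @return Percent reduction at the first follow-up.
#' @export
early_phase_reduction <- function(series) {
  stopifnot(inherits(series, "wound_series"))
  if (nrow(series$observations) < 2L) {
    bp_abort("early-phase reduction needs at least one follow-up scan.",
             "bp_error_insufficient_data")
  }
  percent_reduction(series$observations$area_cm2[1L],
                    series$observations$area_cm2[2L])
}

#' Daily healing rate
#'
#' Absolute area reduction per elapsed day,
#' `(A0 - At) / (day_t - day_baseline)` in cm^2/day, computed against the
#' follow-up scan at `at_index` (1 = first follow-up; `NULL` = the last
#' scan, giving the overall rate). The rate is a plain area change per day;
#' it carries no additional scaling, keeping the stated unit dimensionally
#' consistent.
#'
#' @param series A [wound_series()].
#' @param at_index Follow-up index (`>= 1`), or `NULL` for the last scan.
#' @return Rate in cm^2/day.
#' @export
daily_healing_rate <- function(series, at_index = NULL) {
  stopifnot(inherits(series, "wound_series"))
  obs <- series$observations
  if (nrow(obs) < 2L) {
    bp_abort("daily healing rate needs at least one follow-up scan.",
             "bp_error_insufficient_data")
  }
  i <- if (is.null(at_index)) nrow(obs) else as.integer(at_index) + 1L
  if (i < 2L || i > nrow(obs)) {
    bp_abort("at_index must address an existing follow-up scan.",
             "bp_error_input")
  }
  elapsed <- obs$day[i] - obs$day[1L]
  if (elapsed <= 0) {
    bp_abort("zero elapsed time between scans.", "bp_error_domain")
  }
  (obs$area_cm2[1L] - obs$area_cm2[i]) / elapsed
}

#' Patient-level change in TBSA percentage
#'
#' The overall reduction in burn burden between first and last scans,
#' summed over all of one patient's wounds and normalised by body surface
#' area: `sum(A0 - A_last) / (BSA * 1e4) * 100`. By linearity this equals
#' the sum of per-wound [tbsa_percent()] of the individual reductions.
#'
#' @param series_list A list of [wound_series()] (all wounds of one
#'   patient), or a single observation data frame for one patient.
#' @param bsa_m2 The patient's body surface area (m^2).
#' @return Delta TBSA as a percentage.
#' @export
delta_tbsa_percent <- function(series_list, bsa_m2) {
  if (is.data.frame(series_list)) {
    series_list <- split_wound_series(series_list)
  }
  if (inherits(series_list, "wound_series")) series_list <- list(series_list)
  if (length(series_list) == 0L) {
    bp_abort("no wound series supplied.", "bp_error_input")
  }
  red <- vapply(series_list, function(s) {
    s$baseline$area_cm2 - s$last$area_cm2
  }, 0)
  tbsa_percent(sum(red), bsa_m2)
}

#' Longitudinal metrics for wound series
#'
#' Bundles the area-based healing metrics for each wound: baseline and last
#' areas, absolute and percentage reduction (baseline vs last scan),
#' early-phase reduction (baseline vs first follow-up), and daily healing
#' rates over the early interval and overall. Wounds that grew get negative
#' reductions and are flagged in the `grew` column.
#'
#' Apply to a single [wound_series()], or to an observation data frame
#' (columns `patient_id`, `location`, `day`, `area_cm2`) covering any
#' number of wounds to get one row per wound.
#'
#' @param x A `wound_series` or an observation data frame.
#' @param ... Unused.
#' @return A tibble with one row per wound.
#' @examples
#' obs <- tibble::tibble(
#'   patient_id = "P01", location = "RLL",
#'   day = c(1, 10, 15), area_cm2 = c(329.19, 191.12, 98.42)
#' )
#' wound_metrics(obs)
#' @export
wound_metrics <- function(x, ...) UseMethod("wound_metrics")

#' @rdname wound_metrics
#' @export
wound_metrics.wound_series <- function(x, ...) {
  obs <- x$observations
  if (nrow(obs) < 2L) {
    bp_abort("wound metrics need at least two observations.",
             "bp_error_insufficient_data")
  }
  a0 <- x$baseline$area_cm2
  alast <- x$last$area_cm2
  tibble(
    patient_id = x$baseline$patient_id,
    location = x$baseline$location,
    n_scans = nrow(obs),
    baseline_day = x$baseline$day,
    last_day = x$last$day,
    a0_cm2 = a0,
    a_last_cm2 = alast,
    delta_a_cm2 = absolute_reduction(a0, alast),
    percent_reduction = percent_reduction(a0, alast),
    early_phase_reduction_pct = early_phase_reduction(x),
    daily_rate_early_cm2_per_day = daily_healing_rate(x, at_index = 1L),
    daily_rate_overall_cm2_per_day = daily_healing_rate(x),
    grew = alast > a0
  )
}

#' @rdname wound_metrics
#' @export
wound_metrics.data.frame <- function(x, ...) {
  series <- split_wound_series(x)
  out <- list_rbind(map(series, wound_metrics))
  arrange(out, .data$patient_id, .data$location)
}

#' Patient-level summary: BSA and TBSA-scale burden
#'
#' Joins wound observations with patient anthropometrics and returns, per
#' patient: the Du Bois BSA recomputed from height and weight, the total
#' baseline wound area, the baseline burden as a TBSA percentage, and the
#' overall reduction in burden `delta TBSA %`.
#'
#' @param observations Data frame with `patient_id`, `location`, `day`,
#'   `area_cm2`.
#' @param patients Data frame with `patient_id`, `height_cm`, `weight_kg`
#'   (other columns are carried through).
#' @return A tibble with one row per patient.
#' @export
patient_summary <- function(observations, patients) {
  check_columns(observations, c("patient_id", "location", "day", "area_cm2"))
  check_columns(patients, c("patient_id", "height_cm", "weight_kg"))
  orphans <- setdiff(observations$patient_id, patients$patient_id)
  if (length(orphans)) {
    bp_abort(sprintf("observations reference unknown patient(s): %s.",
                     paste(orphans, collapse = ", ")), "bp_error_integrity")
  }
  per_wound <- wound_metrics(observations)
  per_patient <- per_wound |>
    group_by(.data$patient_id) |>
    summarise(
      n_wounds = n(),
      baseline_total_cm2 = sum(.data$a0_cm2),
      delta_a_total_cm2 = sum(.data$delta_a_cm2),
      .groups = "drop"
    )
  patients |>
    as_tibble() |>
    mutate(bsa_m2 = du_bois_bsa(.data$weight_kg, .data$height_cm)) |>
    inner_join(per_patient, by = "patient_id") |>
    mutate(
      tbsa_baseline_pct = tbsa_percent(.data$baseline_total_cm2, .data$bsa_m2),
      delta_tbsa_pct = tbsa_percent(.data$delta_a_total_cm2, .data$bsa_m2)
    )
}
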
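#' Build the wound-level cohort table
#'
#' Assembles one row per wound carrying the full set of area-based metrics
#' (baseline and last area, absolute and percentage reduction) together with
#' the patient-level TBSA-scale quantities (baseline TBSA%, delta TBSA%,
#' recomputed Du Bois BSA — BSA is always recomputed from height and weight,
#' never taken from a reported column) and, when supplied, per-wound
#' clinical annotations (burn mechanism, burn degree, surgery flag, and an
#' `excluded` flag marking rows whose originally reported derived values are
#' known to be internally inconsistent; the exclusion is visible, never
#' silent).
#'
#' @param patients Data frame: `patient_id`, `height_cm`, `weight_kg`, plus
#'   optional demographics.
#' @param observations Data frame: `patient_id`, `location`, `day`,
#'   `area_cm2` (one row per scan).
#' @param annotations Optional data frame: `patient_id`, `location`,
#'   `mechanism`, `degree`, `surgery`, optionally `excluded` and `note`.
#' @return A tibble of class `cohort_table`, one row per wound, with
#'   attributes `n_patients` and `n_wounds`.
#' @export
build_cohort_table <- function(patients, observations, annotations = NULL) {
  check_columns(patients, c("patient_id", "height_cm", "weight_kg"))
  check_columns(observations, c("patient_id", "location", "day", "area_cm2"))
  orphans <- setdiff(observations$patient_id, patients$patient_id)
  if (length(orphans)) {
    bp_abort(sprintf("observations reference unknown patient(s): %s.",
                     paste(orphans, collapse = ", ")), "bp_error_integrity")
  }
  per_wound <- wound_metrics(observations)
  per_patient <- patient_summary(observations, patients) |>
    select("patient_id", "bsa_m2", "tbsa_baseline_pct", "delta_tbsa_pct")
  tab <- per_wound |>
    inner_join(per_patient, by = "patient_id")
  if (!is.null(annotations)) {
    check_columns(annotations, c("patient_id", "location", "mechanism",
                                 "degree"))
    tab <- tab |>
      left_join(as_tibble(annotations), by = c("patient_id", "location"))
    if (anyNA(tab$mechanism)) {
      bp_abort("some wounds lack a mechanism annotation.",
               "bp_error_annotation")
    }
  }
  if (!"excluded" %in% names(tab)) tab$excluded <- FALSE
  tab <- arrange(tab, .data$patient_id, .data$location)
  structure(tab,
            class = c("cohort_table", class(tab)),
            n_patients = length(unique(tab$patient_id)),
            n_wounds = nrow(tab))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients, %d wounds\n",
              attr(x, "n_patients"), attr(x, "n_wounds")))
  NextMethod()
}

#' @exportS3Method generics::tidy
tidy.cohort_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cohort_table")
  attr(out, "n_patients") <- NULL
  attr(out, "n_wounds") <- NULL
  as_tibble(out)
}

#' @exportS3Method generics::glance
glance.cohort_table <- function(x, ...) {
  pat <- distinct(tidy(x), .data$patient_id, .data$delta_tbsa_pct)
  tibble(
    n_patients = attr(x, "n_patients"),
    n_wounds = attr(x, "n_wounds"),
    a0_min_cm2 = min(x$a0_cm2),
    a0_max_cm2 = max(x$a0_cm2),
    percent_reduction_min = min(x$percent_reduction),
    percent_reduction_max = max(x$percent_reduction),
    delta_tbsa_min_pct = min(pat$delta_tbsa_pct),
    delta_tbsa_max_pct = max(pat$delta_tbsa_pct)
  )
}

#' Cohort-wide ranges of the headline metrics
#'
#' Extrema and medians over the wound rows for baseline area and percent
#' reduction, and over patients for delta TBSA%. Medians use the standard
#' midpoint convention for even counts.
#'
#' @param table A [build_cohort_table()] result.
#' @return A tibble with columns `metric`, `min`, `median`, `max`.
#' @export
cohort_ranges <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table) == 0L) {
    bp_abort("empty cohort table.", "bp_error_input")
  }
  pat <- distinct(tidy(table), .data$patient_id, .data$delta_tbsa_pct)
  tibble(
    metric = c("a0_cm2", "percent_reduction", "delta_tbsa_pct"),
    min = c(min(table$a0_cm2), min(table$percent_reduction),
            min(pat$delta_tbsa_pct)),
    median = c(median(table$a0_cm2), median(table$percent_reduction),
               median(pat$delta_tbsa_pct)),
    max = c(max(table$a0_cm2), max(table$percent_reduction),
            max(pat$delta_tbsa_pct))
  )
}

#' Grouped cohort summaries
#'
#' Tabulates the distribution of baseline TBSA% and percent reduction by
#' burn mechanism or burn degree — a tabular counterpart to the usual swarm
#' plots. Mixed burn degrees (e.g. `"IIb and III"`) are their own
#' categories; annotations apply to whole patients, so patient counts sum
#' to the cohort size.
#'
#' @param table An annotated [build_cohort_table()] result.
#' @param by `"mechanism"` or `"degree"`.
#' @return A tibble with one row per group: wound and patient counts plus
#'   median/min/max of percent reduction (over wounds) and of baseline
#'   TBSA% (over patients).
#' @export
group_summary <- function(table, by = c("mechanism", "degree")) {
  stopifnot(inherits(table, "cohort_table"))
  by <- match.arg(by)
  if (!by %in% names(table)) {
    bp_abort(sprintf("cohort table has no '%s' annotation.", by),
             "bp_error_annotation")
  }
  if (anyNA(table[[by]])) {
    bp_abort(sprintf("unknown (missing) '%s' label on some wounds.", by),
             "bp_error_annotation")
  }
  tab <- tidy(table)
  wound_part <- tab |>
    group_by(group = .data[[by]]) |>
    summarise(
      n_wounds = n(),
      percent_reduction_median = median(.data$percent_reduction),
      percent_reduction_min = min(.data$percent_reduction),
      percent_reduction_max = max(.data$percent_reduction),
      .groups = "drop"
    )
  patient_part <- tab |>
    distinct(.data$patient_id, group = .data[[by]],
             .data$tbsa_baseline_pct) |>
    group_by(.data$group) |>
    summarise(
      n_patients = n_distinct(.data$patient_id),
      tbsa_median = median(.data$tbsa_baseline_pct),
      tbsa_min = min(.data$tbsa_baseline_pct),
      tbsa_max = max(.data$tbsa_baseline_pct),
      .groups = "drop"
    )
  inner_join(patient_part, wound_part, by = "group") |>
    arrange(desc(.data$n_patients), .data$group)
}

# ---- bundled pilot cohort ----------------------------------------------

read_extdata_csv <- function(name) {
  path <- system.file("extdata", name, package = "burnplanimetry",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' The bundled pilot burn cohort
#'
#' Loads the package's pilot dataset: 18 patients with 43 acute thermal
#' burn wounds followed by serial structured-light 3D scanning in a burn
#' unit. Returns the patient anthropometrics, the per-scan wound area
#' observations, per-wound clinical annotations (mechanism, degree,
#' surgery, plus `excluded` flags on wounds whose originally reported
#' derived values are internally inconsistent), and the originally reported
#' derived values (BSA, delta A, percent reduction, delta TBSA%) retained
#' for cross-checking, with `flag` columns documenting known typos and
#' rounding inconsistencies in the source records.
#'
#' @return A named list of tibbles: `patients`, `observations`,
#'   `annotations`, `reported_patients`, `reported_wounds`.
#' @examples
#' cohort <- burn_pilot_cohort()
#' tab <- build_cohort_table(cohort$patients, cohort$observations,
#'                           cohort$annotations)
#' glance(tab)
#' @export
burn_pilot_cohort <- function() {
  list(
    patients = read_extdata_csv("patients.csv"),
    observations = read_extdata_csv("wound_observations.csv"),
    annotations = read_extdata_csv("wound_annotations.csv"),
    reported_patients = read_extdata_csv("reported_patients.csv"),
    reported_wounds = read_extdata_csv("reported_wounds.csv")
  )
}
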
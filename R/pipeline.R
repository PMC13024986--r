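#' Measure wound area from a mesh file
#'
#' The file-level front door for a single scan: reads and validates the
#' mesh, attaches a label sidecar or applies the configured colour rule,
#' splits the selection into edge-connected components, suppresses speckle
#' below `min_component_area_cm2`, and writes per-component and total wound
#' areas. Results go to `measurements.csv` (fixed 2-decimal formatting, for
#' side-by-side comparison with clinical tables) and `measurements.json`
#' (full precision, plus provenance: selection rule, thresholds, mesh
#' statistics).
#'
#' @param mesh_path Path to a PLY/OBJ/STL file.
#' @param out_dir Output directory (created if needed).
#' @param labels_path Optional label sidecar CSV; when absent, the colour
#'   rule in `config` is applied (the mesh must then carry colours).
#' @param config A [run_config()].
#' @return The per-component measurement tibble, invisibly.
#' @export
run_measure <- function(mesh_path, out_dir, labels_path = NULL,
                        config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- validate_mesh(read_mesh(mesh_path),
                        area_epsilon = config$area_epsilon)
  roi <- if (!is.null(labels_path)) {
    roi_from_labels(attach_vertex_labels(mesh, labels_path),
                    label_value = config$label_value,
                    inclusion_rule = config$inclusion_rule)
  } else {
    if (is.null(mesh$colors)) {
      bp_abort(
        "no label sidecar given and the mesh carries no colours: configure a selection pathway.",
        "bp_error_config")
    }
    roi_from_color(mesh, channel_weights = config$channel_weights,
                   threshold = config$color_threshold,
                   polarity = config$color_polarity)
  }
  comps <- mesh_components(mesh, roi$face_indices)
  kept <- filter_components(comps, mesh,
                            min_area_cm2 = config$min_component_area_cm2,
                            source = roi$source)
  comp_areas <- map_dbl(comps, function(fs) surface_area(mesh, fs))
  keep <- comp_areas >= config$min_component_area_cm2
  per_comp <- tibble(
    component = seq_along(comps),
    n_faces = lengths(comps),
    area_cm2 = comp_areas,
    kept = keep
  )
  out <- bind_rows(
    filter(per_comp, .data$kept) |> select(-"kept"),
    tibble(component = NA_integer_,
           n_faces = length(kept$face_indices),
           area_cm2 = kept$area_cm2)
  )
  csv <- mutate(out, area_cm2 = sprintf("%.2f", .data$area_cm2),
                component = ifelse(is.na(.data$component), "TOTAL",
                                   as.character(.data$component)))
  readr::write_csv(csv, file.path(out_dir, "measurements.csv"))
  jsonlite::write_json(
    list(
      mesh = list(path = mesh_path, n_vertices = n_vertices(mesh),
                  n_faces = n_faces(mesh),
                  total_area_cm2 = surface_area(mesh)),
      selection = list(source = roi$source,
                       inclusion_rule = config$inclusion_rule,
                       label_value = config$label_value,
                       channel_weights = config$channel_weights,
                       color_threshold = config$color_threshold,
                       min_component_area_cm2 =
                         config$min_component_area_cm2),
      components = per_comp,
      total_area_cm2 = kept$area_cm2
    ),
    file.path(out_dir, "measurements.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(per_comp)
}

read_schema_csv <- function(path, cols, what) {
  if (!file.exists(path)) {
    bp_abort(sprintf("cannot read %s file '%s'.", what, path),
             "bp_error_input")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    bp_abort(sprintf("%s file '%s' lacks column(s): %s.", what, path,
                     paste(missing, collapse = ", ")), "bp_error_schema")
  }
  if (nrow(df) == 0L) {
    bp_abort(sprintf("%s file '%s' has no rows.", what, path),
             "bp_error_input")
  }
  df
}

write_table_pair <- function(df, out_dir, stem, digits = 2) {
  num <- vapply(df, is.numeric, TRUE)
  csv <- df
  csv[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x), as.character(x), sprintf("%.*f", digits, x))
  })
  readr::write_csv(csv, file.path(out_dir, paste0(stem, ".csv")))
  jsonlite::write_json(df, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(df)
}

#' Compute wound- and patient-level metric tables from CSV inputs
#'
#' Reads a per-scan observation CSV (`patient_id,location,day,area_cm2`)
#' and a patient CSV (`patient_id,sex,age,height_cm,weight_kg`), computes
#' the longitudinal metrics per wound and the BSA/TBSA summary per patient,
#' and writes each as a fixed 2-decimal CSV plus a full-precision JSON
#' twin.
#'
#' @param observations_csv,patients_csv Input CSV paths.
#' @param out_dir Output directory.
#' @return A list with the `wound_metrics` and `patient_summary` tibbles,
#'   invisibly.
#' @export
run_metrics <- function(observations_csv, patients_csv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obs <- read_schema_csv(observations_csv,
                         c("patient_id", "location", "day", "area_cm2"),
                         "observations")
  pat <- read_schema_csv(patients_csv,
                         c("patient_id", "height_cm", "weight_kg"),
                         "patients")
  wm <- wound_metrics(obs)
  ps <- patient_summary(obs, pat)
  write_table_pair(wm, out_dir, "wound_metrics")
  write_table_pair(ps, out_dir, "patient_summary", digits = 3)
  invisible(list(wound_metrics = wm, patient_summary = ps))
}

#' Build and export the cohort table and its summaries
#'
#' Assembles the annotated wound-level cohort table and writes it as
#' `cohort_table.csv`/`.json`, together with `cohort_summary.json` holding
#' the cohort ranges and the grouped tabulations by mechanism and degree.
#'
#' @param patients_csv,observations_csv,annotations_csv Input CSV paths.
#' @param out_dir Output directory.
#' @return The `cohort_table`, invisibly.
#' @export
run_cohort <- function(patients_csv, observations_csv, annotations_csv,
                       out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pat <- read_schema_csv(patients_csv,
                         c("patient_id", "height_cm", "weight_kg"),
                         "patients")
  obs <- read_schema_csv(observations_csv,
                         c("patient_id", "location", "day", "area_cm2"),
                         "observations")
  ann <- read_schema_csv(annotations_csv,
                         c("patient_id", "location", "mechanism", "degree"),
                         "annotations")
  tab <- build_cohort_table(pat, obs, ann)
  cols <- intersect(
    c("patient_id", "location", "mechanism", "degree", "surgery",
      "baseline_day", "last_day", "a0_cm2", "a_last_cm2", "delta_a_cm2",
      "percent_reduction", "delta_tbsa_pct", "excluded"),
    names(tab))
  write_table_pair(select(tidy(tab), all_of(cols)), out_dir, "cohort_table")
  jsonlite::write_json(
    list(
      n_patients = attr(tab, "n_patients"),
      n_wounds = attr(tab, "n_wounds"),
      ranges = cohort_ranges(tab),
      by_mechanism = group_summary(tab, "mechanism"),
      by_degree = group_summary(tab, "degree")
    ),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(tab)
}

#' Generate and export a synthetic scan series
#'
#' Emits, per scan day, an ASCII PLY of the painted mesh and a label
#' sidecar CSV, plus a `manifest.json` recording the scene, the trajectory
#' and the closed-form true areas — enough to exercise any downstream
#' stage from files alone.
#'
#' @param out_dir Output directory.
#' @param scene A [synthetic_scene()].
#' @param trajectory A [trajectory_spec()].
#' @return The series tibble, invisibly.
#' @export
run_synth <- function(out_dir, scene = synthetic_scene(),
                      trajectory = trajectory_spec("exponential",
                                                   a0_cm2 = 10, rate = 0.1,
                                                   scan_days = c(1, 4, 8))) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- generate_series(scene, trajectory)
  files <- pmap(list(series$mesh, series$day), function(m, d) {
    ply <- file.path(out_dir, sprintf("scan_day%03d.ply", d))
    lab <- file.path(out_dir, sprintf("scan_day%03d_labels.csv", d))
    write_mesh(m, ply)
    write_vertex_labels(m, lab)
    list(day = d, mesh = basename(ply), labels = basename(lab))
  })
  jsonlite::write_json(
    list(
      scene = unclass(scene),
      trajectory = unclass(attr(series, "trajectory")),
      scans = files,
      true_area_cm2 = series$true_area_cm2
    ),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(series)
}
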
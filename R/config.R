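#' Run configuration for the pipeline front-ends
#'
#' Bundles the tunable knobs of the measurement pipeline with documented
#' defaults. Configurations round-trip losslessly through a plain-text
#' `key: value` file, so a run can be archived and reproduced exactly.
#'
#' @param inclusion_rule Face inclusion rule for label-driven selection;
#'   `"all_vertices"` (conservative default: boundary triangles never count
#'   as wound) or `"majority"`.
#' @param label_value Wound label id selected by the label pathway.
#' @param channel_weights RGB weights of the colour rule.
#' @param color_threshold Score threshold of the colour rule.
#' @param color_polarity `"above"` or `"below"`.
#' @param min_component_area_cm2 Components smaller than this are treated
#'   as speckle and dropped (0 keeps everything).
#' @param area_epsilon Degenerate-face threshold (mm^2) for
#'   [validate_mesh()].
#' @param seed Integer seed for any stochastic step.
#' @param out_dir Output directory for the `run_*` front-ends.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(inclusion_rule = "all_vertices",
                       label_value = 1L,
                       channel_weights = c(1, -1, -1),
                       color_threshold = 0,
                       color_polarity = "above",
                       min_component_area_cm2 = 0,
                       area_epsilon = 1e-8,
                       seed = 1L,
                       out_dir = ".") {
  structure(
    list(inclusion_rule = inclusion_rule,
         label_value = as.integer(label_value),
         channel_weights = as.numeric(channel_weights),
         color_threshold = as.numeric(color_threshold),
         color_polarity = color_polarity,
         min_component_area_cm2 = as.numeric(min_component_area_cm2),
         area_epsilon = as.numeric(area_epsilon),
         seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path Path of the `key: value` text file.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt1 <- function(x) {
    if (is.character(x)) x else
      paste(vapply(x, function(v) format(v, digits = 17), ""),
            collapse = ",")
  }
  writeLines(sprintf("%s: %s", names(config),
                     vapply(config, fmt1, "")), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    bp_abort(sprintf("config file '%s' not found.", path), "bp_error_input")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  defaults <- run_config()
  cfg <- defaults
  for (m in kv) {
    if (length(m) != 3L) next
    key <- trimws(m[2]); val <- trimws(m[3])
    if (!key %in% names(defaults)) {
      bp_abort(sprintf("unknown config key '%s'.", key), "bp_error_config")
    }
    proto <- defaults[[key]]
    cfg[[key]] <- if (is.character(proto)) {
      val
    } else if (is.integer(proto)) {
      as.integer(val)
    } else {
      as.numeric(strsplit(val, ",")[[1]])
    }
  }
  class(cfg) <- "run_config"
  cfg
}
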
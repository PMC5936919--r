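# Readers and writers for the package's plain-text dialects: solvent
# property tables, partition tables, module/operating key-value configs and
# concentration time-course CSVs. All bench units are converted to SI here.

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 comment.char = "#"),
                 error = function(e) {
                   stop(sprintf("%s: cannot parse CSV (%s)", path,
                                conditionMessage(e)), call. = FALSE)
                 })
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: line 1: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

check_numeric_column <- function(df, col, path) {
  raw <- df[[col]]
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(v))
  if (length(bad)) {
    stop(sprintf("%s: line %d: non-numeric value '%s' in column '%s'",
                 path, bad[1] + 1L, raw[bad[1]], col), call. = FALSE)
  }
  v
}

#' Read a solvent/solute property table
#'
#' CSV with header columns `name`, `molar_mass_g_mol`, `viscosity_mPa_s`,
#' `density_kg_m3`, `vapour_pressure_hPa`, `toxicity_class`,
#' `association_factor` (and optionally `miscible_with_water`); empty cells
#' for missing optional values.
#'
#' @param path CSV file path.
#' @return named list of [phase_spec()] objects (class `solvent_table`);
#'   `as.data.frame()` recovers the tabular form.
#' @export
read_solvent_table <- function(path) {
  df <- read_csv_checked(path, c("name", "molar_mass_g_mol", "viscosity_mPa_s",
                                 "density_kg_m3"))
  for (col in c("molar_mass_g_mol", "viscosity_mPa_s", "density_kg_m3",
                "vapour_pressure_hPa", "toxicity_class", "association_factor")) {
    if (col %in% names(df)) df[[col]] <- check_numeric_column(df, col, path)
  }
  phases <- lapply(seq_len(nrow(df)), function(i) {
    phase_spec(
      name = df$name[i],
      molar_mass = df$molar_mass_g_mol[i],
      viscosity = df$viscosity_mPa_s[i],
      density = df$density_kg_m3[i],
      vapour_pressure = if ("vapour_pressure_hPa" %in% names(df)) df$vapour_pressure_hPa[i] else NA_real_,
      toxicity_class = if ("toxicity_class" %in% names(df)) df$toxicity_class[i] else NA_integer_,
      association_factor = if ("association_factor" %in% names(df) && is.finite(df$association_factor[i])) df$association_factor[i] else 1.0,
      miscible_with_water = if ("miscible_with_water" %in% names(df)) isTRUE(as.logical(df$miscible_with_water[i])) else FALSE
    )
  })
  names(phases) <- df$name
  structure(phases, class = "solvent_table", table = df)
}

#' @export
as.data.frame.solvent_table <- function(x, ...) {
  df <- attr(x, "table")
  names(df)[names(df) == "name"] <- "solvent"
  if ("vapour_pressure_hPa" %in% names(df)) {
    names(df)[names(df) == "vapour_pressure_hPa"] <- "vapour_pressure"
  }
  if (!"miscible_with_water" %in% names(df)) df$miscible_with_water <- FALSE
  df$miscible_with_water <- as.logical(df$miscible_with_water)
  df
}

#' Read a partition-coefficient table
#'
#' CSV with columns `solute`, `solvent`, `medium`, `logP_pred`, `logP_exp`
#' (either logP may be empty).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_partition_table <- function(path) {
  df <- read_csv_checked(path, c("solute", "solvent", "medium"))
  if (!"logP_pred" %in% names(df)) df$logP_pred <- NA_real_
  if (!"logP_exp" %in% names(df)) df$logP_exp <- NA_real_
  df$logP_pred <- check_numeric_column(df, "logP_pred", path)
  df$logP_exp <- check_numeric_column(df, "logP_exp", path)
  df
}

#' Read a module/operating key-value configuration
#'
#' Flat text file of `key = value` lines (`#` comments allowed) with
#' unit-suffixed keys, e.g. `d_i_mm = 3`, `flow_lumen_ml_min = 3`. Unknown
#' keys are kept verbatim.
#'
#' @param path config file path.
#' @return named list of values (numeric where possible), class
#'   `module_config`.
#' @export
read_module_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  cfg <- list()
  for (i in keep) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("%s: line %d: expected 'key = value'", path, i), call. = FALSE)
    }
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  structure(cfg, class = "module_config", path = path)
}

config_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) return(cfg[[key]])
  if (is.null(default)) {
    stop(sprintf("config is missing required key '%s'", key), call. = FALSE)
  }
  default
}

#' Build a membrane module from a configuration
#'
#' @param cfg [read_module_config()] result (or named list). Keys:
#'   `n_fibres`, `d_i_mm`, `d_o_mm`, `length_cm`, `pore_um`, `porosity`,
#'   `tortuosity`, `shell_id_mm`, `beta` (optional, default 5.8).
#' @return [membrane_module()].
#' @export
module_from_config <- function(cfg) {
  membrane_module(
    n_fibres = config_get(cfg, "n_fibres"),
    d_i = mm_to_m(config_get(cfg, "d_i_mm")),
    d_o = mm_to_m(config_get(cfg, "d_o_mm")),
    length = config_get(cfg, "length_cm") / 100,
    pore_size = config_get(cfg, "pore_um", NA_real_) * 1e-6,
    porosity = config_get(cfg, "porosity"),
    tortuosity = config_get(cfg, "tortuosity"),
    shell_inner_diameter = mm_to_m(config_get(cfg, "shell_id_mm")),
    beta = config_get(cfg, "beta", 5.8)
  )
}

#' Build an operating point from a configuration
#'
#' @param cfg [read_module_config()] result. Keys: `mode`,
#'   `flow_lumen_ml_min`, `flow_shell_ml_min`, `temperature_c` (default 25),
#'   `v_w_ml`, `v_s_ml`, `c_w0_mg_ml` (optional).
#' @param mode override for the configured mode.
#' @return [operating_point()].
#' @export
operating_from_config <- function(cfg, mode = NULL) {
  operating_point(
    mode = if (!is.null(mode)) mode else config_get(cfg, "mode"),
    Q_lumen = ml_min_to_m3_s(config_get(cfg, "flow_lumen_ml_min")),
    Q_shell = ml_min_to_m3_s(config_get(cfg, "flow_shell_ml_min")),
    temperature = celsius_to_kelvin(config_get(cfg, "temperature_c", 25)),
    V_w = ml_to_m3(config_get(cfg, "v_w_ml", NA_real_)),
    V_s = ml_to_m3(config_get(cfg, "v_s_ml", NA_real_)),
    c_w0 = mg_ml_to_kg_m3(config_get(cfg, "c_w0_mg_ml", NA_real_))
  )
}

#' Write a time course in the long CSV dialect
#'
#' Columns `time_min`, `stream` (`aqueous`|`organic`), `location`
#' (`reservoir`|`outlet`), `conc_mg_ml`. Outlet rows are emitted only when
#' the course carries outlet columns.
#'
#' @param course `timecourse` data.frame (`time` in s, concentrations in
#'   kg/m3 = mg/ml).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(course, path) {
  stopifnot(is.data.frame(course), all(c("time", "c_w", "c_s") %in% names(course)))
  time_min <- course$time / 60
  long <- rbind(
    data.frame(time_min = time_min, stream = "aqueous", location = "reservoir",
               conc_mg_ml = course$c_w),
    data.frame(time_min = time_min, stream = "organic", location = "reservoir",
               conc_mg_ml = course$c_s)
  )
  if ("c_w_outlet" %in% names(course)) {
    long <- rbind(long,
      data.frame(time_min = time_min, stream = "aqueous", location = "outlet",
                 conc_mg_ml = course$c_w_outlet),
      data.frame(time_min = time_min, stream = "organic", location = "outlet",
                 conc_mg_ml = course$c_s_outlet))
  }
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time course from the long CSV dialect
#'
#' @param path CSV path with columns `time_min`, `stream`, `location`,
#'   `conc_mg_ml` (see [write_timecourse_csv()]).
#' @return `timecourse` data.frame with `time` (s), `c_w`, `c_s` and, when
#'   present in the file, `c_w_outlet`, `c_s_outlet`.
#' @export
read_timecourse_csv <- function(path) {
  df <- read_csv_checked(path, c("time_min", "stream", "location", "conc_mg_ml"))
  df$time_min <- check_numeric_column(df, "time_min", path)
  df$conc_mg_ml <- check_numeric_column(df, "conc_mg_ml", path)
  bad_stream <- which(!df$stream %in% c("aqueous", "organic"))
  if (length(bad_stream)) {
    stop(sprintf("%s: line %d: stream must be 'aqueous' or 'organic', got '%s'",
                 path, bad_stream[1] + 1L, df$stream[bad_stream[1]]), call. = FALSE)
  }
  pick <- function(stream, location) {
    sub <- df[df$stream == stream & df$location == location, ]
    sub[order(sub$time_min), ]
  }
  aq <- pick("aqueous", "reservoir")
  or <- pick("organic", "reservoir")
  if (nrow(aq) == 0L) {
    stop(sprintf("%s: no aqueous reservoir rows", path), call. = FALSE)
  }
  out <- data.frame(time = min_to_s(aq$time_min), c_w = aq$conc_mg_ml)
  out$c_s <- if (nrow(or) == nrow(aq)) or$conc_mg_ml else NA_real_
  aq_out <- pick("aqueous", "outlet")
  if (nrow(aq_out) == nrow(aq)) out$c_w_outlet <- aq_out$conc_mg_ml
  or_out <- pick("organic", "outlet")
  if (nrow(or_out) == nrow(aq)) out$c_s_outlet <- or_out$conc_mg_ml
  structure(out, class = c("timecourse", "data.frame"),
            c_w0 = out$c_w[which.min(out$time)])
}
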
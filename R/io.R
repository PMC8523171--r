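#' @name coopbind-io
#' @title Tabular readers/writers and the JSON result envelope
#' @description
#' All tabular inputs are plain CSV with required named headers (column
#' order is free; unknown extra columns are ignored with a warning; a
#' missing column or a non-numeric cell is an error naming the column and
#' row). Results are wrapped in a JSON envelope carrying the tool version,
#' timestamp, configuration echo and warnings, so every output is
#' reproducible from its own metadata.
NULL

read_schema_csv <- function(path, required_numeric, required_character = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  required <- c(required_numeric, required_character)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  df <- df[required]
  for (col in required_numeric) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (anyNA(v)) {
      if (length(bad) == 0L) bad <- which(is.na(v))
      stop(sprintf("non-numeric value in column '%s' at data row %d", col,
                   bad[1L]), call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Read / write a thermogram CSV
#'
#' Schema: `injection_index, volume_ul, heat_ucal` (header required). The
#' cell geometry and concentrations are not part of the file and must be
#' supplied to reconstruct the protocol.
#'
#' @param path CSV path.
#' @param cell_volume_ul,syringe_conc_um,cell_conc_um,temperature_c
#'   Protocol fields (see [itc_protocol()]).
#' @return A [thermogram()].
#' @export
read_thermogram_csv <- function(path, cell_volume_ul = 200,
                                syringe_conc_um = 120, cell_conc_um = 15,
                                temperature_c = 25) {
  df <- read_schema_csv(path, c("injection_index", "volume_ul", "heat_ucal"))
  df <- df[order(df$injection_index), ]
  protocol <- itc_protocol(cell_volume_ul = cell_volume_ul,
                           injection_volumes_ul = df$volume_ul,
                           syringe_conc_um = syringe_conc_um,
                           cell_conc_um = cell_conc_um,
                           temperature_c = temperature_c)
  thermogram(df$heat_ucal, protocol)
}

#' @rdname read_thermogram_csv
#' @param tg A [thermogram()] to write.
#' @export
write_thermogram_csv <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  df <- data.frame(injection_index = seq_along(tg$heats_ucal),
                   volume_ul = tg$protocol$injection_volumes_ul,
                   heat_ucal = tg$heats_ucal)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write profile CSVs
#'
#' Schema: `path_id, cell_id, replicate_id, position_px, intensity_gfp,
#' intensity_rfp`; one row per pixel, grouped into one
#' [two_channel_profile()] per `path_id`.
#'
#' @param path CSV path.
#' @param pixel_size_nm Pixel size to stamp on the profiles.
#' @return A list of [two_channel_profile()] objects.
#' @export
read_profiles_csv <- function(path, pixel_size_nm = 120) {
  df <- read_schema_csv(path,
                        c("position_px", "intensity_gfp", "intensity_rfp"),
                        c("path_id", "cell_id", "replicate_id"))
  lapply(split(df, df$path_id), function(d) {
    d <- d[order(d$position_px), ]
    two_channel_profile(d$intensity_gfp, d$intensity_rfp,
                        pixel_size_nm = pixel_size_nm,
                        path_id = d$path_id[1L], cell_id = d$cell_id[1L],
                        replicate_id = d$replicate_id[1L])
  })
}

#' @rdname read_profiles_csv
#' @param profiles List of [two_channel_profile()] objects to write.
#' @export
write_profiles_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(path_id = p$path_id, cell_id = p$cell_id,
               replicate_id = p$replicate_id,
               position_px = seq_along(p$intensity_gfp) - 1L,
               intensity_gfp = p$intensity_gfp,
               intensity_rfp = p$intensity_rfp)
  }))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write object and cell tables
#'
#' Objects schema: `object_id, cell_id, condition, location, tdp_intensity,
#' mrna_intensity, area_px`. Cells schema: `cell_id, condition,
#' nuclear_mean, cytoplasmic_mean`.
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_objects_csv <- function(path) {
  df <- read_schema_csv(path,
                        c("tdp_intensity", "mrna_intensity", "area_px"),
                        c("object_id", "cell_id", "condition", "location"))
  validate_objects(df)
}

#' @rdname read_objects_csv
#' @param records Objects data frame to write.
#' @export
write_objects_csv <- function(records, path) {
  utils::write.csv(format(validate_objects(records), digits = 17,
                          trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_objects_csv
#' @export
read_cells_csv <- function(path) {
  read_schema_csv(path, c("nuclear_mean", "cytoplasmic_mean"),
                  c("cell_id", "condition"))
}

#' @rdname read_objects_csv
#' @param cells Cells data frame to write.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(format(cells, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Result envelope
#'
#' Wraps an analysis payload with the package version, a timestamp, an echo
#' of the effective configuration (including any seed) and accumulated
#' warnings; serializes losslessly to/from JSON.
#'
#' @param payload Any JSON-serializable result (list/data frame).
#' @param config Named list echoing the run configuration.
#' @param warnings Character vector.
#' @return Object of class `"result_envelope"`.
#' @export
result_envelope <- function(payload, config = list(), warnings = character()) {
  structure(
    list(tool = "coopbind",
         version = as.character(utils::packageVersion("coopbind")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config,
         warnings = warnings,
         payload = payload),
    class = "result_envelope"
  )
}

#' @rdname result_envelope
#' @param env A `result_envelope`.
#' @param path Output JSON path.
#' @export
write_result_json <- function(env, path) {
  stopifnot(inherits(env, "result_envelope"))
  jsonlite::write_json(unclass(env), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname result_envelope
#' @export
read_result_json <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(env, class = "result_envelope")
}

#' @export
print.result_envelope <- function(x, ...) {
  cat(sprintf("<result_envelope> %s %s, %s; %d warning(s)\n", x$tool,
              x$version, x$timestamp, length(x$warnings)))
  utils::str(x$payload, max.level = 1)
  invisible(x)
}
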
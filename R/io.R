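## CSV and JSON serialization. Time series go out as one time column plus
## named channels; observations as (time, channel, value); configs and run
## manifests as JSON. Floats are written at 10 significant digits.

fmt10 <- function(x) formatC(x, digits = 10, format = "g")

#' Write a simulated time series to CSV
#'
#' @param series a \code{sorensen_sim} (or any data.frame with a
#'   \code{time} column).
#' @param path output path.
#' @param channels columns to write besides \code{time} (default: all).
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(series, path, channels = NULL) {
  stopifnot("time" %in% names(series))
  cols <- c("time", channels %||% setdiff(names(series), "time"))
  df <- as.data.frame(series)[cols]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt10)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("time series file lacks a 'time' column")
  df
}

#' Write an observation set to CSV
#'
#' @param obs an [observation_set()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_observations <- function(obs, path) {
  df <- obs$data
  df$time <- fmt10(df$time)
  df$value <- fmt10(df$value)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an observation CSV
#'
#' Expects the schema \code{time,channel,value}; rejects malformed rows
#' with their line number and unknown channels with the list of valid
#' names; an empty file is an error.
#'
#' @param path CSV path.
#' @param sigma scale parameter attached to the resulting set.
#' @return an [observation_set()].
#' @export
read_observations <- function(path, sigma = 0.05) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty observation file: ", path)
  hdr <- strsplit(lines[1], ",")[[1]]
  if (!identical(hdr, c("time", "channel", "value")))
    stop("observation file must have header 'time,channel,value'")
  parts <- strsplit(lines[-1], ",")
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("malformed observation row at line ", bad[1] + 1)
  df <- data.frame(time = as.numeric(vapply(parts, `[`, "", 1)),
                   channel = vapply(parts, `[`, "", 2),
                   value = as.numeric(vapply(parts, `[`, "", 3)))
  nn <- which(!is.finite(df$time) | !is.finite(df$value))
  if (length(nn))
    stop("non-numeric time or value at line ", nn[1] + 1)
  observation_set(df, sigma = sigma)
}

## ---- configuration --------------------------------------------------------

.config_keys <- c("route", "dose", "body_weight", "window", "duration",
                  "grid", "label", "params_preset", "simo_preset",
                  "rtol", "atol", "seed")

#' Load and validate a protocol configuration
#'
#' JSON configuration with the protocol fields plus parameter-preset names
#' and solver tolerances. Unknown keys are rejected by name; type and
#' domain violations are reported with the offending key.
#'
#' @param path JSON file path.
#' @return list with \code{proto} (a [protocol()]), \code{params},
#'   \code{simo}, \code{rtol}, \code{atol}, \code{seed} and the raw
#'   \code{config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(config_error("config file not found: ", path))
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop(config_error("config is not valid JSON: ",
                                      conditionMessage(e))))
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop(config_error("unknown configuration key(s): ",
                      paste(unknown, collapse = ", ")))
  if (is.null(cfg$route)) stop(config_error("missing key 'route'"))
  if (is.null(cfg$dose) && !identical(cfg$route, "none"))
    stop(config_error("missing key 'dose' (number, required for route ",
                      cfg$route, ")"))
  for (k in c("dose", "body_weight", "window", "duration", "grid",
              "rtol", "atol"))
    if (!is.null(cfg[[k]]) && !is.numeric(cfg[[k]]))
      stop(config_error("key '", k, "' must be numeric"))
  proto <- tryCatch(
    protocol(route = cfg$route, dose = cfg$dose %||% 0,
             body_weight = cfg$body_weight %||% 70,
             window = cfg$window %||% 3,
             duration = cfg$duration %||% 180,
             grid = cfg$grid %||% 1, label = cfg$label),
    error = function(e) stop(config_error(conditionMessage(e))))
  params <- tryCatch(sorensen_params(cfg$params_preset %||% "appendix_a1"),
                     error = function(e)
                       stop(config_error("params_preset: ",
                                         conditionMessage(e))))
  simo <- tryCatch(simo_params(cfg$simo_preset %||% "ogtt_fit"),
                   error = function(e)
                     stop(config_error("simo_preset: ", conditionMessage(e))))
  list(proto = proto, params = params, simo = simo,
       rtol = cfg$rtol %||% 1e-8, atol = cfg$atol %||% 1e-10,
       seed = cfg$seed %||% 1, config = cfg)
}

#' Write a protocol configuration
#'
#' @param cfg named list of configuration keys (see [load_config()]).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop(config_error("unknown configuration key(s): ",
                      paste(unknown, collapse = ", ")))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_error <- function(...) {
  structure(class = c("sorensen_config_error", "error", "condition"),
            list(message = paste0(...), call = NULL))
}

#' Run manifest
#'
#' Metadata sufficient to reproduce a run: command, configuration, preset
#' names, seeds, solver tolerances and the package version. Wall-clock
#' fields are informative only.
#'
#' @param command character command name.
#' @param config raw configuration list (may be NULL).
#' @param presets named character vector of preset names.
#' @param seed integer seed(s).
#' @param tolerances named numeric (rtol/atol).
#' @param outputs character paths produced by the run.
#' @return list of class \code{run_manifest}.
#' @export
run_manifest <- function(command, config = NULL, presets = NULL, seed = NULL,
                         tolerances = NULL, outputs = NULL) {
  structure(list(
    command = command, config = config, presets = as.list(presets),
    seed = seed, tolerances = as.list(tolerances), outputs = outputs,
    package_version = tryCatch(
      as.character(utils::packageVersion("sorensen")),
      error = function(e) "unversioned"),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a run manifest as JSON
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
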
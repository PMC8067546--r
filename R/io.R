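## File formats.  All files use seconds, nM, Kelvin, mM; UTF-8 CSV with
## comma separators and '.' decimals; JSON manifests/summaries carry a
## schema_version field so downstream comparisons stay stable.

.schemaVersion <- 1L

#' Write a set of binding traces to CSV plus a JSON manifest
#'
#' The CSV holds the long-format samples with header columns exactly
#' \code{spot_id, probe_class, time_s, sigma}; the sidecar JSON manifest
#' holds the injection schedule and the condition metadata, which are
#' shared by all traces in the file.
#'
#' @param traces a list of \code{\link{BindingTrace}} objects sharing one
#'   schedule
#' @param csvPath output CSV path
#' @param manifestPath output JSON manifest path
#' @return invisibly, the two paths
#' @export
writeTraces <- function(traces, csvPath, manifestPath) {
  if (is(traces, "BindingTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, is, logical(1), "BindingTrace")))
  sch <- traces[[1]]@schedule
  for (tr in traces[-1]) {
    if (!isTRUE(all.equal(tr@schedule@stepTimes, sch@stepTimes)) ||
        !isTRUE(all.equal(tr@schedule@concentrations, sch@concentrations)))
      nwStop("all traces written to one file must share the injection schedule",
             "nwConsistencyError")
  }
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(spot_id = tr@spotId, probe_class = tr@probeClass,
               time_s = tr@times, sigma = tr@sigma)))
  utils::write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  manifest <- list(
    schema_version = .schemaVersion,
    schedule = list(step_times_s = sch@stepTimes,
                    concentrations_nM = sch@concentrations,
                    end_time_s = sch@endTime),
    condition = list(temperature_K = sch@temperature,
                     ionic_strength_mM = sch@ionicStrength))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csvPath, manifestPath))
}

#' Read binding traces from CSV plus a JSON manifest
#'
#' Validates the header (a missing column is reported by name), attaches
#' the schedule from the manifest (a mismatch between the number of
#' injection times and concentrations is a consistency error), sorts
#' unsorted sample times with a warning, and checks that sample times
#' lie within the schedule span.
#'
#' @param csvPath trace CSV (columns spot_id, probe_class, time_s, sigma)
#' @param manifestPath JSON manifest with the schedule and condition
#' @return list of \code{\link{BindingTrace}} objects, one per spot_id
#' @export
readTraces <- function(csvPath, manifestPath) {
  if (!file.exists(csvPath))
    nwStop(sprintf("trace file not found: %s", csvPath), "nwFormatError")
  if (!file.exists(manifestPath))
    nwStop(sprintf("manifest file not found: %s", manifestPath), "nwFormatError")
  df <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  needed <- c("spot_id", "probe_class", "time_s", "sigma")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    nwStop(sprintf("trace CSV is missing column(s): %s",
                   paste(missing, collapse = ", ")), "nwFormatError")
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  st <- as.numeric(man$schedule$step_times_s)
  cc <- as.numeric(man$schedule$concentrations_nM)
  if (length(st) != length(cc))
    nwStop(sprintf("manifest schedule mismatch: %d injection times but %d concentrations",
                   length(st), length(cc)), "nwConsistencyError")
  sch <- StepSchedule(
    stepTimes = st, concentrations = cc,
    endTime = as.numeric(man$schedule$end_time_s %||% max(st) + 3000),
    temperature = as.numeric(man$condition$temperature_K %||% 303.15),
    ionicStrength = as.numeric(man$condition$ionic_strength_mM %||% 150))
  lapply(split(df, df$spot_id), function(d) {
    if (is.unsorted(d$time_s, strictly = TRUE)) {
      nwWarn(sprintf("unsorted sample times in spot '%s'; sorting",
                     d$spot_id[1]), "nwSortWarning")
      d <- d[order(d$time_s), , drop = FALSE]
    }
    if (max(d$time_s) > sch@endTime + 1e-9 || min(d$time_s) < 0)
      nwStop(sprintf("samples of spot '%s' fall outside the schedule span",
                     d$spot_id[1]), "nwConsistencyError")
    BindingTrace(times = d$time_s, sigma = d$sigma, schedule = sch,
                 probeClass = d$probe_class[1], spotId = d$spot_id[1])
  })
}

#' Write per-step fit results to CSV
#'
#' @param steps result of \code{\link{fitAllSteps}} (or a list of them,
#'   concatenated with their spot identity)
#' @param path output CSV path
#' @return invisibly, the path
#' @export
writeStepResults <- function(steps, path) {
  if (!is.list(steps) || is(steps, "DataFrame")) steps <- list(steps)
  df <- do.call(rbind, lapply(steps, function(s) {
    md <- S4Vectors::metadata(s)
    cbind(data.frame(spot_id = md$spotId %||% NA_character_,
                     probe_class = md$probeClass %||% NA_character_),
          as.data.frame(s))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-step fit results written by \code{\link{writeStepResults}}
#'
#' @param path CSV path
#' @return named list of \code{S4Vectors::DataFrame}, one per spot
#' @export
readStepResults <- function(path) {
  if (!file.exists(path))
    nwStop(sprintf("step-results file not found: %s", path), "nwFormatError")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$spot_id), function(d) {
    out <- S4Vectors::DataFrame(d[, setdiff(names(d), c("spot_id", "probe_class")),
                                  drop = FALSE])
    S4Vectors::metadata(out) <- list(spotId = d$spot_id[1],
                                     probeClass = d$probe_class[1])
    out
  })
}

## Known analysis-configuration keys with defaults and validators
.configSpec <- list(
  traces = list(default = NULL, check = is.character),
  manifest = list(default = NULL, check = is.character),
  output_dir = list(default = ".", check = is.character),
  discard_s = list(default = 10, check = function(x) is.numeric(x) && x >= 0),
  kon_regressor = list(default = "c",
                       check = function(x) x %in% c("c", "delta_c", "exact")),
  bootstrap = list(default = FALSE, check = is.logical),
  bootstrap_n = list(default = 500,
                     check = function(x) is.numeric(x) && x >= 10),
  temperature_K = list(default = 303.15,
                       check = function(x) is.numeric(x) && x > 0),
  gas_constant = list(default = 1.987e-3,
                      check = function(x) is.numeric(x) && x > 0),
  seed = list(default = 1, check = is.numeric))

#' Read and validate an analysis configuration (JSON)
#'
#' Unknown keys are rejected with an error naming the key; all numeric
#' settings are validated at load.
#'
#' @param path JSON config path
#' @return named list with defaults filled in, plus \code{config_hash}
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path))
    nwStop(sprintf("config file not found: %s", path), "nwFormatError")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), names(.configSpec))
  if (length(unknown))
    nwStop(sprintf("unknown configuration key(s): %s",
                   paste(unknown, collapse = ", ")), "nwConfigurationError")
  cfg <- lapply(names(.configSpec), function(k) {
    v <- if (k %in% names(raw)) raw[[k]] else .configSpec[[k]]$default
    if (!is.null(v) && !.configSpec[[k]]$check(v))
      nwStop(sprintf("invalid value for configuration key '%s'", k),
             "nwConfigurationError")
    v
  })
  names(cfg) <- names(.configSpec)
  cfg$config_hash <- md5Hash(jsonlite::toJSON(raw, auto_unbox = TRUE,
                                              digits = NA))
  cfg
}

#' Write a machine-readable condition summary (JSON)
#'
#' Fields mirror the condition-level quantities of the analysis
#' (Kd specific/nonspecific, kon, koff per class, K2, dG and their
#' uncertainties), plus the schema version, seed and config hash so
#' reruns are reproducible and comparable.
#'
#' @param summary named list of results (see \code{\link{analyzeProbePair}})
#' @param path output JSON path
#' @param seed integer seed used for the run
#' @param configHash hash of the configuration that produced the run
#' @return invisibly, the path
#' @export
writeSummary <- function(summary, path, seed = NA, configHash = NA_character_) {
  out <- c(list(schema_version = .schemaVersion, seed = seed,
                config_hash = configHash), summary)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
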
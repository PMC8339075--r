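#' DSC cooling run
#'
#' Container for a differential scanning calorimetry run: the programmed and
#' actual sample temperature histories and the differential heat-rate signal
#' per unit sample mass. Sign convention: exothermic events (latent-heat
#' release) raise `dsc_signal`.
#'
#' @param time Time since programme start, s, strictly increasing.
#' @param T_programmed Programmed temperature, degC.
#' @param T_sample Actual sample temperature, degC.
#' @param dsc_signal Differential heat rate per unit mass, W/g,
#'   exothermic-positive.
#' @param mass Sample mass, mg.
#' @param cooling_rate Nominal programme rate, K/min, signed (negative for
#'   cooling).
#' @param sample_id Optional sample label.
#' @details The programmed channel must actually follow the nominal rate:
#' the median of `d(T_programmed)/dt` must agree with `cooling_rate` within
#' 2% (the transition does not perturb the programmed channel, so no window
#' is excluded).
#' @return An object of class `dsc_run` (a data.frame with the four channels
#'   and metadata attributes `mass`, `cooling_rate`, `sample_id`).
#' @export
dsc_run <- function(time, T_programmed, T_sample, dsc_signal,
                    mass, cooling_rate, sample_id = "sample") {
  n <- length(time)
  if (length(T_programmed) != n || length(T_sample) != n || length(dsc_signal) != n) {
    stopf("all channels must have equal length")
  }
  if (n < 10) stopf("a DSC run needs at least 10 samples")
  if (any(diff(time) <= 0)) stopf("time must be strictly increasing")
  if (!is.finite(mass) || mass <= 0) stopf("mass must be positive")
  if (!is.finite(cooling_rate) || cooling_rate == 0) {
    stopf("cooling_rate must be nonzero (negative for cooling)")
  }
  med_rate <- median(diff(T_programmed) / diff(time)) * 60
  if (abs(med_rate - cooling_rate) > 0.02 * abs(cooling_rate)) {
    stopf("programmed channel rate (%.4g K/min) deviates > 2%% from nominal (%.4g K/min)",
          med_rate, cooling_rate)
  }
  structure(data.frame(time = time, T_programmed = T_programmed,
                       T_sample = T_sample, dsc_signal = dsc_signal),
            mass = mass, cooling_rate = cooling_rate, sample_id = sample_id,
            class = c("dsc_run", "data.frame"))
}

run_mass <- function(run) attr(run, "mass")
run_rate <- function(run) attr(run, "cooling_rate")      # K/min, signed
run_rate_Ks <- function(run) attr(run, "cooling_rate") / 60

#' Read / write a DSC run as CSV
#'
#' Plain-text schema: columns `time_s, temp_prog_C, temp_sample_C,
#' dsc_W_per_g`; run metadata (`mass_mg`, `cooling_rate_K_per_min`,
#' `sample_id`) carried in `# key: value` header comment lines, overridable
#' through the function arguments.
#'
#' @param path File path.
#' @param mass_mg,cooling_rate_K_per_min,sample_id Optional metadata
#'   overrides; required if the header lacks them.
#' @return `read_dsc_csv` returns a [dsc_run()]; `write_dsc_csv` returns
#'   `path` invisibly.
#' @export
read_dsc_csv <- function(path, mass_mg = NULL, cooling_rate_K_per_min = NULL,
                         sample_id = NULL) {
  if (!file.exists(path)) stopf("DSC csv not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  if (length(hdr)) {
    meta <- tryCatch(yaml::yaml.load(paste(sub("^#\\s?", "", hdr), collapse = "\n")),
                     error = function(e) list())
    if (!is.list(meta)) meta <- list()
  }
  df <- read.csv(text = paste(grep("^#", lines, invert = TRUE, value = TRUE),
                              collapse = "\n"))
  need <- c("time_s", "temp_prog_C", "temp_sample_C", "dsc_W_per_g")
  if (!all(need %in% names(df))) {
    stopf("DSC csv must have columns %s", paste(need, collapse = ", "))
  }
  mass <- mass_mg %||% meta$mass_mg
  rate <- cooling_rate_K_per_min %||% meta$cooling_rate_K_per_min
  sid <- sample_id %||% meta$sample_id %||% basename(path)
  if (is.null(mass) || is.null(rate)) {
    stopf("mass_mg and cooling_rate_K_per_min must come from the header or arguments")
  }
  dsc_run(df$time_s, df$temp_prog_C, df$temp_sample_C, df$dsc_W_per_g,
          mass = mass, cooling_rate = rate, sample_id = sid)
}

#' @param run A [dsc_run()].
#' @rdname read_dsc_csv
#' @export
write_dsc_csv <- function(run, path) {
  stopifnot(inherits(run, "dsc_run"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mass_mg: %.12g", run_mass(run)),
               sprintf("# cooling_rate_K_per_min: %.12g", run_rate(run)),
               sprintf("# sample_id: %s", attr(run, "sample_id")),
               "time_s,temp_prog_C,temp_sample_C,dsc_W_per_g"), con)
  writeLines(sprintf("%.12g,%.12g,%.12g,%.12g", run$time, run$T_programmed,
                     run$T_sample, run$dsc_signal), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
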
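#' Study protocol configuration
#'
#' Builds the configuration object describing the constant-routine PVT
#' protocol that the synthetic cohort generator emulates: a 10-min
#' Psychomotor Vigilance Test every 2 h while awake, with baseline sessions
#' on days 2-4 (4-14 h after wake) and five total-sleep-deprivation (TSD)
#' sessions on day 4 at 16, 18, 20, 22 and 24 h after wake.
#'
#' @param session_times_by_day named list mapping day (as `"2"`, `"3"`, `"4"`)
#'   to the vector of scheduled times since wake (hours). Defaults to
#'   baseline times 4-14 h on days 2 and 3, and 4-24 h on day 4 (the last
#'   five sessions being the TSD block).
#' @param session_duration scheduled session length in minutes (default 10).
#' @param isi_range inter-stimulus interval range in seconds (default
#'   `c(1, 9)`, sampled uniformly).
#' @param trait_correlation correlation between the baseline-speed trait block
#'   (`base_speed`, `base_sd`) and the vulnerability trait block
#'   (`lapse_propensity`, `homeo_gain`). Default 0.4.
#' @param invalid_session_rate probability that a simulated session is
#'   corrupted in one of the four QC-triggering ways (late administration,
#'   wrong-button excess, >1-min response gap, truncation). Default 0.
#' @param false_start_rate per-trial probability of an anticipatory response
#'   (reaction time below 100 ms). Default 0.02.
#' @param wrong_button_rate per-trial probability of a wrong-button response.
#'   Default 0.01.
#' @param rt_cap maximum reaction time in ms; a trial with no response within
#'   the cap is recorded as a timeout. Default 30000.
#' @param seed master seed; every stochastic draw in the generator flows from
#'   this via deterministic per-participant, per-session stream splitting.
#' @param traits optional list overriding the trait-distribution parameters
#'   (see Details).
#'
#' @details
#' The trait distribution defaults are calibrated once so that a default
#' n = 160 cohort reproduces the study conditions the analysis assumes:
#' TSD group mean lapse counts near the reported resilient / intermediate /
#' vulnerable ranges (0.0-13.6 / 14.0-30.4 / 30.6-52.8 mean lapses per
#' session), roughly half of the between-participant variance in TSD lapses
#' explained by baseline lapses, and about 37% of participants averaging
#' <= 2 lapses per baseline session. See the package vignette for the
#' calibration rationale.
#'
#' @return An object of class `pvt_protocol` (a validated list).
#' @export
pvt_protocol <- function(session_times_by_day = NULL,
                         session_duration = 10,
                         isi_range = c(1, 9),
                         trait_correlation = 0.4,
                         invalid_session_rate = 0,
                         false_start_rate = 0.02,
                         wrong_button_rate = 0.01,
                         rt_cap = 30000,
                         seed = 1L,
                         traits = list()) {
  if (is.null(session_times_by_day)) {
    session_times_by_day <- list(
      "2" = seq(4, 14, by = 2),
      "3" = seq(4, 14, by = 2),
      "4" = seq(4, 24, by = 2)
    )
  }
  assert_that(session_duration > 0, "session_duration must be positive")
  assert_that(length(isi_range) == 2 && isi_range[1] > 0 &&
                isi_range[2] > isi_range[1],
              "isi_range must be an increasing positive pair (seconds)")
  assert_that(abs(trait_correlation) <= 0.95,
              "trait_correlation must lie in [-0.95, 0.95]")
  assert_that(invalid_session_rate >= 0 && invalid_session_rate <= 1,
              "invalid_session_rate must be a probability")

  trait_defaults <- list(
    # attentive-state RT: lognormal meanlog/sdlog (log-ms)
    base_speed_mean = log(280), base_speed_sd = 0.12,
    base_sd_mean    = 0.18,     base_sd_spread = 0.25,
    # lapse-state log-odds model
    lapse_propensity_mean = -3.75, lapse_propensity_sd = 0.65,
    homeo_gain_mean = 0.8, homeo_gain_sd = 0.28,
    homeo_tau = 3,                       # hours; saturating sleep-pressure basis
    circ_amp_mean = 0.5, circ_amp_sd = 0.15,
    circ_phase_mean = 22, circ_phase_sd = 1,
    tot_gain_mean = 0.04, tot_gain_sd = 0.015,
    # within-trait-block correlations
    speed_sd_cor = 0.3, propensity_gain_cor = 0.2,
    # lapse-state RT: shifted Pareto above the lapse threshold
    lapse_rt_min = 500, lapse_rt_alpha = 2,
    # attentive-state time-on-task drift (log-ms per minute)
    attentive_tot_drift = 0.005
  )
  unknown <- setdiff(names(traits), names(trait_defaults))
  if (length(unknown) > 0) {
    stop("unknown trait parameters: ", paste(unknown, collapse = ", "))
  }
  trait_defaults[names(traits)] <- traits

  cfg <- list(
    session_times_by_day = session_times_by_day,
    session_duration = session_duration,
    isi_range = isi_range,
    trait_correlation = trait_correlation,
    invalid_session_rate = invalid_session_rate,
    false_start_rate = false_start_rate,
    wrong_button_rate = wrong_button_rate,
    rt_cap = rt_cap,
    seed = as.integer(seed),
    traits = trait_defaults
  )
  class(cfg) <- "pvt_protocol"
  cfg
}

#' @export
print.pvt_protocol <- function(x, ...) {
  cat("PVT study protocol\n")
  for (d in names(x$session_times_by_day)) {
    cat(sprintf("  day %s sessions (h after wake): %s\n", d,
                paste(x$session_times_by_day[[d]], collapse = ", ")))
  }
  cat(sprintf("  session duration: %g min; ISI uniform on [%g, %g] s\n",
              x$session_duration, x$isi_range[1], x$isi_range[2]))
  cat(sprintf("  trait correlation: %g; invalid session rate: %g; seed: %d\n",
              x$trait_correlation, x$invalid_session_rate, x$seed))
  invisible(x)
}

#' Baseline and sleep-deprivation session times
#'
#' Helpers returning the scheduled day-4 baseline times (4-14 h after wake)
#' and TSD times (16-24 h after wake) for a protocol.
#'
#' @param config a [pvt_protocol()] object.
#' @return Numeric vector of times since wake in hours.
#' @export
baseline_times <- function(config) {
  t4 <- config$session_times_by_day[["4"]]
  t4[t4 <= 14]
}

#' @rdname baseline_times
#' @export
tsd_times <- function(config) {
  t4 <- config$session_times_by_day[["4"]]
  t4[t4 >= 16]
}

# Serialize / restore a protocol as JSON (YAML also accepted on read when the
# yaml package is available).

#' Read or write a protocol configuration file
#'
#' @param config a [pvt_protocol()] object.
#' @param path file path; `.json` (always available) or `.yaml`/`.yml`
#'   (requires the yaml package).
#' @return `write_protocol` returns `path` invisibly; `read_protocol` returns
#'   a [pvt_protocol()] object.
#' @export
write_protocol <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML output")
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML input")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$session_times_by_day <- lapply(x$session_times_by_day, as.numeric)
  do.call(pvt_protocol, c(
    x[c("session_times_by_day", "session_duration", "isi_range",
        "trait_correlation", "invalid_session_rate", "false_start_rate",
        "wrong_button_rate", "rt_cap", "seed")],
    list(traits = x$traits)
  ))
}
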
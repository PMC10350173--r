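#' Configuration for the synthetic photometry generator
#'
#' Two-channel fluorescence time series at a fixed sampling rate (default
#' 40 Hz, matching typical frame-synchronised acquisition): a signal channel
#' (470 nm, calcium-dependent) carrying event-locked transients on a
#' photobleaching baseline, and a control channel (415 nm, isosbestic) with
#' the same bleaching dynamics but no transients. Bleaching is a single
#' exponential; transients are a difference of exponentials (fast rise, slow
#' decay) peak-normalised to `transient_amplitude`.
#'
#' @param duration_s recording length in seconds.
#' @param rate_hz sampling rate, Hz.
#' @param baseline_level raw fluorescence baseline of the signal channel
#'   (arbitrary units).
#' @param control_scale ratio of control-channel to signal-channel baseline
#'   (autofluorescence is typically dimmer than GCaMP baseline; default 0.8).
#'   With `control_scale = 1` the channels are identical in the noiseless,
#'   transient-free case.
#' @param baseline_drift photobleaching time constant in seconds (larger =
#'   slower bleach); `Inf` disables bleaching.
#' @param transient_amplitude transient peak in dF/F units relative to the
#'   control-subtracted baseline.
#' @param transient_tau_rise_s,transient_tau_decay_s kernel time constants
#'   (seconds); rise must be strictly smaller than decay.
#' @param event_times_s onsets (seconds) at which transients are injected;
#'   all must lie in `[0, duration_s)`.
#' @param noise_sd additive white noise SD, raw units, per channel.
#' @param baseline_window_s length-2 numeric `(start, end)` of the
#'   pre-stimulus baseline period (default first 120 s).
#' @param seed integer RNG seed.
#' @return An object of class `photom_sim_config`.
#' @export
photom_sim_config <- function(duration_s = 420, rate_hz = 40,
                              baseline_level = 100, control_scale = 0.8,
                              baseline_drift = 600,
                              transient_amplitude = 2,
                              transient_tau_rise_s = 0.2,
                              transient_tau_decay_s = 1.5,
                              event_times_s = numeric(),
                              noise_sd = 0.5,
                              baseline_window_s = c(0, 120),
                              seed = 1L) {
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(rate_hz, "rate_hz")
  stopifnot_scalar_pos(baseline_level, "baseline_level")
  stopifnot_scalar_pos(transient_tau_rise_s, "transient_tau_rise_s")
  stopifnot_scalar_pos(transient_tau_decay_s, "transient_tau_decay_s")
  if (transient_tau_rise_s >= transient_tau_decay_s)
    stop("transient rise time constant must be smaller than decay")
  if (control_scale <= 0 || control_scale > 1)
    stop("`control_scale` must be in (0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (length(event_times_s) &&
      (any(event_times_s < 0) || any(event_times_s >= duration_s)))
    stop("all event times must lie in [0, duration_s)")
  structure(
    list(duration_s = duration_s, rate_hz = rate_hz,
         baseline_level = baseline_level, control_scale = control_scale,
         baseline_drift = baseline_drift,
         transient_amplitude = transient_amplitude,
         transient_tau_rise_s = transient_tau_rise_s,
         transient_tau_decay_s = transient_tau_decay_s,
         event_times_s = as.numeric(event_times_s),
         noise_sd = noise_sd,
         baseline_window_s = as.numeric(baseline_window_s),
         seed = as.integer(seed)),
    class = "photom_sim_config")
}

# Difference-of-exponentials kernel, peak-normalised to 1 at
# t* = log(tau_d/tau_r) * tau_r*tau_d / (tau_d - tau_r).
transient_kernel <- function(t, tau_rise, tau_decay) {
  h <- ifelse(t < 0, 0, exp(-t / tau_decay) - exp(-t / tau_rise))
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  h / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

#' Simulate a two-channel photometry session
#'
#' The signal channel is `baseline_level * bleach(t) + transients + noise`;
#' the control channel is `control_scale * baseline_level * bleach(t)` plus
#' independent noise and carries no transients. Transient absolute amplitude
#' is `transient_amplitude` times the control-subtracted baseline
#' `(1 - control_scale) * baseline_level`, so a noiseless processed trace has
#' dF/F peaks near the configured amplitude early in the session.
#'
#' @param config a [photom_sim_config()].
#' @param events optional data.frame (`label`, `start_s`, `stop_s`) of
#'   behavioural bout annotations to carry in the session; defaults to one
#'   `"event"` bout of 1 s at each transient onset.
#' @return A [photometry_session()] with attribute `config`.
#' @export
simulate_photometry <- function(config, events = NULL) {
  stopifnot(inherits(config, "photom_sim_config"))
  n <- floor(config$duration_s * config$rate_hz)
  t <- (seq_len(n) - 1) / config$rate_hz
  bleach <- if (is.finite(config$baseline_drift))
    exp(-t / config$baseline_drift) else rep(1, n)
  base_sig <- config$baseline_level * bleach
  base_ctl <- config$control_scale * config$baseline_level * bleach

  amp_abs <- config$transient_amplitude *
    (1 - config$control_scale) * config$baseline_level
  transients <- rep(0, n)
  for (ev in config$event_times_s)
    transients <- transients + amp_abs *
      transient_kernel(t - ev, config$transient_tau_rise_s,
                       config$transient_tau_decay_s)

  noise <- with_seed(config$seed, {
    list(sig = stats::rnorm(n, 0, config$noise_sd),
         ctl = stats::rnorm(n, 0, config$noise_sd))
  })

  if (is.null(events)) {
    events <- if (length(config$event_times_s))
      data.frame(label = "event",
                 start_s = config$event_times_s,
                 stop_s = config$event_times_s + 1,
                 stringsAsFactors = FALSE)
    else data.frame(label = character(), start_s = numeric(),
                    stop_s = numeric(), stringsAsFactors = FALSE)
  }

  out <- photometry_session(
    time_s = t,
    signal = base_sig + transients + noise$sig,
    control = base_ctl + noise$ctl,
    rate_hz = config$rate_hz,
    baseline_window_s = config$baseline_window_s,
    events = events)
  attr(out, "config") <- config
  out
}

#' Write a photometry session to delimited text
#'
#' The trace goes to a three-column (`time_s`, `signal`, `control`)
#' tab-separated file; events to a (`label`, `start_s`, `stop_s`) table.
#'
#' @param session a [photometry_session()].
#' @param trace_file,events_file output paths.
#' @return Invisibly, `session`.
#' @export
write_photometry_session <- function(session, trace_file, events_file) {
  stopifnot(inherits(session, "photometry_session"))
  utils::write.table(
    data.frame(time_s = session$time_s, signal = session$signal,
               control = session$control),
    trace_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(session$events, events_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(session)
}

#' Read a photometry session from delimited text
#'
#' @param trace_file,events_file paths written by
#'   [write_photometry_session()].
#' @param rate_hz sampling rate; inferred from the time column when NULL.
#' @param baseline_window_s baseline interval `(start, end)` in seconds.
#' @return A [photometry_session()].
#' @export
read_photometry_session <- function(trace_file, events_file,
                                    rate_hz = NULL,
                                    baseline_window_s = c(0, 120)) {
  tr <- utils::read.delim(trace_file)
  ev <- utils::read.delim(events_file, stringsAsFactors = FALSE)
  rate_hz <- rate_hz %||% (1 / stats::median(diff(tr$time_s)))
  photometry_session(tr$time_s, tr$signal, tr$control, rate_hz,
                     baseline_window_s, ev)
}
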
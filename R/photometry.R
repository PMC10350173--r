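#' Two-channel fibre photometry session
#'
#' Container for a recording with a calcium-dependent signal channel
#' (470 nm) and an isosbestic control channel (415 nm) sampled at a fixed
#' rate, a pre-stimulus baseline window, and behavioural bout annotations.
#'
#' @param time_s monotone time vector, seconds.
#' @param signal,control fluorescence vectors, same length as `time_s`.
#' @param rate_hz sampling rate; must match the time spacing within 1%.
#' @param baseline_window_s length-2 `(start, end)` of the baseline period;
#'   must precede the first annotated event.
#' @param events data.frame with `label`, `start_s`, `stop_s` columns (may
#'   be empty).
#' @return Object of class `photometry_session`.
#' @export
photometry_session <- function(time_s, signal, control, rate_hz,
                               baseline_window_s, events) {
  n <- length(time_s)
  if (length(signal) != n || length(control) != n)
    stop("signal, control and time vectors must have equal length")
  if (is.unsorted(time_s, strictly = TRUE)) stop("time must be increasing")
  dt <- stats::median(diff(time_s))
  if (abs(dt - 1 / rate_hz) > 0.01 / rate_hz)
    stop("`rate_hz` inconsistent with time spacing (> 1% off)")
  baseline_window_s <- as.numeric(baseline_window_s)
  if (length(baseline_window_s) != 2 ||
      baseline_window_s[2] <= baseline_window_s[1])
    stop("`baseline_window_s` must be an increasing (start, end) pair")
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("label", "start_s", "stop_s")
  if (!all(req %in% names(events)))
    stop("`events` must have label, start_s, stop_s columns")
  if (nrow(events)) {
    events <- events[order(events$start_s), req, drop = FALSE]
    rownames(events) <- NULL
    if (min(events$start_s) < baseline_window_s[2])
      warning("first event starts inside the baseline window")
  }
  structure(
    list(time_s = as.numeric(time_s), signal = as.numeric(signal),
         control = as.numeric(control), rate_hz = rate_hz,
         baseline_window_s = baseline_window_s, events = events),
    class = "photometry_session")
}

#' Preprocess a photometry session to a z-scored dF/F trace
#'
#' The control channel is subtracted from the signal channel (eliminating
#' autofluorescence, bleaching and motion components); F0 is the mean of the
#' corrected trace over the final `baseline_s` seconds of the baseline
#' window; dF/F = (corrected - F0) / F0; the result is z-scored by
#' subtracting its mean and dividing by its standard deviation, by default
#' over the whole session (`zscore_scope = "baseline"` restricts the
#' normalising statistics to the baseline window). `control_fit = "regress"`
#' replaces the raw subtraction by subtraction of the control linearly
#' rescaled onto the signal (least squares), a common robustness variant.
#'
#' @param session a [photometry_session()].
#' @param baseline_s seconds at the end of the baseline window used for F0
#'   (default 60; at least 60 s of baseline must be available).
#' @param zscore_scope `"session"` (default) or `"baseline"`.
#' @param control_fit `"subtract"` (default, literal channel difference) or
#'   `"regress"`.
#' @return Object of class `processed_trace`: list with `time_s`, `z`
#'   (z-scored dF/F), `dff`, `rate_hz`, `events`, `f0`.
#' @export
preprocess <- function(session, baseline_s = 60,
                       zscore_scope = c("session", "baseline"),
                       control_fit = c("subtract", "regress")) {
  stopifnot(inherits(session, "photometry_session"))
  zscore_scope <- match.arg(zscore_scope)
  control_fit <- match.arg(control_fit)
  bw <- session$baseline_window_s
  if (diff(bw) < baseline_s)
    stop(sprintf("baseline window shorter than %g s", baseline_s))
  corrected <- if (control_fit == "subtract") {
    session$signal - session$control
  } else {
    fit <- stats::lm(session$signal ~ session$control)
    session$signal - stats::fitted(fit) + mean(session$signal)
  }
  in_f0 <- session$time_s >= bw[2] - baseline_s & session$time_s < bw[2]
  if (!any(in_f0)) stop("no samples in the F0 window")
  f0 <- mean(corrected[in_f0])
  if (f0 <= 0)
    stop("baseline fluorescence F0 is not positive; cannot form dF/F")
  dff <- (corrected - f0) / f0
  scope <- if (zscore_scope == "session") rep(TRUE, length(dff))
           else session$time_s >= bw[1] & session$time_s < bw[2]
  s <- stats::sd(dff[scope])
  if (s == 0) stop("dF/F has zero variance; z-score undefined")
  structure(
    list(time_s = session$time_s,
         z = (dff - mean(dff[scope])) / s,
         dff = dff, rate_hz = session$rate_hz,
         events = session$events, f0 = f0),
    class = "processed_trace")
}

#' Classify behavioural bouts by their temporal context
#'
#' Investigation bouts are labelled `investigation_preceding_attack` when an
#' attack bout starts within `gap_s` seconds after the investigation ends,
#' else `investigation_isolated`. Attack bouts are labelled
#' `attack_with_prior_investigation` when an investigation ends within
#' `gap_s` seconds before (or overlaps) the attack onset, else
#' `attack_without_prior_investigation`. The session-level label
#' (`"attack_day"` / `"no_attack_day"`) records whether any attack occurred.
#' Other labels pass through with `bout_class` equal to their label.
#'
#' @param events data.frame (`label`, `start_s`, `stop_s`), time-ordered;
#'   bouts sharing a label must not overlap.
#' @param gap_s maximum investigation-to-attack gap in seconds (default 2).
#' @param investigation_label,attack_label the labels carrying the taxonomy.
#' @return The events with an added `bout_class` column and attribute
#'   `session_class`.
#' @export
classify_bouts <- function(events, gap_s = 2,
                           investigation_label = "investigation",
                           attack_label = "attack") {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events)) {
    events <- events[order(events$start_s), , drop = FALSE]
    rownames(events) <- NULL
    for (lab in unique(events$label)) {
      e <- events[events$label == lab, ]
      if (nrow(e) > 1 && any(e$start_s[-1] < e$stop_s[-nrow(e)]))
        stop(sprintf("overlapping `%s` bouts", lab))
    }
  }
  inv <- events$label == investigation_label
  atk <- events$label == attack_label
  cls <- events$label
  atk_starts <- events$start_s[atk]
  inv_ends <- events$stop_s[inv]
  if (any(inv)) {
    precedes <- vapply(events$stop_s[inv], function(e)
      any(atk_starts >= e & atk_starts <= e + gap_s), TRUE)
    cls[inv] <- ifelse(precedes, "investigation_preceding_attack",
                       "investigation_isolated")
  }
  if (any(atk)) {
    preceded <- vapply(events$start_s[atk], function(s)
      any(inv_ends >= s - gap_s & inv_ends <= s + gap_s), TRUE)
    cls[atk] <- ifelse(preceded, "attack_with_prior_investigation",
                       "attack_without_prior_investigation")
  }
  events$bout_class <- cls
  attr(events, "session_class") <- if (any(atk)) "attack_day" else "no_attack_day"
  attr(events, "gap_s") <- gap_s
  events
}

#' Peri-event extraction
#'
#' Cuts the processed trace into trials aligned to bout onsets: each row
#' spans `window_s[1]` seconds before to `window_s[2]` seconds after the
#' event start, with the onset at sample index `round(pre * rate) + 1`.
#' Events whose window exceeds the recording are excluded and counted.
#' One `peri_event_set` is returned per bout class.
#'
#' @param trace a `processed_trace` from [preprocess()].
#' @param events labelled events from [classify_bouts()] (any data.frame
#'   with `start_s` and `bout_class` or `label`).
#' @param window_s length-2 `(pre, post)` seconds (default `c(4, 4)`; odour
#'   analyses conventionally use `c(2, 2)`).
#' @return Named list of `peri_event_set` objects (one per class), each a
#'   list with `matrix` (trials x timepoints), `window_s`, `event_class`,
#'   `alignment` (onset column), `onsets_s`, `n_excluded`. Classes whose
#'   every trial is excluded yield an empty-matrix set, not an error.
#' @export
peri_event <- function(trace, events, window_s = c(4, 4)) {
  stopifnot(inherits(trace, "processed_trace"))
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  cls_col <- if ("bout_class" %in% names(events)) "bout_class" else "label"
  pre_n <- round(window_s[1] * trace$rate_hz)
  post_n <- round(window_s[2] * trace$rate_hz)
  if (pre_n + post_n < 2) stop("window too small for the sampling rate")
  n <- length(trace$z)
  out <- list()
  for (cl in unique(events[[cls_col]])) {
    starts <- events$start_s[events[[cls_col]] == cl]
    idx <- vapply(starts, function(s) which.min(abs(trace$time_s - s)), 1L)
    usable <- idx - pre_n >= 1 & idx + post_n - 1 <= n
    rows <- t(vapply(idx[usable], function(i)
      trace$z[(i - pre_n):(i + post_n - 1)], numeric(pre_n + post_n)))
    if (!sum(usable)) rows <- matrix(numeric(0), 0, pre_n + post_n)
    out[[cl]] <- structure(
      list(matrix = rows, window_s = as.numeric(window_s),
           event_class = cl, alignment = pre_n + 1L,
           onsets_s = starts[usable], n_excluded = sum(!usable)),
      class = "peri_event_set")
  }
  out
}

#' Pre/post event activity summaries
#'
#' Per trial, the mean z-scored dF/F over the pre-onset and post-onset
#' halves of the window; per class, the mean paired difference and a
#' Wilcoxon signed-rank test (descriptive only for single-trial classes).
#'
#' @param periset a `peri_event_set`.
#' @return List with `per_trial` (data.frame `pre_mean`, `post_mean`,
#'   `diff`), `mean_diff`, `p` (NA when untestable), `n_trials`.
#' @export
pre_post_stats <- function(periset) {
  stopifnot(inherits(periset, "peri_event_set"))
  m <- periset$matrix
  if (!nrow(m))
    return(list(per_trial = data.frame(pre_mean = numeric(),
                                       post_mean = numeric(),
                                       diff = numeric()),
                mean_diff = NA_real_, p = NA_real_, n_trials = 0L))
  a <- periset$alignment
  pre <- rowMeans(m[, seq_len(a - 1L), drop = FALSE])
  post <- rowMeans(m[, a:ncol(m), drop = FALSE])
  d <- post - pre
  p <- if (nrow(m) >= 2 && any(d != 0))
    stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE)$p.value
  else NA_real_
  list(per_trial = data.frame(pre_mean = pre, post_mean = post, diff = d),
       mean_diff = mean(d), p = p, n_trials = nrow(m))
}

#' Compare post-pre responses between two peri-event classes
#'
#' Rank-sum comparison of the per-trial post minus pre differences of two
#' classes (e.g. investigation preceding attack vs in isolation).
#'
#' @param set_a,set_b `peri_event_set` objects.
#' @return List with `mean_diff_a`, `mean_diff_b`, `p` (Wilcoxon rank-sum;
#'   NA when a class has < 2 trials).
#' @export
compare_classes <- function(set_a, set_b) {
  sa <- pre_post_stats(set_a); sb <- pre_post_stats(set_b)
  da <- sa$per_trial$diff; db <- sb$per_trial$diff
  p <- if (length(da) >= 2 && length(db) >= 2)
    stats::wilcox.test(da, db, exact = FALSE)$p.value else NA_real_
  list(mean_diff_a = sa$mean_diff, mean_diff_b = sb$mean_diff, p = p,
       n_a = sa$n_trials, n_b = sb$n_trials)
}
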
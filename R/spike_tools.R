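#' Analysis window specification
#'
#' @param name window label.
#' @param start,end window bounds in ms relative to the alignment event;
#'   windows are half-open `[start, end)`.
#' @param alignment `"target_on"`, `"saccade_on"` or `"fixation_on"`.
#' @return list of class `window_spec`.
#' @export
window_spec <- function(name, start, end, alignment = "target_on") {
  if (start >= end) stop("window start must be < end")
  structure(list(name = name, start = start, end = end, alignment = alignment),
            class = "window_spec")
}

#' Align a unit's spikes on a trial event
#'
#' Converts session-clock spike times to times relative to the chosen event,
#' one row per included trial. Trials whose saccade was rejected (blink,
#' off-target, anticipatory, no-response) are excluded.
#'
#' @param unit list with `unit_id` and `spike_ms` (session clock, ms).
#' @param trials session trial table (needs `trial_id`, `condition`,
#'   `target_on_ms`, `fix_on_ms`).
#' @param saccades per-trial saccade table from [session_saccades()].
#' @param event_name `"target_on"`, `"saccade_on"` or `"fixation_on"`.
#' @param span analysis span in ms relative to the event (spikes outside are
#'   dropped), default `c(-400, 400)`.
#' @return object of class `aligned_raster`: list with `unit_id`,
#'   `event_name`, `span`, `trials` (data.frame with `trial_id`, `condition`,
#'   `rt_ms`, `pv_deg_s`, `event_ms`) and `spikes` (list of per-trial
#'   relative spike-time vectors, trial order preserved).
#' @export
align_spikes <- function(unit, trials, saccades, event_name = "target_on",
                         span = c(-400, 400)) {
  if (!event_name %in% c("target_on", "saccade_on", "fixation_on"))
    stop("argument error: unknown event name '", event_name, "'")
  keep <- saccades$valid
  trials <- trials[keep, , drop = FALSE]
  saccades <- saccades[keep, , drop = FALSE]
  event_ms <- switch(event_name,
    target_on = trials$target_on_ms,
    saccade_on = saccades$onset_ms,
    fixation_on = trials$fix_on_ms
  )
  sp <- sort(unit$spike_ms)
  rel <- lapply(event_ms, function(e) {
    s <- sp[sp >= e + span[1] & sp < e + span[2]] - e
    as.numeric(s)
  })
  structure(list(
    unit_id = unit$unit_id,
    event_name = event_name,
    span = span,
    trials = data.frame(trial_id = trials$trial_id,
                        condition = trials$condition,
                        rt_ms = saccades$rt_ms,
                        pv_deg_s = saccades$pv_deg_s,
                        event_ms = event_ms,
                        stringsAsFactors = FALSE),
    spikes = rel
  ), class = "aligned_raster")
}

#' Spike density function (Gaussian kernel, 10 ms bandwidth)
#'
#' Every spike contributes a unit-mass Gaussian with SD = `bandwidth_ms`
#' ("bandwidth" is the kernel SD, not FWHM). Values are in spikes/s on a 1 ms
#' grid; the estimate is computed on a span padded by 6 SD and cropped, so a
#' trial's integral over the span equals its interior spike count to within
#' 1e-6 (spikes at least ~5 SD inside the span edges).
#'
#' @param raster an [align_spikes()] raster.
#' @param bandwidth_ms Gaussian kernel SD in ms (default 10).
#' @param span time span of the returned grid; defaults to the raster span.
#' @return list of class `sdf_matrix`: `time` (ms grid), `values`
#'   (trials x time matrix, spikes/s), `bandwidth_ms`, `trials` (the raster's
#'   trial table).
#' @export
sdf <- function(raster, bandwidth_ms = 10, span = raster$span) {
  if (bandwidth_ms <= 0) stop("argument error: bandwidth must be positive")
  time <- seq(span[1], span[2], by = 1)
  n_trials <- length(raster$spikes)
  values <- matrix(0, nrow = n_trials, ncol = length(time))
  all_sp <- unlist(raster$spikes)
  if (length(all_sp)) {
    trial_of <- rep.int(seq_len(n_trials),
                        vapply(raster$spikes, length, integer(1)))
    # keep spikes whose kernel mass reaches the span (6 SD support)
    inside <- all_sp >= span[1] - 6 * bandwidth_ms &
      all_sp <= span[2] + 6 * bandwidth_ms
    all_sp <- all_sp[inside]
    trial_of <- trial_of[inside]
    if (length(all_sp)) {
      d <- outer(all_sp, time, "-")
      k <- exp(-d^2 / (2 * bandwidth_ms^2)) * (1000 / (bandwidth_ms * sqrt(2 * pi)))
      values <- rowsum(k, group = trial_of, reorder = FALSE)
      full <- matrix(0, nrow = n_trials, ncol = length(time))
      full[unique(trial_of), ] <- values
      values <- full
    }
  }
  structure(list(time = time, values = values, bandwidth_ms = bandwidth_ms,
                 trials = raster$trials), class = "sdf_matrix")
}

#' Per-trial firing rate in an analysis window
#'
#' Counts spikes in the half-open window `[start, end)` and divides by the
#' window duration.
#'
#' @param raster an [align_spikes()] raster whose alignment matches
#'   `window$alignment`.
#' @param window a [window_spec()].
#' @return numeric vector, spikes/s per trial (raster trial order).
#' @export
window_rate <- function(raster, window) {
  if (length(raster$spikes) == 0) stop("empty trial set")
  if (window$start < raster$span[1] || window$end > raster$span[2])
    stop("window [", window$start, ", ", window$end,
         ") outside raster span [", raster$span[1], ", ", raster$span[2], ")")
  dur_s <- (window$end - window$start) / 1000
  vapply(raster$spikes,
         function(s) sum(s >= window$start & s < window$end) / dur_s,
         numeric(1))
}

#' Per-trial spike count in a window
#' @inheritParams window_rate
#' @return integer vector of counts per trial.
#' @export
window_count <- function(raster, window) {
  vapply(raster$spikes,
         function(s) sum(s >= window$start & s < window$end),
         numeric(1))
}

#' Unit inclusion filter
#'
#' A unit enters the analysis only if it has at least `min_trials` valid
#' trials in each task condition and fired strictly more than `min_spikes`
#' spikes within the analysis window (default -300 to +400 ms around target
#' onset).
#'
#' @param raster target-aligned [align_spikes()] raster of the unit.
#' @param min_trials minimum valid trials per condition (default 5).
#' @param min_spikes spike count that must be exceeded (default 20).
#' @param window analysis window for the spike count.
#' @return list with `pass` (logical) and `reason`
#'   (`"ok"`, `"too_few_trials"` or `"too_few_spikes"`).
#' @export
inclusion_filter <- function(raster, min_trials = 5, min_spikes = 20,
                             window = window_spec("analysis", -300, 400)) {
  n_by_cond <- table(factor(raster$trials$condition, c("good", "bad")))
  if (any(n_by_cond < min_trials))
    return(list(pass = FALSE, reason = "too_few_trials"))
  total <- sum(window_count(raster, window))
  if (total <= min_spikes)
    return(list(pass = FALSE, reason = "too_few_spikes"))
  list(pass = TRUE, reason = "ok")
}
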
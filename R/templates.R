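#' Subtype firing-rate templates
#'
#' A rate template parameterizes the trial-aligned firing-rate function
#' \eqn{\lambda(t)} of one functional SC subtype. Non-tonic units are a sum of
#' a baseline, a transient visual component (Gaussian bump peaking
#' `visual_peak_latency` ms after target onset), a late visual component (a
#' mixture of a Gaussian bump at `late_peak_latency` and a sustained plateau
#' that persists until after the saccade), and a saccade-locked motor burst
#' peaking `motor_peak_lead` ms before saccade onset. Tonic units instead start
#' from a high baseline that is suppressed after target onset, deepening to a
#' trough `tonic_trough_lead` ms before saccade onset and recovering after the
#' saccade.
#'
#' Default component timings follow the population values the analysis is
#' designed to recover: early visual peak at 42 ms, late visual peak near
#' 106 ms, pre-saccadic burst peaking 11 ms before saccade onset, tonic
#' baseline 22 spikes/s suppressed to 12 spikes/s with a trough 33 ms before
#' saccade onset.
#'
#' @param subtype one of `"visual"`, `"visuomotor"`, `"motor"`, `"tonic"`.
#' @param ... named overrides for individual template fields.
#'
#' @return An object of class `rate_template` (a named list). Fields:
#'   `baseline` (spikes/s), `visual_gain`, `visual_peak_latency`,
#'   `visual_width`, `late_gain`, `late_peak_latency`, `late_width`,
#'   `late_frac_bump` (share of the late component that is a discrete bump,
#'   the rest being a sustained plateau), `late_rise_center`,
#'   `late_rise_scale`, `motor_gain`, `motor_peak_lead`, `motor_rise_width`
#'   (burst rise SD), `motor_width` (burst decay SD),
#'   `tonic_suppression` (sustained drop, spikes/s), `tonic_trough_depth`
#'   (extra drop at the pre-saccadic trough), `tonic_onset_latency`,
#'   `tonic_trough_lead`, `tonic_trough_width`, `subtype`.
#' @seealso [rate_function()], [generator_params()]
#' @export
rate_template <- function(subtype = c("visual", "visuomotor", "motor", "tonic"),
                          ...) {
  subtype <- match.arg(subtype)
  tpl <- switch(subtype,
    visual = list(
      baseline = 8, visual_gain = 90, late_gain = 45,
      late_frac_bump = 0, late_rise_center = 65, motor_gain = 0,
      tonic_suppression = 0, tonic_trough_depth = 0
    ),
    visuomotor = list(
      baseline = 10, visual_gain = 70, late_gain = 50,
      late_frac_bump = 0.7, motor_gain = 160,
      tonic_suppression = 0, tonic_trough_depth = 0
    ),
    motor = list(
      baseline = 5, visual_gain = 2, late_gain = 60,
      late_peak_latency = 120, late_frac_bump = 1,
      motor_gain = 250, motor_width = 9,
      tonic_suppression = 0, tonic_trough_depth = 0
    ),
    tonic = list(
      baseline = 22, visual_gain = 0, late_gain = 0,
      late_frac_bump = 0, motor_gain = 0,
      tonic_suppression = 10, tonic_trough_depth = 8
    )
  )
  common <- list(
    visual_peak_latency = 42, visual_width = 12,
    late_peak_latency = 106, late_width = 15,
    late_rise_center = 55, late_rise_scale = 3,
    motor_peak_lead = 11, motor_rise_width = 6, motor_width = 8,
    tonic_onset_latency = 60, tonic_onset_scale = 8,
    tonic_trough_lead = 33, tonic_trough_width = 18,
    release_lead = 60, release_scale = 25
  )
  common[names(tpl)] <- tpl
  tpl <- c(common, list(subtype = subtype))
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(tpl))
    if (length(bad)) stop("unknown template field(s): ", paste(bad, collapse = ", "))
    tpl[names(dots)] <- dots
  }
  validate_rate_template(tpl)
  structure(tpl, class = "rate_template")
}

validate_rate_template <- function(tpl) {
  stopifnot(
    tpl$baseline >= 0,
    tpl$visual_gain >= 0, tpl$late_gain >= 0, tpl$motor_gain >= 0,
    tpl$visual_width > 0, tpl$late_width > 0, tpl$motor_width > 0,
    tpl$motor_rise_width > 0,
    tpl$late_frac_bump >= 0, tpl$late_frac_bump <= 1,
    tpl$tonic_suppression >= 0, tpl$tonic_trough_depth >= 0
  )
  if (identical(tpl$subtype, "visual") && tpl$motor_gain != 0)
    stop("visual subtype requires motor_gain = 0")
  if (identical(tpl$subtype, "tonic") &&
      (tpl$visual_gain != 0 || tpl$late_gain != 0 || tpl$motor_gain != 0 ||
       tpl$tonic_suppression <= 0))
    stop("tonic subtype requires zero gains and positive suppression")
  invisible(tpl)
}

#' Trial firing-rate function on a 1 ms grid
#'
#' Evaluates the template rate \eqn{\lambda(t)} for one trial, with time
#' relative to target onset. On good trials the value gain engages at
#' `params$value_onset` ms post-target and multiplies the late and motor
#' components (for tonic templates it divides the suppression, so a gain > 1
#' still means higher firing on good trials). A per-trial latent gain
#' `latent_gain` also scales the late/motor components; the generator shares
#' one draw per trial across simultaneously recorded units to induce the
#' rate-to-behavior coupling.
#'
#' @param template a [rate_template()].
#' @param condition `"good"` or `"bad"`.
#' @param rt saccade reaction time for this trial (ms, > 0).
#' @param params a [generator_params()] object (supplies `value_gain`,
#'   `value_onset`).
#' @param latent_gain per-trial multiplicative fluctuation of the late/motor
#'   components (default 1).
#' @param span time span in ms relative to target onset, default
#'   `c(-400, rt + 300)`.
#' @return list with `time` (1 ms grid) and `rate` (spikes/s, clipped at 0).
#' @export
rate_function <- function(template, condition = c("good", "bad"), rt, params,
                          latent_gain = 1, span = NULL) {
  condition <- match.arg(condition)
  stopifnot(inherits(template, "rate_template"), rt > 0)
  if (is.null(span)) span <- c(-400, ceiling(rt) + 300)
  t <- seq(span[1], span[2], by = 1)

  gain <- if (condition == "good") params$value_gain else 1
  # value multiplier engages at value_onset (good trials only)
  m <- 1 + (gain - 1) * (t >= params$value_onset)

  vis <- template$visual_gain *
    exp(-(t - template$visual_peak_latency)^2 / (2 * template$visual_width^2))

  # sustained part of the late component persists until released after the
  # saccade ends (release centered release_lead ms after saccade onset)
  release <- 1 - stats::plogis((t - (rt + template$release_lead)) /
                                 template$release_scale)
  late_bump <- exp(-(t - template$late_peak_latency)^2 / (2 * template$late_width^2))
  late_plateau <- stats::plogis((t - template$late_rise_center) /
                                  template$late_rise_scale) * release
  late <- template$late_gain *
    (template$late_frac_bump * late_bump +
       (1 - template$late_frac_bump) * late_plateau)

  # saccadic burst: sharp rise, slower decay (asymmetric Gaussian)
  tc <- rt - template$motor_peak_lead
  mw <- ifelse(t < tc, template$motor_rise_width, template$motor_width)
  mot <- template$motor_gain * exp(-(t - tc)^2 / (2 * mw^2))

  if (identical(template$subtype, "tonic")) {
    supp <- (template$tonic_suppression *
               stats::plogis((t - template$tonic_onset_latency) /
                               template$tonic_onset_scale) +
               template$tonic_trough_depth *
               exp(-(t - (rt - template$tonic_trough_lead))^2 /
                     (2 * template$tonic_trough_width^2))) * release
    rate <- template$baseline - supp * latent_gain / m
  } else {
    rate <- template$baseline + vis + latent_gain * m * (late + mot)
  }
  list(time = t, rate = pmax(rate, 0))
}

#' Synthetic-session generator parameters
#'
#' Bundles every knob of the synthetic-session generator. The defaults encode
#' the study conditions the analysis assumes: good/bad reaction times
#' 186 +/- 25 ms and 211 +/- 36 ms, target eccentricities 4-25 degrees, a
#' saturating main sequence calibrated so mean peak velocity is near
#' 740 deg/s, 56 good and 43 bad completed trials per session, and the
#' subtype templates of [rate_template()]. The value gain (default 1.5) is
#' the per-modulated-unit good/bad rate ratio on late and pre-saccadic
#' components; mixing it over the per-subtype modulation-sign proportions
#' yields population-level ratios near 1.2-1.5.
#'
#' The rate-to-behavior coupling is a shared per-trial latent gain
#' `g ~ Normal(1, latent_sd)` multiplying late/motor components of all units,
#' while the trial RT is shifted by `-rate_rt_coupling * (g - 1) * rt_sd`:
#' trials where the population fires harder have shorter latencies.
#'
#' @param ... named overrides of any default field.
#' @return object of class `generator_params`.
#' @export
generator_params <- function(...) {
  p <- list(
    rt_mean_good = 186, rt_sd_good = 25,
    rt_mean_bad = 211, rt_sd_bad = 36,
    rt_floor = 150,
    amp_range = c(4, 25),
    amp_jitter = 0.03,
    main_seq_vmax = 870, main_seq_const = 8,
    pv_value_bonus = 0.05,
    eye_noise_sd = 0.005,
    n_units_per_subtype = 6,
    subtypes = c("visual", "visuomotor", "motor", "tonic"),
    subtype_templates = NULL,
    # per-subtype probabilities of positive / negative / absent value sign
    sign_probs = list(
      visual = c(0.53, 0.23, 0.24),
      visuomotor = c(0.70, 0.12, 0.18),
      motor = c(0.75, 0.04, 0.21),
      tonic = c(0.38, 0.43, 0.19)
    ),
    value_gain = 1.5,
    value_onset = 95,
    rate_rt_coupling = 2,
    latent_sd = 0.15,
    unit_gain_jitter = 0.25,
    n_trials_good = 56, n_trials_bad = 43,
    fix_duration = 300, fix_jitter = 100,
    hold_duration = 500, intertrial_gap = 600,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown generator field(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  if (is.null(p$subtype_templates)) {
    p$subtype_templates <- lapply(p$subtypes, rate_template)
    names(p$subtype_templates) <- p$subtypes
  }
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  if (p$rt_sd_good <= 0 || p$rt_sd_bad <= 0) stop("RT standard deviations must be > 0")
  if (p$rt_floor <= 0) stop("rt_floor must be > 0")
  if (p$amp_range[1] >= p$amp_range[2]) stop("amp_range must satisfy min < max")
  if (p$n_trials_good <= 0 || p$n_trials_bad <= 0)
    stop("configuration error: trial counts must be positive")
  if (p$n_units_per_subtype <= 0)
    stop("configuration error: n_units_per_subtype must be positive")
  if (!all(p$subtypes %in% c("visual", "visuomotor", "motor", "tonic")))
    stop("unknown subtype in `subtypes`")
  if (p$value_gain <= 0) stop("value_gain must be positive")
  invisible(p)
}
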
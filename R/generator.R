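#' Sample an inhomogeneous Poisson spike train by thinning
#'
#' Draws spike times from the rate function `rate` (1 ms grid, spikes/s) by
#' thinning a homogeneous Poisson process at the envelope rate
#' `max(rate$rate)`; candidate times are accepted with probability
#' \eqn{\lambda(t)/\lambda_{max}} with \eqn{\lambda} linearly interpolated
#' between grid points. Exact for bounded rates.
#'
#' @param rate list with `time` (ms, 1 ms grid) and `rate` (spikes/s), as
#'   returned by [rate_function()].
#' @return numeric vector of strictly increasing spike times (ms, same clock
#'   as `rate$time`). Uses the current R RNG stream; seed with [set.seed()].
#' @export
sample_spike_train <- function(rate) {
  lam <- rate$rate
  if (any(!is.finite(lam))) stop("unbounded rate")
  if (any(lam < 0)) stop("rate must be non-negative")
  lmax <- max(lam)
  if (lmax == 0) return(numeric(0))
  t0 <- rate$time[1]
  t1 <- rate$time[length(rate$time)]
  n_cand <- stats::rpois(1, lmax * (t1 - t0) / 1000)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, t0, t1))
  lam_at <- stats::approx(rate$time, lam, xout = cand)$y
  keep <- stats::runif(n_cand) < lam_at / lmax
  cand[keep]
}

## minimum-jerk displacement fraction s(tau), tau in [0, 1]
mj_frac <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

## saccade duration (ms) so that the minimum-jerk peak velocity equals pv
mj_duration <- function(amp, pv) 1875 * amp / pv

## lead time (ms) from movement start to the first crossing of `thr` deg/s:
## the minimum-jerk speed is pv * 16 tau^2 (1 - tau)^2, so the crossing
## fraction solves tau (1 - tau) = sqrt(thr / (16 pv)). Reaction times are
## defined operationally at the 30 deg/s crossing, so the generator starts
## the movement this much before the nominal RT.
mj_onset_delay <- function(pv, dur, thr = 30) {
  s <- sqrt(thr / (16 * pv))
  tau <- (1 - sqrt(pmax(1 - 4 * s, 0))) / 2
  tau * dur
}

#' Sample saccade behavior for one trial
#'
#' Draws reaction time, amplitude and peak velocity for one trial and builds
#' the corresponding eye-position segment. The amplitude is the session
#' eccentricity (targets sit at the recorded units' receptive field) with a
#' small per-trial jitter; peak velocity follows the saturating main sequence
#' \deqn{PV = V_{max}\,(1 - e^{-A/C})\,(1 + b\,[good])}
#' with a small value bonus `b` on good trials. The eye segment is a
#' minimum-jerk displacement whose analytic peak velocity equals `pv`, so its
#' speed crosses a 30 deg/s threshold exactly once on the way up and once on
#' the way down.
#'
#' @param params [generator_params()].
#' @param condition `"good"` or `"bad"`.
#' @param eccentricity target eccentricity in degrees; drawn uniformly from
#'   `params$amp_range` when `NULL`.
#' @param angle saccade direction (radians, default 0 = rightward).
#' @param latent_gain shared per-trial latent gain (couples rates to RT).
#' @param noise_sd positional noise SD for the returned segment (deg;
#'   default 0 gives the noise-free profile).
#' @return list with `rt` (ms), `amplitude` (deg), `pv` (deg/s), `duration`
#'   (ms) and `eye`, a data.frame `t_ms` (relative to target onset), `x_deg`,
#'   `y_deg` spanning -200 ms to 200 ms past the saccade end.
#' @export
sample_behavior <- function(params, condition = c("good", "bad"),
                            eccentricity = NULL, angle = 0,
                            latent_gain = 1, noise_sd = 0) {
  condition <- match.arg(condition)
  if (is.null(eccentricity))
    eccentricity <- stats::runif(1, params$amp_range[1], params$amp_range[2])
  amp <- eccentricity * (1 + stats::rnorm(1, 0, params$amp_jitter))
  amp <- max(amp, 0.5)
  pv <- params$main_seq_vmax * (1 - exp(-amp / params$main_seq_const))
  if (condition == "good") pv <- pv * (1 + params$pv_value_bonus)
  rt <- draw_rt(params, condition, latent_gain)
  dur <- mj_duration(amp, pv)
  start <- rt - mj_onset_delay(pv, dur)

  t <- seq(-200, ceiling(rt + dur + 200), by = 1)
  disp <- amp * mj_frac((t - start) / dur)
  x <- disp * cos(angle)
  y <- disp * sin(angle)
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(t), 0, noise_sd)
    y <- y + stats::rnorm(length(t), 0, noise_sd)
  }
  list(rt = rt, amplitude = amp, pv = pv, duration = dur,
       eye = data.frame(t_ms = t, x_deg = x, y_deg = y))
}

## truncated-normal RT draw shifted by the latent-gain coupling; the floor
## is enforced by rejection on the final RT so the distribution has no atom
## at the truncation point
draw_rt <- function(params, condition, latent_gain = 1) {
  mu <- if (condition == "good") params$rt_mean_good else params$rt_mean_bad
  sd <- if (condition == "good") params$rt_sd_good else params$rt_sd_bad
  shift <- params$rate_rt_coupling * (latent_gain - 1) * sd
  for (i in 1:1000) {
    rt <- stats::rnorm(1, mu, sd) - shift
    if (rt >= params$rt_floor) return(rt)
  }
  params$rt_floor
}

#' Generate a synthetic recording session
#'
#' Builds a complete session bundle: a trial event table (fixation onset,
#' target onset, good/bad condition, target position, object id), per-unit
#' spike trains drawn by [sample_spike_train()] from the subtype rate
#' templates, and a continuous 1 kHz eye trace containing one target-directed
#' saccade per trial (plus the return saccade to fixation). Ground truth
#' (per-unit subtype, modulation sign and effective value gain; per-trial RT,
#' amplitude, PV and latent gain; the full parameter set) is attached for
#' recovery tests.
#'
#' All trials are completed single-object trials; the monkey fixates for at
#' least 300 ms before target onset. One latent gain per trial is shared by
#' all units and couples population rate to RT (see [generator_params()]).
#' Identical `params` (including `seed`) give a bit-identical bundle.
#'
#' @param params [generator_params()].
#' @return object of class `sc_session`: list with `manifest`, `trials`
#'   (data.frame), `units` (list of `unit_id`, `channel`, `spike_ms`), `eye`
#'   (data.frame `t_ms`, `x_deg`, `y_deg`) and `truth`.
#' @export
generate_session <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)

  n_good <- params$n_trials_good
  n_bad <- params$n_trials_bad
  n_trials <- n_good + n_bad
  condition <- sample(c(rep("good", n_good), rep("bad", n_bad)))

  ecc <- stats::runif(1, params$amp_range[1], params$amp_range[2])
  angle <- stats::runif(1, 0, 2 * pi)
  target_x <- ecc * cos(angle)
  target_y <- ecc * sin(angle)

  ## per-trial behavior
  g <- pmax(stats::rnorm(n_trials, 1, params$latent_sd), 0.2)
  beh <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    beh[[i]] <- sample_behavior(params, condition[i], eccentricity = ecc,
                                angle = angle, latent_gain = g[i])
  }
  rt <- vapply(beh, `[[`, numeric(1), "rt")
  amp <- vapply(beh, `[[`, numeric(1), "amplitude")
  pv <- vapply(beh, `[[`, numeric(1), "pv")
  dur <- vapply(beh, `[[`, numeric(1), "duration")
  object_id <- ifelse(condition == "good",
                      sample(1:4, n_trials, replace = TRUE),
                      sample(5:8, n_trials, replace = TRUE))

  ## trial timeline on one session clock (ms)
  fix_on <- numeric(n_trials)
  target_on <- numeric(n_trials)
  cursor <- 500
  for (i in seq_len(n_trials)) {
    fix_on[i] <- cursor
    target_on[i] <- fix_on[i] + params$fix_duration +
      stats::runif(1, 0, params$fix_jitter)
    sacc_end <- target_on[i] + rt[i] + dur[i]
    cursor <- sacc_end + params$hold_duration + 150 + dur[i] +
      params$intertrial_gap
  }
  session_end <- ceiling(cursor + 500)

  ## continuous eye trace: displacement toward the target per trial,
  ## return saccade after the hold period
  t_grid <- seq(0, session_end, by = 1)
  frac <- numeric(length(t_grid))
  delay <- mj_onset_delay(pv, dur)
  for (i in seq_len(n_trials)) {
    s0 <- target_on[i] + rt[i] - delay[i]
    r0 <- target_on[i] + rt[i] + dur[i] + params$hold_duration + 150
    i0 <- max(1L, floor(s0) - 1L)
    i1 <- min(length(t_grid), ceiling(r0 + dur[i]) + 2L)
    seg <- i0:i1
    ts <- t_grid[seg]
    frac[seg] <- mj_frac((ts - s0) / dur[i]) - mj_frac((ts - r0) / dur[i])
  }
  amp_of_trial <- stats::approx(
    x = c(0, target_on + rt - delay, session_end),
    y = c(amp[1], amp, amp[n_trials]),
    xout = t_grid, method = "constant", rule = 2
  )$y
  disp <- frac * amp_of_trial
  eye <- data.frame(
    t_ms = t_grid,
    x_deg = disp * cos(angle) + stats::rnorm(length(t_grid), 0, params$eye_noise_sd),
    y_deg = disp * sin(angle) + stats::rnorm(length(t_grid), 0, params$eye_noise_sd)
  )

  ## units
  subtypes <- rep(params$subtypes, each = params$n_units_per_subtype)
  n_units <- length(subtypes)
  unit_id <- sprintf("u%03d", seq_len(n_units))
  sign <- character(n_units)
  unit_value_gain <- numeric(n_units)
  response_scale <- numeric(n_units)
  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    st <- subtypes[u]
    pr <- params$sign_probs[[st]]
    sign[u] <- sample(c("positive", "negative", "none"), 1, prob = pr)
    mag <- stats::runif(1, 1 - params$unit_gain_jitter, 1 + params$unit_gain_jitter)
    unit_value_gain[u] <- switch(sign[u],
      positive = 1 + (params$value_gain - 1) * mag,
      negative = 1 / (1 + (params$value_gain - 1) * mag),
      none = 1
    )
    response_scale[u] <- stats::runif(1, 0.8, 1.2)
    tpl <- params$subtype_templates[[st]]
    tpl$visual_gain <- tpl$visual_gain * response_scale[u]
    tpl$late_gain <- tpl$late_gain * response_scale[u]
    tpl$motor_gain <- tpl$motor_gain * response_scale[u]
    tpl$tonic_suppression <- tpl$tonic_suppression * response_scale[u]
    tpl$tonic_trough_depth <- tpl$tonic_trough_depth * response_scale[u]
    up <- params
    up$value_gain <- unit_value_gain[u]

    spikes <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      lam <- rate_function(tpl, condition[i], rt[i], up, latent_gain = g[i])
      spikes[[i]] <- sample_spike_train(lam) + target_on[i]
    }
    units[[u]] <- list(unit_id = unit_id[u], channel = u,
                       spike_ms = unlist(spikes))
  }

  trials <- data.frame(
    trial_id = seq_len(n_trials),
    condition = condition,
    fix_on_ms = fix_on,
    target_on_ms = target_on,
    target_x_deg = target_x,
    target_y_deg = target_y,
    object_id = object_id,
    outcome = "correct",
    stringsAsFactors = FALSE
  )

  truth <- list(
    units = data.frame(unit_id = unit_id, subtype = subtypes, sign = sign,
                       value_gain = unit_value_gain,
                       response_scale = response_scale,
                       stringsAsFactors = FALSE),
    trials = data.frame(trial_id = seq_len(n_trials), rt_ms = rt,
                        amplitude_deg = amp, pv_deg_s = pv,
                        duration_ms = dur, latent_gain = g),
    eccentricity = ecc, angle = angle,
    params = unclass(params),
    note = paste("Synthetic session. Template shapes and all generator",
                 "parameters are modeling choices of this package, not",
                 "measured quantities.")
  )

  structure(list(
    manifest = list(session_id = sprintf("syn%04d", params$seed %% 10000L),
                    sampling_rate_hz = 1000, subject = "SYN",
                    n_trials = n_trials, n_units = n_units,
                    synthetic = TRUE),
    trials = trials,
    units = units,
    eye = eye,
    truth = truth
  ), class = "sc_session")
}

#' @export
print.sc_session <- function(x, ...) {
  cat(sprintf("<sc_session %s: %d trials (%d good / %d bad), %d units, %.1f s eye trace>\n",
              x$manifest$session_id, nrow(x$trials),
              sum(x$trials$condition == "good"),
              sum(x$trials$condition == "bad"),
              length(x$units), nrow(x$eye) / 1000))
  invisible(x)
}
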
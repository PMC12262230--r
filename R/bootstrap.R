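#' Split trials into reaction-time tertiles
#'
#' Sorts trials by RT (stable, so ties keep their original order) and splits
#' them into short / medium / long groups at the empirical 1/3 and 2/3
#' quantiles; group sizes differ by at most one (remainders go to the
#' earlier groups).
#'
#' @param rts per-trial reaction times (ms), at least 3.
#' @return list of class `quantile_split`: `labels` (factor
#'   short/medium/long, trial order preserved), `boundaries` (the largest RT
#'   of the short and medium groups).
#' @export
split_quantiles <- function(rts) {
  n <- length(rts)
  if (n < 3) stop("need at least 3 trials to form tertiles")
  k <- n %/% 3
  rem <- n %% 3
  sizes <- c(short = k + (rem >= 1), medium = k + (rem == 2), long = k)
  ord <- order(rts)
  lab <- character(n)
  lab[ord] <- rep(c("short", "medium", "long"), times = sizes)
  labels <- factor(lab, levels = c("short", "medium", "long"))
  structure(list(
    labels = labels,
    boundaries = c(max(rts[labels == "short"]), max(rts[labels == "medium"])),
    sizes = sizes
  ), class = "quantile_split")
}

#' Pseudo-population SDF bank
#'
#' Precomputes per-trial spike density functions for a set of units on both
#' alignments (target onset and saccade onset), over common grids, so that
#' pseudo-trials can be pooled cheaply. All units come from one session and
#' therefore share the same valid trial set; row r of every unit's matrices
#' is the same behavioral trial.
#'
#' @param bundle `sc_session`.
#' @param saccades per-trial saccade table ([session_saccades()]).
#' @param unit_ids which units to include (default: all).
#' @param target_span,saccade_span SDF spans in ms relative to each event.
#' @param bandwidth_ms SDF kernel SD.
#' @return object of class `sdf_bank`: `target` / `saccade` (lists of
#'   trials x time matrices, one per unit), `target_time`, `saccade_time`,
#'   `trials` (shared valid-trial table with `rt_ms`, `condition`),
#'   `unit_ids`.
#' @export
pseudo_population <- function(bundle, saccades, unit_ids = NULL,
                              target_span = c(-300, 450),
                              saccade_span = c(-300, 150),
                              bandwidth_ms = 10) {
  if (is.null(unit_ids))
    unit_ids <- vapply(bundle$units, `[[`, character(1), "unit_id")
  units <- bundle$units[vapply(bundle$units, function(u)
    u$unit_id %in% unit_ids, logical(1))]
  tmat <- smat <- vector("list", length(units))
  trials <- NULL
  for (i in seq_along(units)) {
    rt <- align_spikes(units[[i]], bundle$trials, saccades, "target_on",
                       span = target_span + c(-60, 60))
    rs <- align_spikes(units[[i]], bundle$trials, saccades, "saccade_on",
                       span = saccade_span + c(-60, 60))
    st <- sdf(rt, bandwidth_ms, span = target_span)
    ss <- sdf(rs, bandwidth_ms, span = saccade_span)
    tmat[[i]] <- st$values
    smat[[i]] <- ss$values
    if (is.null(trials)) trials <- rt$trials
  }
  structure(list(
    target = tmat, saccade = smat,
    target_time = seq(target_span[1], target_span[2], by = 1),
    saccade_time = seq(saccade_span[1], saccade_span[2], by = 1),
    trials = trials,
    unit_ids = vapply(units, `[[`, character(1), "unit_id")
  ), class = "sdf_bank")
}

#' Simulate one pooled pseudo-trial
#'
#' Selects `n_pool` units uniformly with replacement and, from each, one
#' trial of the requested RT quantile uniformly at random; the pooled trace
#' is the mean of the selected single-trial SDFs. Units are sampled with
#' replacement because per-session subtype counts can be smaller than
#' `n_pool`.
#'
#' @param bank an [pseudo_population()] SDF bank (typically restricted to one
#'   functional subtype).
#' @param quantile `"short"`, `"medium"` or `"long"`.
#' @param split a [split_quantiles()] result for `bank$trials$rt_ms`
#'   (computed internally when `NULL`).
#' @param n_pool units per pseudo-trial (default 25).
#' @param alignment `"target"` or `"saccade"`.
#' @return numeric vector, pooled SDF trace on the bank's time grid.
#' @export
simulate_pseudo_trial <- function(bank, quantile, split = NULL, n_pool = 25,
                                  alignment = c("target", "saccade")) {
  alignment <- match.arg(alignment)
  if (is.null(split)) split <- split_quantiles(bank$trials$rt_ms)
  rows <- which(split$labels == quantile)
  if (!length(rows)) stop("quantile '", quantile, "' has no trials")
  mats <- bank[[alignment]]
  u <- sample.int(length(mats), n_pool, replace = TRUE)
  r <- rows[sample.int(length(rows), n_pool, replace = TRUE)]
  acc <- 0
  for (k in seq_len(n_pool)) acc <- acc + mats[[u[k]]][r[k], ]
  acc / n_pool
}

#' Bootstrap configuration
#'
#' @param n_pool units pooled per pseudo-trial (default 25).
#' @param n_pseudo_trials simulated trials per quantile and repeat
#'   (default 25, within the procedure's 10-35 range).
#' @param n_repeats bootstrap repeats (default 10000; reduce for quick runs).
#' @param seed RNG seed for the bootstrap.
#' @param epochs named list of target-aligned epochs; `presac_end = NA`
#'   means "130 ms plus the median RT of the long quantile" (computed from
#'   the data, bounding the open-ended pre-saccadic epoch away from
#'   post-saccadic activity).
#' @param saccade_epoch saccade-aligned pre-saccadic epoch (ms).
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_pool = 25, n_pseudo_trials = 25,
                             n_repeats = 10000, seed = 1L,
                             epochs = list(evis = c(30, 80),
                                           lvis = c(80, 130),
                                           presac = c(130, NA)),
                             saccade_epoch = c(-40, 0)) {
  stopifnot(n_pool >= 1, n_pseudo_trials >= 1, n_repeats >= 1)
  structure(list(n_pool = n_pool, n_pseudo_trials = n_pseudo_trials,
                 n_repeats = n_repeats, seed = as.integer(seed),
                 epochs = epochs, saccade_epoch = saccade_epoch),
            class = "bootstrap_config")
}

#' Extremum of a trace within an epoch
#'
#' Argmax (peak) or argmin (trough) of a pooled SDF trace restricted to an
#' epoch; the first occurrence wins on exact ties.
#'
#' @param time time grid (ms).
#' @param trace SDF values on `time`.
#' @param epoch length-2 numeric, epoch bounds in ms (inclusive).
#' @param kind `"peak"` or `"trough"`.
#' @return list with `time` (ms) and `rate` (spikes/s).
#' @export
epoch_extremum <- function(time, trace, epoch, kind = c("peak", "trough")) {
  kind <- match.arg(kind)
  sel <- which(time >= epoch[1] & time <= epoch[2])
  if (!length(sel)) stop("epoch outside the trace span")
  i <- if (kind == "peak") sel[which.max(trace[sel])] else
    sel[which.min(trace[sel])]
  list(time = time[i], rate = trace[i])
}

#' Pseudo-population bootstrap of epoch timing and rate
#'
#' The population-resampling procedure that dissects early-visual,
#' late-visual and pre-saccadic epochs: trials are split into RT tertiles;
#' in each repeat, `n_pseudo_trials` pooled pseudo-trials (each the mean of
#' one random quantile trial from each of `n_pool` randomly drawn units) are
#' simulated per quantile and averaged; the per-epoch extremum time and rate
#' of the averaged trace are extracted on both alignments. The summary holds
#' the mean and 2.5/97.5 percentile CIs of these quantities over repeats.
#'
#' Epoch extrema are peaks for visual / visuomotor / motor populations and
#' troughs for tonic populations (`extremum = "trough"`). With
#' `condition = "good"` or `"bad"` the whole procedure runs on that
#' condition's trials only (tertiles recomputed within condition).
#'
#' @param bank [pseudo_population()] SDF bank for units of one subtype.
#' @param config [bootstrap_config()].
#' @param extremum `"peak"` or `"trough"`.
#' @param condition `NULL` (all trials), `"good"` or `"bad"`.
#' @return data.frame of class `bootstrap_summary`: one row per
#'   (quantile, epoch, alignment) with `mean_time`, `time_lo`, `time_hi`,
#'   `mean_rate`, `rate_lo`, `rate_hi`, `kind`, `n_repeats`, plus the
#'   realized quantile boundaries as an attribute `boundaries`.
#' @export
bootstrap_population <- function(bank, config = bootstrap_config(),
                                 extremum = c("peak", "trough"),
                                 condition = NULL) {
  extremum <- match.arg(extremum)
  set.seed(config$seed)
  trials <- bank$trials
  rows_all <- seq_len(nrow(trials))
  if (!is.null(condition)) {
    rows_all <- which(trials$condition == condition)
    if (length(rows_all) < 3) stop("too few trials in condition ", condition)
  }
  split <- split_quantiles(trials$rt_ms[rows_all])

  ## resolve the open-ended target-aligned pre-saccadic epoch
  epochs <- config$epochs
  if (is.na(epochs$presac[2])) {
    long_med <- stats::median(trials$rt_ms[rows_all][split$labels == "long"])
    epochs$presac[2] <- 130 + long_med
  }
  t_time <- bank$target_time
  s_time <- bank$saccade_time
  for (ep in epochs) if (ep[1] < t_time[1] || ep[2] > t_time[length(t_time)])
    stop("configuration error: epoch outside the target-aligned SDF span")
  se <- config$saccade_epoch
  if (se[1] < s_time[1] || se[2] > s_time[length(s_time)])
    stop("configuration error: saccade epoch outside the SDF span")

  n_units <- length(bank$target)
  n_draw <- config$n_pool * config$n_pseudo_trials
  quantiles <- levels(split$labels)
  epoch_names <- c(names(epochs), "presac_sacc")
  res_time <- res_rate <- array(
    NA_real_, dim = c(config$n_repeats, length(quantiles), length(epoch_names)),
    dimnames = list(NULL, quantiles, epoch_names)
  )

  for (qi in seq_along(quantiles)) {
    rows_q <- rows_all[split$labels == quantiles[qi]]
    Tq <- do.call(rbind, lapply(bank$target, function(m) m[rows_q, , drop = FALSE]))
    Sq <- do.call(rbind, lapply(bank$saccade, function(m) m[rows_q, , drop = FALSE]))
    nq <- length(rows_q)
    for (rep_i in seq_len(config$n_repeats)) {
      u <- sample.int(n_units, n_draw, replace = TRUE)
      j <- sample.int(nq, n_draw, replace = TRUE)
      idx <- (u - 1L) * nq + j
      mt <- colMeans(Tq[idx, , drop = FALSE])
      ms <- colMeans(Sq[idx, , drop = FALSE])
      for (ei in seq_along(epochs)) {
        ex <- epoch_extremum(t_time, mt, epochs[[ei]], extremum)
        res_time[rep_i, qi, ei] <- ex$time
        res_rate[rep_i, qi, ei] <- ex$rate
      }
      ex <- epoch_extremum(s_time, ms, se, extremum)
      res_time[rep_i, qi, length(epoch_names)] <- ex$time
      res_rate[rep_i, qi, length(epoch_names)] <- ex$rate
    }
  }

  out <- expand.grid(quantile = quantiles, epoch = epoch_names,
                     stringsAsFactors = FALSE)
  out$alignment <- ifelse(out$epoch == "presac_sacc", "saccade_on", "target_on")
  out$kind <- extremum
  summ <- function(a, q, e, f, ...) f(a[, q, e], ...)
  out$mean_time <- mapply(function(q, e) mean(res_time[, q, e]),
                          out$quantile, out$epoch)
  out$time_lo <- mapply(function(q, e)
    stats::quantile(res_time[, q, e], 0.025, names = FALSE),
    out$quantile, out$epoch)
  out$time_hi <- mapply(function(q, e)
    stats::quantile(res_time[, q, e], 0.975, names = FALSE),
    out$quantile, out$epoch)
  out$mean_rate <- mapply(function(q, e) mean(res_rate[, q, e]),
                          out$quantile, out$epoch)
  out$rate_lo <- mapply(function(q, e)
    stats::quantile(res_rate[, q, e], 0.025, names = FALSE),
    out$quantile, out$epoch)
  out$rate_hi <- mapply(function(q, e)
    stats::quantile(res_rate[, q, e], 0.975, names = FALSE),
    out$quantile, out$epoch)
  out$n_repeats <- config$n_repeats
  attr(out, "boundaries") <- split$boundaries
  attr(out, "epochs") <- epochs
  class(out) <- c("bootstrap_summary", "data.frame")
  out
}
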
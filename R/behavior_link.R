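#' Correlation between single-trial firing rate and behavior
#'
#' Pearson correlation between a unit's per-trial firing rate (80-160 ms
#' post-target by convention) and a per-trial behavioral measure (RT or PV).
#' Trials with fewer than `min_spikes` spikes in the window are dropped, and
#' at least `min_trials` trials must survive. A constant rate or behavior
#' vector raises an undefined-correlation error (the unit is flagged rather
#' than silently zeroed).
#'
#' @param rates per-trial rates (spikes/s).
#' @param behavior per-trial behavioral values (same length/order).
#' @param counts per-trial spike counts in the window, used for the
#'   `min_spikes` rule; when `NULL` they are reconstructed from the rates
#'   and `window_ms`.
#' @param window_ms window duration in ms (only used to reconstruct counts).
#' @param min_spikes minimum spikes per included trial (default 5).
#' @param min_trials minimum surviving trials (default 15).
#' @return list with `r`, `p` (two-sided), `n` (surviving trials).
#' @export
rate_behavior_correlation <- function(rates, behavior, counts = NULL,
                                      window_ms = 80, min_spikes = 5,
                                      min_trials = 15) {
  stopifnot(length(rates) == length(behavior))
  if (is.null(counts)) counts <- round(rates * window_ms / 1000)
  keep <- counts >= min_spikes & is.finite(behavior)
  x <- rates[keep]
  y <- behavior[keep]
  if (length(x) < min_trials)
    stop("too_few_trials: only ", length(x), " trials with >= ", min_spikes,
         " spikes (need ", min_trials, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant rates or behavior")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-unit value / RT / PV index table
#'
#' Builds one row per included, classified unit: the value index (good - bad
#' mean rate, 80-160 ms post-target), AUROC with permutation p, signed-rank
#' value sign, and the RT and PV indices (Pearson correlation of the
#' 80-160 ms rate with trial RT and PV, good and bad trials pooled).
#' Units whose indices are undefined (too few qualifying trials, constant
#' rate) keep `NA` with the reason recorded.
#'
#' @param bundle `sc_session`.
#' @param saccades per-trial saccade table.
#' @param classes classification table from [classify_session()].
#' @param alpha significance threshold for the flags.
#' @param n_perm AUROC permutations.
#' @param figure_convention report AUROC as 1 - AUROC.
#' @param window rate window (default 80-160 ms target-aligned).
#' @return data.frame of class `index_table`: `unit_id`, `subtype`,
#'   `value_index`, `auroc`, `auroc_p`, `signed_rank_p`, `value_sign`,
#'   `rt_index`, `rt_p`, `pv_index`, `pv_p`, `n_valid_trials`,
#'   `reward_sig`, `rt_sig`, `pv_sig`, `index_reason`.
#' @export
build_index_table <- function(bundle, saccades, classes, alpha = 0.05,
                              n_perm = 1000, figure_convention = FALSE,
                              window = window_spec("index", 80, 160, "target_on")) {
  keep <- classes$subtype != "unclassified"
  ids <- classes$unit_id[keep]
  subtypes <- classes$subtype[keep]
  rows <- vector("list", length(ids))
  unit_by_id <- stats::setNames(bundle$units,
                                vapply(bundle$units, `[[`, character(1), "unit_id"))
  for (i in seq_along(ids)) {
    unit <- unit_by_id[[ids[i]]]
    raster <- align_spikes(unit, bundle$trials, saccades, "target_on",
                           span = c(-400, 400))
    mod <- unit_modulation(raster, alpha = alpha, n_perm = n_perm,
                           figure_convention = figure_convention)
    rates <- window_rate(raster, window)
    counts <- window_count(raster, window)
    rt_res <- try(rate_behavior_correlation(rates, raster$trials$rt_ms,
                                            counts = counts), silent = TRUE)
    pv_res <- try(rate_behavior_correlation(rates, raster$trials$pv_deg_s,
                                            counts = counts), silent = TRUE)
    reason <- "none"
    if (inherits(rt_res, "try-error")) {
      reason <- sub("^.*?: *", "", trimws(attr(rt_res, "condition")$message))
      rt_res <- list(r = NA_real_, p = NA_real_, n = sum(counts >= 5))
    }
    if (inherits(pv_res, "try-error"))
      pv_res <- list(r = NA_real_, p = NA_real_, n = NA_integer_)
    rows[[i]] <- data.frame(
      unit_id = ids[i], subtype = subtypes[i],
      value_index = mod$value_index,
      auroc = mod$auroc, auroc_p = mod$auroc_p,
      signed_rank_p = mod$signed_rank_p, value_sign = mod$sign,
      rt_index = rt_res$r, rt_p = rt_res$p,
      pv_index = pv_res$r, pv_p = pv_res$p,
      n_valid_trials = rt_res$n,
      reward_sig = is.finite(mod$auroc_p) && mod$auroc_p < alpha,
      rt_sig = is.finite(rt_res$p) && rt_res$p <= alpha,
      pv_sig = is.finite(pv_res$p) && pv_res$p <= alpha,
      index_reason = reason,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit_id = character(0), subtype = character(0),
               value_index = numeric(0), auroc = numeric(0),
               auroc_p = numeric(0), signed_rank_p = numeric(0),
               value_sign = character(0), rt_index = numeric(0),
               rt_p = numeric(0), pv_index = numeric(0), pv_p = numeric(0),
               n_valid_trials = integer(0), reward_sig = logical(0),
               rt_sig = logical(0), pv_sig = logical(0),
               index_reason = character(0), stringsAsFactors = FALSE)
  class(out) <- c("index_table", "data.frame")
  out
}

#' Cross-neuron correlation between modulation indices
#'
#' Pearson correlation, across units of one subtype, between two per-unit
#' indices (e.g. value index vs RT index). All units with both indices
#' defined are included, whether or not the individual indices are
#' significant. Also returns the least-squares line for plotting.
#'
#' @param table an [build_index_table()] table.
#' @param subtype which functional subtype to correlate.
#' @param x,y column names of the two indices (default `value_index` vs
#'   `rt_index`).
#' @return list with `r`, `p`, `n`, `intercept`, `slope`.
#' @export
index_correlation <- function(table, subtype, x = "value_index",
                              y = "rt_index") {
  sel <- table$subtype == subtype & is.finite(table[[x]]) & is.finite(table[[y]])
  if (sum(sel) < 3)
    stop("need at least 3 units of subtype '", subtype,
         "' with both indices defined")
  xs <- table[[x]][sel]
  ys <- table[[y]][sel]
  ct <- stats::cor.test(xs, ys)
  fit <- stats::lm.fit(cbind(1, xs), ys)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(sel),
       intercept = fit$coefficients[1], slope = fit$coefficients[2])
}

#' Overlap of reward-, RT- and PV-modulated units
#'
#' Partitions the units of each subtype into the eight cells of the
#' reward x RT x PV significance Venn diagram.
#'
#' @param table an [build_index_table()] table with significance flags.
#' @return data.frame, one row per subtype, with columns `reward_only`,
#'   `rt_only`, `pv_only`, `reward_rt`, `reward_pv`, `rt_pv`, `all_three`,
#'   `none` and `n_units`; the eight counts sum to `n_units`.
#' @export
modulation_overlap <- function(table) {
  subtypes <- unique(table$subtype)
  rows <- lapply(subtypes, function(st) {
    s <- table[table$subtype == st, , drop = FALSE]
    rw <- s$reward_sig; rt <- s$rt_sig; pv <- s$pv_sig
    data.frame(
      subtype = st,
      reward_only = sum(rw & !rt & !pv),
      rt_only = sum(!rw & rt & !pv),
      pv_only = sum(!rw & !rt & pv),
      reward_rt = sum(rw & rt & !pv),
      reward_pv = sum(rw & !rt & pv),
      rt_pv = sum(!rw & rt & pv),
      all_three = sum(rw & rt & pv),
      none = sum(!rw & !rt & !pv),
      n_units = nrow(s),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
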
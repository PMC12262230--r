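#' Classification windows
#'
#' The five windows used for functional classification: baseline (-200..0),
#' phasic #1 (0..80) and phasic #2 (80..160) relative to target onset;
#' pre-saccadic (-100..-50) and peri-saccadic (-50..20) relative to saccade
#' onset.
#'
#' @return named list of [window_spec()] objects.
#' @export
classification_windows <- function() {
  list(
    baseline = window_spec("baseline", -200, 0, "target_on"),
    phasic1 = window_spec("phasic1", 0, 80, "target_on"),
    phasic2 = window_spec("phasic2", 80, 160, "target_on"),
    pre = window_spec("pre", -100, -50, "saccade_on"),
    peri = window_spec("peri", -50, 20, "saccade_on")
  )
}

## one-sided / two-sided rank-sum p-value helper (normal approximation is
## fine at the trial counts involved; rank-based, so scale invariant)
rank_p <- function(x, y, alternative) {
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                      exact = FALSE)$p.value)
}

#' Classify one unit from its window firing rates
#'
#' Applies the rule-based functional taxonomy to per-trial rates in the five
#' [classification_windows()]:
#' \itemize{
#'   \item \strong{tonic}: phasic #1 or phasic #2 significantly \emph{below}
#'     baseline (tested first; tonic units are recognized by target-evoked
#'     suppression of a high baseline).
#'   \item \strong{visual}: phasic #1 and phasic #2 significantly above
#'     baseline, and no pre- vs peri-saccadic difference.
#'   \item \strong{visuomotor}: phasic #1 and phasic #2 above baseline
#'     \emph{and} a significant pre- vs peri-saccadic difference (units
#'     meeting the visual activation criteria are visuomotor exactly when the
#'     motor contrast is significant).
#'   \item \strong{motor}: significant pre- vs peri-saccadic difference with
#'     phasic #1 significantly below phasic #2 (and no visual activation).
#'   \item otherwise \strong{unclassified} (`criteria_not_met`), or
#'     `no_task_response` when the Kruskal-Wallis omnibus over all five
#'     windows is not significant.
#' }
#' Significance is a Kruskal-Wallis omnibus followed by pairwise directional
#' rank-sum comparisons, all at `alpha` without multiplicity correction. All
#' tests are rank-based, so labels are invariant to uniform rate scaling.
#'
#' @param rates named list of per-trial rate vectors: `baseline`, `phasic1`,
#'   `phasic2` (target-aligned), `pre`, `peri` (saccade-aligned).
#' @param alpha significance threshold (default 0.05).
#' @return list of class `class_label`: `subtype`, `exclusion_reason`, and
#'   `criteria` (data.frame of each test with its p-value).
#' @export
classify_unit <- function(rates, alpha = 0.05) {
  need <- c("baseline", "phasic1", "phasic2", "pre", "peri")
  if (!all(need %in% names(rates)))
    stop("argument error: missing window(s): ",
         paste(setdiff(need, names(rates)), collapse = ", "))
  rates <- rates[need]

  kw <- suppressWarnings(stats::kruskal.test(rates))
  p <- c(
    omnibus = kw$p.value,
    p1_gt_base = rank_p(rates$phasic1, rates$baseline, "greater"),
    p2_gt_base = rank_p(rates$phasic2, rates$baseline, "greater"),
    p1_lt_base = rank_p(rates$phasic1, rates$baseline, "less"),
    p2_lt_base = rank_p(rates$phasic2, rates$baseline, "less"),
    pre_ne_peri = rank_p(rates$pre, rates$peri, "two.sided"),
    p1_lt_p2 = rank_p(rates$phasic1, rates$phasic2, "less")
  )
  criteria <- data.frame(test = names(p), p_value = unname(p),
                         stringsAsFactors = FALSE)
  label <- function(subtype, reason = "none")
    structure(list(subtype = subtype, exclusion_reason = reason,
                   criteria = criteria), class = "class_label")

  if (is.na(p["omnibus"]) || p["omnibus"] >= alpha)
    return(label("unclassified", "no_task_response"))

  ## directional calls additionally require the sample means to agree with
  ## the claimed direction: with sparse counts, rank tests on windows of
  ## unequal duration can reach significance against the direction of the
  ## means (the shorter window has more zero-count trials)
  mdir <- c(
    p1_gt_base = mean(rates$phasic1) > mean(rates$baseline),
    p2_gt_base = mean(rates$phasic2) > mean(rates$baseline),
    p1_lt_base = mean(rates$phasic1) < mean(rates$baseline),
    p2_lt_base = mean(rates$phasic2) < mean(rates$baseline),
    pre_ne_peri = TRUE,
    p1_lt_p2 = mean(rates$phasic1) < mean(rates$phasic2)
  )
  sig <- function(nm) !is.na(p[nm]) && p[nm] < alpha && mdir[nm]
  ## a phasic-1-only reduction additionally needs the phasic-2 mean on the
  ## suppressed side: target-evoked suppression of a tonic unit persists,
  ## whereas a unit whose phasic-2 is elevated is not suppressed
  if (sig("p2_lt_base") || (sig("p1_lt_base") && mdir["p2_lt_base"]))
    return(label("tonic"))
  visual_act <- sig("p1_gt_base") && sig("p2_gt_base")
  motor_act <- sig("pre_ne_peri")
  if (visual_act && motor_act) return(label("visuomotor"))
  if (visual_act) return(label("visual"))
  if (motor_act && sig("p1_lt_p2")) return(label("motor"))
  label("unclassified", "criteria_not_met")
}

#' Classify every unit of a session
#'
#' Aligns each unit on target and saccade onset, applies the
#' [inclusion_filter()], computes the five classification window rates and
#' runs [classify_unit()]. Every unit appears exactly once; per-subtype and
#' per-exclusion-reason counts sum to the total unit count.
#'
#' @param bundle `sc_session`.
#' @param saccades per-trial saccade table ([session_saccades()]).
#' @param alpha significance threshold.
#' @return data.frame, one row per unit: `unit_id`, `subtype`,
#'   `exclusion_reason`, the p-values of the classification tests, and
#'   `n_good`, `n_bad` valid trial counts.
#' @export
classify_session <- function(bundle, saccades, alpha = 0.05) {
  w <- classification_windows()
  if (length(bundle$units) == 0)
    return(data.frame(unit_id = character(0), subtype = character(0),
                      exclusion_reason = character(0), n_good = integer(0),
                      n_bad = integer(0), stringsAsFactors = FALSE))
  rows <- vector("list", length(bundle$units))
  for (i in seq_along(bundle$units)) {
    unit <- bundle$units[[i]]
    rt <- align_spikes(unit, bundle$trials, saccades, "target_on",
                       span = c(-400, 400))
    rs <- align_spikes(unit, bundle$trials, saccades, "saccade_on",
                       span = c(-400, 400))
    n_good <- sum(rt$trials$condition == "good")
    n_bad <- sum(rt$trials$condition == "bad")
    inc <- inclusion_filter(rt)
    if (!inc$pass) {
      lab <- list(subtype = "unclassified",
                  exclusion_reason = "too_few_trials_or_spikes",
                  criteria = NULL)
    } else {
      rates <- list(
        baseline = window_rate(rt, w$baseline),
        phasic1 = window_rate(rt, w$phasic1),
        phasic2 = window_rate(rt, w$phasic2),
        pre = window_rate(rs, w$pre),
        peri = window_rate(rs, w$peri)
      )
      lab <- classify_unit(rates, alpha)
    }
    pv <- if (is.null(lab$criteria)) {
      stats::setNames(rep(NA_real_, 7),
                      c("omnibus", "p1_gt_base", "p2_gt_base", "p1_lt_base",
                        "p2_lt_base", "pre_ne_peri", "p1_lt_p2"))
    } else stats::setNames(lab$criteria$p_value, lab$criteria$test)
    rows[[i]] <- cbind(
      data.frame(unit_id = unit$unit_id, subtype = lab$subtype,
                 exclusion_reason = lab$exclusion_reason,
                 n_good = n_good, n_bad = n_bad, stringsAsFactors = FALSE),
      as.data.frame(as.list(pv))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
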
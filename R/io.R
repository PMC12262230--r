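#' Write a session bundle to a directory
#'
#' Serializes the bundle as plain columnar text: `manifest.json`,
#' `trials.csv`, `spikes.csv`, `eye.csv` and (for synthetic sessions)
#' `truth.json`. Times are written in ms with 0.1 ms precision, positions in
#' degrees.
#'
#' @param bundle `sc_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tr <- bundle$trials
  tr$fix_on_ms <- round(tr$fix_on_ms, 1)
  tr$target_on_ms <- round(tr$target_on_ms, 1)
  tr$target_x_deg <- round(tr$target_x_deg, 4)
  tr$target_y_deg <- round(tr$target_y_deg, 4)
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  sp <- do.call(rbind, lapply(bundle$units, function(u) {
    if (!length(u$spike_ms)) return(NULL)
    data.frame(unit_id = u$unit_id, channel = u$channel,
               spike_ms = round(sort(u$spike_ms), 1),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  eye <- bundle$eye
  eye$x_deg <- round(eye$x_deg, 4)
  eye$y_deg <- round(eye$y_deg, 4)
  utils::write.csv(eye, file.path(dir, "eye.csv"), row.names = FALSE)
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Counterpart of [write_session()], with schema validation: all files must
#' be present, condition labels must be `good`/`bad`, spike times must be
#' sorted per unit and the eye trace must be uniformly sampled at 1 kHz.
#'
#' @param dir session directory.
#' @return `sc_session` (with `truth` when `truth.json` exists).
#' @export
read_session <- function(dir) {
  need <- c("manifest.json", "trials.csv", "spikes.csv", "eye.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("I/O error: missing session file(s): ", paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  bad_cond <- setdiff(unique(trials$condition), c("good", "bad"))
  if (length(bad_cond))
    stop("format error in trials.csv: unknown condition label '",
         bad_cond[1], "'")
  sp <- utils::read.csv(file.path(dir, "spikes.csv"), stringsAsFactors = FALSE)
  units <- lapply(split(sp, factor(sp$unit_id, unique(sp$unit_id))),
                  function(d) {
    if (is.unsorted(d$spike_ms))
      stop("format error in spikes.csv: non-monotone spike times for unit ",
           d$unit_id[1])
    list(unit_id = d$unit_id[1], channel = d$channel[1], spike_ms = d$spike_ms)
  })
  names(units) <- NULL
  eye <- utils::read.csv(file.path(dir, "eye.csv"), stringsAsFactors = FALSE)
  if (nrow(eye) > 1 && any(abs(diff(eye$t_ms) - 1) > 1e-6))
    stop("format error in eye.csv: sampling is not uniform 1 kHz")
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json")))
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
  structure(list(manifest = manifest, trials = trials, units = units,
                 eye = eye, truth = truth), class = "sc_session")
}

#' Pipeline configuration
#'
#' All defaults are the analysis constants used throughout: 30 deg/s saccade
#' onset threshold, 10 ms SDF bandwidth, alpha = 0.05, 80-160 / 80-240 ms
#' value windows, tertile bootstrap with 25 pooled units. The blink cutoff
#' defaults to 1200 deg/s at the pipeline level: a literal 700 deg/s cutoff
#' would discard most large-amplitude saccades whose main-sequence peak
#' velocities legitimately exceed it (see the methods vignette);
#' [detect_saccades()] keeps 700 as its own default for isolated use.
#'
#' @param ... overrides of any default field.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    session_dir = NULL,          # NULL: simulate with `params`
    params = generator_params(),
    out_dir = "scvigor_out",
    onset_threshold = 30,
    blink_threshold = 1200,
    rt_window = c(50, 600),
    alpha = 0.05,
    bandwidth_ms = 10,
    n_perm = 1000,
    figure_convention = FALSE,
    bootstrap = bootstrap_config(n_repeats = 1000),
    min_bootstrap_units = 3,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown pipeline field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, saccade detection, unit classification, value
#' modulation, the pseudo-population bootstrap per classified subtype, and
#' the behavior-link index table, persisting every stage's output (CSV/JSON)
#' plus the effective configuration in `out_dir`. Reruns with the same
#' configuration and seed reproduce all artifacts byte-identically.
#'
#' @param config [pipeline_config()].
#' @return `out_dir`, invisibly; outputs: `session/` (when simulated),
#'   `saccades.csv`, `classes.csv`, `indices.csv`, `overlap.csv`,
#'   `boot_summary.json`, `config.json`, `log.txt`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  cat("", file = log_path)
  logline <- function(stage, msg)
    cat(sprintf("[%s] seed=%d %s\n", stage, config$seed, msg),
        file = log_path, append = TRUE)

  set.seed(config$seed)
  if (is.null(config$session_dir)) {
    bundle <- generate_session(config$params)
    write_session(bundle, file.path(config$out_dir, "session"))
    logline("simulate", sprintf("generated %d trials / %d units",
                                nrow(bundle$trials), length(bundle$units)))
  } else {
    bundle <- read_session(config$session_dir)
    logline("ingest", config$session_dir)
  }

  saccades <- session_saccades(bundle, config$onset_threshold,
                               config$blink_threshold, config$rt_window)
  sacc_out <- saccades
  for (cn in c("onset_ms", "offset_ms", "rt_ms"))
    sacc_out[[cn]] <- round(sacc_out[[cn]], 1)
  for (cn in c("pv_deg_s", "amplitude_deg"))
    sacc_out[[cn]] <- round(sacc_out[[cn]], 3)
  utils::write.csv(sacc_out, file.path(config$out_dir, "saccades.csv"),
                   row.names = FALSE)
  logline("saccades", sprintf("%d/%d valid", sum(saccades$valid),
                              nrow(saccades)))

  set.seed(config$seed + 1L)
  classes <- classify_session(bundle, saccades, config$alpha)
  cls_out <- classes
  num <- vapply(cls_out, is.numeric, logical(1))
  cls_out[num] <- lapply(cls_out[num], function(x) signif(x, 6))
  utils::write.csv(cls_out, file.path(config$out_dir, "classes.csv"),
                   row.names = FALSE)
  logline("classify", paste(capture_counts(classes$subtype), collapse = ", "))

  set.seed(config$seed + 2L)
  indices <- build_index_table(bundle, saccades, classes,
                               alpha = config$alpha, n_perm = config$n_perm,
                               figure_convention = config$figure_convention)
  idx_out <- indices
  num <- vapply(idx_out, is.numeric, logical(1))
  idx_out[num] <- lapply(idx_out[num], function(x) signif(x, 6))
  utils::write.csv(idx_out, file.path(config$out_dir, "indices.csv"),
                   row.names = FALSE)
  utils::write.csv(modulation_overlap(indices),
                   file.path(config$out_dir, "overlap.csv"), row.names = FALSE)
  logline("modulate", sprintf("%d units indexed", nrow(indices)))

  boot <- list()
  for (st in c("visual", "visuomotor", "motor", "tonic")) {
    ids <- classes$unit_id[classes$subtype == st]
    if (length(ids) < config$min_bootstrap_units) next
    bank <- pseudo_population(bundle, saccades, unit_ids = ids,
                              bandwidth_ms = config$bandwidth_ms)
    bc <- config$bootstrap
    bc$seed <- config$seed + 10L
    summ <- bootstrap_population(bank, bc,
                                 extremum = if (st == "tonic") "trough" else "peak")
    summ_num <- as.data.frame(summ)
    num <- vapply(summ_num, is.numeric, logical(1))
    summ_num[num] <- lapply(summ_num[num], function(x) signif(x, 6))
    boot[[st]] <- summ_num
    logline("bootstrap", sprintf("%s: %d units", st, length(ids)))
  }
  jsonlite::write_json(boot, file.path(config$out_dir, "boot_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")

  cfg_out <- unclass(config)
  cfg_out$params <- unclass(cfg_out$params)
  cfg_out$params$subtype_templates <-
    lapply(cfg_out$params$subtype_templates, unclass)
  cfg_out$bootstrap <- unclass(cfg_out$bootstrap)
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  logline("done", "all stages complete")
  invisible(config$out_dir)
}

capture_counts <- function(x) {
  tb <- table(x)
  sprintf("%s=%d", names(tb), as.integer(tb))
}
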
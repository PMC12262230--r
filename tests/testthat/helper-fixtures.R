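# Shared fixtures. Heavy synthetic populations are generated once per test
# run and cached; all tests reuse the same study-condition defaults.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache))
    assign(name, expr, envir = fixture_cache)
  get(name, envir = fixture_cache)
}

# main population: 50 units per subtype under default study conditions
pop_bundle <- function() {
  cached("pop", generate_session(generator_params(n_units_per_subtype = 50,
                                                  seed = 7)))
}

pop_saccades <- function() {
  cached("pop_sac", session_saccades(pop_bundle(), blink_threshold = 1200))
}

pop_classes <- function() {
  cached("pop_cls", classify_session(pop_bundle(), pop_saccades()))
}

pop_bank <- function(subtype) {
  cached(paste0("bank_", subtype), {
    cls <- pop_classes()
    pseudo_population(pop_bundle(), pop_saccades(),
                      unit_ids = cls$unit_id[cls$subtype == subtype])
  })
}

pop_index_table <- function() {
  cached("pop_idx", {
    set.seed(424242)
    build_index_table(pop_bundle(), pop_saccades(), pop_classes(),
                      n_perm = 500)
  })
}

# visual-only session with the default 95 ms value onset (onset recovery)
visual_bundle <- function() {
  cached("vis", generate_session(
    generator_params(subtypes = "visual", n_units_per_subtype = 100,
                     seed = 13)))
}

visual_saccades <- function() {
  cached("vis_sac", session_saccades(visual_bundle(), blink_threshold = 1200))
}

# null population: visual units with the value gain and the rate-to-RT
# coupling switched off (type-I calibrations)
null_bundle <- function() {
  cached("null", generate_session(
    generator_params(subtypes = "visual", n_units_per_subtype = 200,
                     seed = 77, value_gain = 1, rate_rt_coupling = 0)))
}

null_saccades <- function() {
  cached("null_sac", session_saccades(null_bundle(), blink_threshold = 1200))
}

# small session for cheap structural tests
small_bundle <- function() {
  cached("small", generate_session(generator_params(n_units_per_subtype = 2,
                                                    seed = 3)))
}

small_saccades <- function() {
  cached("small_sac", session_saccades(small_bundle(), blink_threshold = 1200))
}

# unit-level onset battery used by onset tests: standardized difference of
# condition-mean SDFs, searched in the post-target response window
unit_onset <- function(bundle, saccades, unit,
                       direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  r <- align_spikes(unit, bundle$trials, saccades, "target_on",
                    span = c(-400, 400))
  s <- sdf(r)
  good <- r$trials$condition == "good"
  mg <- colMeans(s$values[good, , drop = FALSE])
  mb <- colMeans(s$values[!good, , drop = FALSE])
  vg <- apply(s$values[good, , drop = FALSE], 2, stats::var)
  vb <- apply(s$values[!good, , drop = FALSE], 2, stats::var)
  se <- sqrt(vg / sum(good) + vb / sum(!good))
  modulation_onset(mg, mb, s$time, direction = direction,
                   search = c(0, 250), se = se)
}

# eye trace whose radial speed is an exact Gaussian profile (deg/s)
gaussian_speed_trace <- function(peak = 400, center = 150, sd_ms = 15,
                                 len = 400) {
  t <- 0:len
  v <- peak * exp(-(t - center)^2 / (2 * sd_ms^2))
  x <- cumsum(v) * 1e-3   # deg, left Riemann integral at 1 kHz
  data.frame(t_ms = t, x_deg = x, y_deg = 0)
}

ci_overlap <- function(lo1, hi1, lo2, hi2) !(lo1 > hi2 | hi1 < lo2)
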
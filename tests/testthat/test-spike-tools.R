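# raster with hand-chosen spikes, bypassing the generator
toy_raster <- function(spikes, conditions = NULL, span = c(-400, 400)) {
  n <- length(spikes)
  if (is.null(conditions)) conditions <- rep(c("good", "bad"), length.out = n)
  structure(list(
    unit_id = "toy", event_name = "target_on", span = span,
    trials = data.frame(trial_id = seq_len(n), condition = conditions,
                        rt_ms = rep(200, n), pv_deg_s = rep(600, n),
                        event_ms = rep(1000, n), stringsAsFactors = FALSE),
    spikes = spikes
  ), class = "aligned_raster")
}

test_that("align_spikes subtracts the event time per trial", {
  b <- small_bundle()
  sac <- small_saccades()
  u <- list(unit_id = "x", channel = 1,
            spike_ms = b$trials$target_on_ms[1] + 42)
  r <- align_spikes(u, b$trials, sac, "target_on")
  expect_equal(r$spikes[[1]], 42)
  expect_length(r$spikes, sum(sac$valid))

  empty <- list(unit_id = "e", channel = 1, spike_ms = numeric(0))
  re <- align_spikes(empty, b$trials, sac, "target_on")
  expect_length(re$spikes, sum(sac$valid))
  expect_true(all(lengths(re$spikes) == 0))

  expect_error(align_spikes(u, b$trials, sac, "juice_on"), "argument error")
})

test_that("saccade alignment equals target alignment shifted by trial RT", {
  b <- small_bundle()
  sac <- small_saccades()
  u <- b$units[[1]]
  rt <- align_spikes(u, b$trials, sac, "target_on", span = c(-500, 500))
  rs <- align_spikes(u, b$trials, sac, "saccade_on", span = c(-500, 500))
  for (i in seq_along(rt$spikes)) {
    shift <- rs$trials$event_ms[i] - rt$trials$event_ms[i]
    # compare on a window safely inside both spans for any trial RT
    a <- rt$spikes[[i]] - shift
    a <- a[a >= -100 & a < 150]
    b2 <- rs$spikes[[i]]
    b2 <- b2[b2 >= -100 & b2 < 150]
    expect_equal(sort(a), sort(b2), tolerance = 1e-9)
  }
})

test_that("SDF matches the Gaussian closed form and conserves spike mass", {
  r <- toy_raster(list(0), conditions = "good", span = c(-100, 100))
  s <- sdf(r, bandwidth_ms = 10)
  expect_equal(max(s$values), 1000 / (10 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(s$time[which.max(s$values)], 0)
  expect_equal(sum(s$values) / 1000, 1, tolerance = 1e-6)

  # a trial's integral equals its interior spike count
  r3 <- toy_raster(list(c(-50, 0, 10, 25)), conditions = "good",
                   span = c(-150, 150))
  s3 <- sdf(r3)
  expect_equal(sum(s3$values) / 1000, 4, tolerance = 1e-6)

  # no spikes: all-zero matrix with one row per trial
  r0 <- toy_raster(list(numeric(0), numeric(0)))
  s0 <- sdf(r0)
  expect_equal(dim(s0$values), c(2, diff(r0$span) + 1))
  expect_true(all(s0$values == 0))

  expect_error(sdf(r0, bandwidth_ms = 0), "argument error")
})

test_that("SDF is linear: the estimate of merged spike sets is the sum", {
  set.seed(8)
  a <- sort(runif(15, -200, 200))
  b <- sort(runif(10, -200, 200))
  sa <- sdf(toy_raster(list(a), "good"))
  sb <- sdf(toy_raster(list(b), "good"))
  sab <- sdf(toy_raster(list(sort(c(a, b))), "good"))
  expect_equal(sab$values, sa$values + sb$values, tolerance = 1e-9)
})

test_that("window rates equal brute-force counting", {
  w <- window_spec("w", 40, 240)
  set.seed(21)
  spikes <- replicate(30, sort(runif(rpois(1, 15), -400, 400)),
                      simplify = FALSE)
  r <- toy_raster(spikes)
  rates <- window_rate(r, w)
  oracle <- vapply(spikes, function(s) sum(s >= 40 & s < 240) / 0.2,
                   numeric(1))
  expect_identical(rates, oracle)

  # 4 spikes in a 200 ms window is 20 spikes/s; empty window is 0
  r4 <- toy_raster(list(c(50, 60, 100, 239), numeric(0)))
  expect_equal(window_rate(r4, w), c(20, 0))

  expect_error(window_spec("bad", 10, 10), "start")
  expect_error(window_rate(toy_raster(list()), w), "empty trial set")
  expect_error(window_rate(r4, window_spec("big", -500, 100)), "span")
})

test_that("inclusion filter enforces the trial and spike-count rules", {
  sp20 <- c(replicate(10, list(c(0, 50))))   # 20 spikes over 10 trials
  r <- toy_raster(sp20)   # 5 good + 5 bad
  expect_false(inclusion_filter(r)$pass)
  expect_equal(inclusion_filter(r)$reason, "too_few_spikes")

  # 21 spikes passes (strictly more than 20 required)
  sp21 <- sp20; sp21[[1]] <- c(0, 50, 100)
  expect_true(inclusion_filter(toy_raster(sp21))$pass)

  # 4 trials in one condition fails regardless of spikes
  r4 <- toy_raster(replicate(9, list(c(0, 10, 20))),
                   conditions = c(rep("good", 4), rep("bad", 5)))
  expect_false(inclusion_filter(r4)$pass)
  expect_equal(inclusion_filter(r4)$reason, "too_few_trials")
})
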
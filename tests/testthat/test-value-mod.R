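test_that("auroc equals exhaustive pair counting and obeys its identities", {
  # identical distributions
  expect_equal(auroc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  # full separation
  expect_equal(auroc(c(5, 6, 7), c(1, 2)), 1)
  # worked example: one favorable pair of two
  expect_equal(auroc(c(3, 5), 4), 0.5)
  # complement identity on random samples
  set.seed(3)
  for (i in 1:20) {
    g <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(auroc(g, b) + auroc(b, g), 1)
  }
  # figure convention flips around 0.5
  expect_equal(auroc(c(5, 6), c(1, 2), figure_convention = TRUE), 0)
})

test_that("exact signed-rank enumeration reproduces closed-form cases", {
  # 6 pairs with a constant positive offset: p = 2/64
  res <- signed_rank_exact(1:6 + 10, 1:6)
  expect_equal(res$p, 2 / 64)

  # zero differences are dropped entirely
  expect_equal(signed_rank_exact(c(1, 2, 3), c(1, 2, 3))$p, 1)

  # independent oracle: enumerate sign flips directly for random data
  set.seed(9)
  for (i in 1:10) {
    d <- round(rnorm(7), 1)
    d <- d[d != 0]
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    mu <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    w_all <- as.numeric(signs %*% r)
    p_oracle <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    expect_equal(signed_rank_exact(d, rep(0, length(d)))$p, p_oracle)
  }
})

test_that("value_comparison calls sign and index correctly", {
  # identical samples: zero index, no sign
  x <- c(10, 12, 14, 16, 18, 20)
  res <- value_comparison(x, x)
  expect_equal(res$value_index, 0)
  expect_equal(res$sign, "none")

  # constant positive offset: exact p = 0.03125, positive sign
  res2 <- value_comparison(x + 10, x)
  expect_equal(res2$p, 0.03125)
  expect_equal(res2$sign, "positive")
  expect_equal(res2$value_index, 10)

  res3 <- value_comparison(x, x + 10)
  expect_equal(res3$sign, "negative")

  expect_error(value_comparison(c(1, 2), c(1, 2, 3, 4, 5)), "at least 5")

  # all-zero rates in both conditions: no sign, index 0
  z <- rep(0, 8)
  res0 <- value_comparison(z, z)
  expect_equal(res0$sign, "none")
  expect_equal(res0$value_index, 0)
})

test_that("auroc permutation p-values behave like a permutation test", {
  # identical constant samples: p = 1
  set.seed(10)
  expect_equal(auroc_significance(rep(5, 6), rep(5, 6), n_perm = 200), 1)

  # fully separated samples at n = 10 + 10: p near the permutation floor
  set.seed(11)
  p_sep <- auroc_significance(101:110, 1:10, n_perm = 1000)
  expect_lte(p_sep, 2 / 1001)

  # estimate stable across RNG seeds within binomial error
  g <- c(12, 15, 9, 14, 18, 11, 13, 16, 10, 17)
  b <- c(10, 12, 8, 11, 13, 9, 12, 14)
  ps <- vapply(1:5, function(s) {
    set.seed(s)
    auroc_significance(g, b, n_perm = 1000)
  }, numeric(1))
  expect_lt(max(ps) - min(ps), 0.06)

  expect_error(auroc_significance(1:3, 1:3), "at least 8")
})

test_that("modulation onset follows the threshold-persistence rule", {
  time <- -300:400
  base <- rep(0, length(time))

  # identical traces: no onset
  expect_true(is.na(modulation_onset(base, base, time)))

  # clean step of 5 baseline SDs at 100 ms: onset within [95, 110]
  set.seed(12)
  noise <- rnorm(length(time), 0, 1)
  d <- noise + ifelse(time >= 100, 5, 0)
  onset <- modulation_onset(d, base, time)
  expect_false(is.na(onset))
  expect_gte(onset, 95)
  expect_lte(onset, 110)

  # a 10 ms blip never triggers the 20 ms persistence rule
  blip <- ifelse(time >= 100 & time < 110, 100, 0)
  expect_true(is.na(modulation_onset(blip, base, time)))

  # negative-going modulation is found on the mirrored trace
  dn <- noise - ifelse(time >= 120, 5, 0)
  on_neg <- modulation_onset(dn, base, time, direction = "negative")
  expect_false(is.na(on_neg))
  expect_gte(on_neg, 115)
  expect_lte(on_neg, 130)

  # zero baseline variance with zero difference: absent, not an error
  expect_true(is.na(modulation_onset(base, base + 0, time)))
})

test_that("unit_modulation recovers generator truth signs", {
  b <- pop_bundle()
  sac <- pop_saccades()
  truth <- b$truth$units
  vis <- which(truth$subtype == "visual")[1:25]
  set.seed(55)
  res <- lapply(b$units[vis], function(u) {
    r <- align_spikes(u, b$trials, sac, "target_on", span = c(-400, 400))
    unit_modulation(r, n_perm = 200)
  })
  called <- vapply(res, `[[`, character(1), "sign")
  tr <- truth$sign[vis]
  # no called sign ever contradicts the planted sign
  expect_false(any(called == "positive" & tr == "negative"))
  expect_false(any(called == "negative" & tr == "positive"))
  # most planted modulations are recovered
  expect_gte(mean(called[tr != "none"] == tr[tr != "none"]), 0.7)
  # AUROC sits on the correct side of 0.5 for recovered units
  au <- vapply(res, `[[`, numeric(1), "auroc")
  expect_true(all(au[called == "positive"] > 0.5))
  expect_true(all(au[called == "negative"] < 0.5))
})
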
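twitch_1hz <- function(peak = 40) {
  function(t) {
    ph <- (t %% 1000) / 1000
    peak * ifelse(ph < 0.35, sin(pi * ph / 0.35)^2, 0)
  }
}

test_that("closed-loop blood volume is conserved over 10 s", {
  h <- run_circulation(circulation_params(), twitch_1hz(), duration_ms = 10000)
  drift <- abs(rowSums(h$volumes) - h$params$total_volume)
  expect_true(all(drift / h$params$total_volume < 1e-3))
  expect_true(all(h$volumes >= 0))
})

test_that("valve flows are one-way", {
  h <- run_circulation(circulation_params(), twitch_1hz(), duration_ms = 5000)
  expect_true(all(h$valve_flows >= 0))
})

test_that("zero tension drive gives a flowless system and zero stroke volume", {
  # atrial timing amplitude silenced too, so the loop is fully passive;
  # stressed volume redistributes with a ~25 s time constant, after which
  # every valve flow decays toward zero
  h <- run_circulation(circulation_params(E_la_amp = 1e-9, E_ra_amp = 1e-9),
                       function(t) 0 * t, duration_ms = 120000)
  q30 <- max(h$valve_flows[h$time > 29000 & h$time < 31000, ])
  qend <- max(h$valve_flows[h$time > 118000, ])
  expect_lt(qend, 0.05)
  expect_lt(qend, q30 / 10)
  expect_equal(stroke_volume(h), 0)
})

test_that("a periodic twitch settles to a periodic loop", {
  p <- circulation_params(atrial_period_ms = 1000)
  h <- run_circulation(p, twitch_1hz(), duration_ms = 20000)
  per <- meaningful_ejection_periods(h)
  expect_gt(nrow(per), 10)
  edv <- tail(per$edv, 5)
  expect_true(all(abs(diff(edv)) / edv[-1] < 0.01))
  sv <- stroke_volume(h)
  expect_gt(sv, 40)
  expect_lt(sv, 110)
})

test_that("meaningful ejection periods ignore sub-threshold ripple", {
  tt <- seq(0, 5000)
  ph <- (tt %% 1000) / 1000
  saw <- ifelse(ph < 0.6, 120 - 70 * ph / 0.6, 50 + 70 * (ph - 0.6) / 0.4)
  expect_equal(stroke_volume(list(time = tt, volume = saw)), 70)
  per <- meaningful_ejection_periods(list(time = tt, volume = saw))
  expect_equal(nrow(per), 4)  # interior cycles of the 5 s sawtooth
  # 0.5 mL ripple at 10x frequency must not add periods
  rip <- saw + 0.5 * sin(2 * pi * tt / 100)
  per2 <- meaningful_ejection_periods(list(time = tt, volume = rip))
  expect_equal(nrow(per2), nrow(per))
  expect_equal(mean(per2$edv - per2$esv), 70, tolerance = 0.05)
  # flat trace: no periods, SV = 0
  expect_equal(nrow(meaningful_ejection_periods(
    list(time = tt, volume = rep(100, length(tt))))), 0)
  expect_equal(stroke_volume(list(time = tt, volume = rep(100, length(tt)))), 0)
})

test_that("stroke volume averages the per-period volume drops", {
  tt <- seq(0, 3000)
  v <- rep(80, length(tt))
  v[tt >= 400 & tt < 500] <- 80 + 60 * sin(pi * (tt[tt >= 400 & tt < 500] - 400) / 100)
  v[tt >= 500 & tt < 600] <- 140 - 60 * (tt[tt >= 500 & tt < 600] - 500) / 100
  v[tt >= 1400 & tt < 1500] <- 80 + 40 * sin(pi * (tt[tt >= 1400 & tt < 1500] - 1400) / 100)
  v[tt >= 1500 & tt < 1600] <- 120 - 40 * (tt[tt >= 1500 & tt < 1600] - 1500) / 100
  expect_equal(stroke_volume(list(time = tt, volume = v)), 50, tolerance = 0.1)
})

test_that("stroke volume is non-decreasing in the tension gain", {
  svs <- sapply(c(0.02, 0.05, 0.08, 0.12), function(k) {
    p <- circulation_params(k_lv = k, atrial_period_ms = 1000)
    stroke_volume(run_circulation(p, twitch_1hz(), duration_ms = 8000))
  })
  expect_true(all(diff(svs) >= -1e-6))
})

test_that("negative volumes are reported with the compartment name", {
  p <- circulation_params(Vinit_LA = 6)
  expect_error(run_circulation(p, function(t) 0 * t + 200, duration_ms = 5000),
               "compartment")
})
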
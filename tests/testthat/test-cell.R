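test_that("parameter constructor validates and multipliers compose", {
  p <- cell_params()
  expect_s3_class(p, "cell_params")
  expect_error(cell_params(g_Ks = -1), ">= 0")

  # identity map leaves every field untouched
  q <- apply_conductance_multipliers(p, list())
  expect_identical(unclass(q), unclass(p))

  q <- apply_conductance_multipliers(p, list(g_Ks = 2))
  expect_equal(q$g_Ks, 2 * p$g_Ks)
  expect_equal(q$g_Kr, p$g_Kr)

  expect_error(apply_conductance_multipliers(p, list(g_Na = 2)),
               "only g_Ks and g_Kr")
  expect_error(apply_conductance_multipliers(p, list(g_Ks = 0)), "positive")
  # composition multiplies
  q2 <- apply_conductance_multipliers(q, list(g_Ks = 3))
  expect_equal(q2$multipliers$g_Ks, 6)
})

test_that("mutation preset catalogue has five valid entries", {
  cat <- mutation_presets()
  expect_length(cat, 5)
  expect_error(mutation_preset("KCNQ1-XYZ"), "valid presets")
  for (nm in names(cat)) {
    p <- apply_mutation(cell_params(), nm)
    expect_silent(validate_cell_params(p))
    expect_identical(p$mutation_id, nm)
  }
})

test_that("an unstimulated cell stays at rest", {
  tr <- simulate_cell(cell_params(), n_beats = 5,
                      stim_amplitude_pA_pF = 0)
  expect_true(all(abs(tr$Vm - tr$Vm[1]) < 2))
  # fixed point: negligible drift rate at the end of 5 s
  n <- length(tr$Vm)
  dvdt <- abs(diff(tr$Vm[(n - 100):n])) / diff(tr$time[(n - 100):n])
  expect_true(max(dvdt) < 0.01)
  expect_true(all(tr$Cai >= 0))
})

test_that("APD90 of a triangular AP is 270 ms by linear interpolation", {
  tr <- triangle_trace()
  expect_equal(measure_apd(tr, 0.9), 270, tolerance = 1e-3)
  # fraction scales the repolarization level
  expect_equal(measure_apd(tr, 0.5), 150, tolerance = 1e-3)
})

test_that("a flat trace yields an explicit no-beat result", {
  flat <- list(time = seq(0, 1000), Vm = rep(-86, 1001))
  a <- measure_apd(flat)
  expect_true(is.na(a))
  expect_true(attr(a, "no_beat"))
})

test_that("APD is non-increasing in the g_Ks multiplier", {
  apds <- sapply(c(1, 4, 20, 100), function(m) {
    p <- if (m == 1) cell_params() else
      apply_conductance_multipliers(cell_params(), list(g_Ks = m))
    measure_apd(simulate_cell(p, n_beats = 6))
  })
  expect_true(all(diff(apds) < 0))
})

test_that("halving the time step changes the action potential marginally", {
  a1 <- simulate_cell(cell_params(), n_beats = 2, dt_ms = 0.02)
  a2 <- simulate_cell(cell_params(), n_beats = 2, dt_ms = 0.01)
  expect_lt(abs(measure_apd(a1) - measure_apd(a2)), 1)
  expect_lt(sqrt(mean((a1$Vm - a2$Vm)^2)), 0.5)
})

test_that("gating variables stay in [0,1] and traces export to CSV", {
  tr <- simulate_cell(cell_params(), n_beats = 1)
  vgates <- tr$state[2:11]          # voltage-dependent gates
  expect_true(all(vgates >= 0 & vgates <= 1))
  # the published fCa steady-state formula tops out at 1.53/1.46 ~ 1.05,
  # so that gate's admissible range is [0, 1.05]; g stays in [0, 1]
  expect_gte(tr$state[["fCa"]], 0); expect_lte(tr$state[["fCa"]], 1.05)
  expect_gte(tr$state[["g"]], 0); expect_lte(tr$state[["g"]], 1)
  f <- tempfile(fileext = ".csv")
  write_cell_trace(tr, f)
  d <- read.csv(f)
  expect_identical(names(d), c("time_ms", "Vm_mV", "Cai_mM"))
  expect_equal(nrow(d), length(tr$time))
  unlink(f)
})
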
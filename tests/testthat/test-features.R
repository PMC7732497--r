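test_that("tissue APD feature matches the single-cell oracle on plane waves", {
  cell <- simulate_cell(cell_params(), n_beats = 3)
  apd_cell <- measure_apd(cell, which = "mean")
  rec <- plane_wave_recording(cell, nx = 24, ny = 16)
  apd_tissue <- compute_apd_feature(rec)
  expect_equal(as.numeric(apd_tissue), as.numeric(apd_cell), tolerance = 5 / apd_cell)
  expect_false(attr(apd_tissue, "unreliable"))
  # node reordering leaves the mean unchanged
  rec2 <- rec; perm <- sample(nrow(rec$vm))
  rec2$vm <- rec$vm[perm, ]
  expect_equal(as.numeric(compute_apd_feature(rec2)), as.numeric(apd_tissue))
})

test_that("a quiescent recording flags the APD feature unreliable", {
  rec <- make_recording(matrix(-86, 64, 500), 8, 8)
  a <- compute_apd_feature(rec)
  expect_true(attr(a, "unreliable"))
})

test_that("dominant frequency recovers pure sinusoid frequencies", {
  tt <- seq_len(5000) - 1          # 5 s window: 0.2 Hz bins
  vm <- t(sapply(1:16, function(i) sin(2 * pi * 5.7 * tt / 1000)))
  rec <- make_recording(vm, 4, 4)
  dfs <- compute_df_features(rec)
  bin <- 0.2
  expect_lt(abs(dfs[["DF_mean"]] - 5.7), bin)
  expect_equal(dfs[["DF_std"]], 0)

  # half the nodes at 4 Hz, half at 6 Hz (both on exact bins):
  # mean 5, population SD 1
  f <- rep(c(4, 6), each = 8)
  vm2 <- t(sapply(f, function(fi) sin(2 * pi * fi * tt / 1000)))
  rec2 <- make_recording(vm2, 4, 4)
  d2 <- compute_df_features(rec2)
  expect_equal(d2[["DF_mean"]], 5)
  expect_equal(d2[["DF_std"]], 1)
})

test_that("peak power matches the analytic periodogram of a unit sinusoid", {
  # frequency on an exact bin: P(f0) = amp^2 / 2 under the 2|X|^2/N^2 norm
  n <- 2000
  tt <- seq_len(n) - 1
  f0 <- 5  # Hz; bin spacing 0.5 Hz at 2 s
  vm <- matrix(sin(2 * pi * f0 * tt / 1000), 1)
  rec <- make_recording(rbind(vm, vm, vm, vm * 2), 2, 2)
  d <- suppressWarnings(compute_df_features(rec))  # 2 s window: floor raised
  expect_equal(d[["DF_mean"]], f0, tolerance = 1e-9)
  # three unit nodes (0.5) and one amplitude-2 node (2.0)
  expect_equal(d[["DF_peakP_mean"]], (3 * 0.5 + 2.0) / 4, tolerance = 1e-6)
})

test_that("short windows raise the band floor and too-short windows error", {
  tt <- seq(0, 2000)
  vm <- matrix(sin(2 * pi * 5 * tt / 1000), 1)
  rec <- make_recording(rbind(vm, vm, vm, vm), 2, 2)
  expect_warning(compute_df_features(rec), "band floor")
  tiny <- make_recording(matrix(rnorm(4 * 20), 4), 2, 2)
  expect_error(suppressWarnings(compute_df_features(tiny)))
})

test_that("wavelength is conduction velocity times APD", {
  cell <- simulate_cell(cell_params(), n_beats = 3)
  rec <- plane_wave_recording(cell, nx = 24, ny = 16, delay_ms = 1)
  # 1 node per ms at dx = 0.0125 cm -> 12.5 cm/s
  cv <- conduction_velocity(rec)
  expect_equal(cv, 12.5, tolerance = 0.01)
  wr <- suppressWarnings(compute_wavelength_and_rotation(rec))
  apd <- as.numeric(compute_apd_feature(rec))
  expect_equal(wr[["Wavelength"]], cv * apd / 1000, tolerance = 1e-6)
  # plane waves have no rotor: rotation flagged missing
  expect_true(is.na(wr[["Rotation_rate"]]))
  expect_true(attr(wr, "rotation_missing"))
})

test_that("rotation rate of a rigidly rotating tip is its circumference speed", {
  # tip moving on a circle of radius r with period T: speed 2 pi r / T
  nx <- 41; ny <- 41; Tper <- 200; r <- 6; dt <- 5
  nfr <- 160
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  vm <- matrix(NA_real_, nx * ny, nfr)
  for (f in seq_len(nfr)) {
    ang <- 2 * pi * (f - 1) * dt / Tper
    xc <- 21 + r * cos(ang); yc <- 21 + r * sin(ang)
    vm[, f] <- 40 * cos(atan2(ys - yc, xs - xc))
  }
  rec <- make_recording(vm, nx, ny, dt = dt)
  pm <- list(phase = apply(vm / 40, 2, function(c1) atan2(sqrt(1 - pmin(c1^2, 1)), c1)),
             time = rec$time, mask = rep(TRUE, nx * ny))
  class(pm) <- "phase_map"
  # use the true phase movie directly (sign ambiguity irrelevant to tips)
  base <- sapply(seq_len(nfr), function(f) {
    ang <- 2 * pi * (f - 1) * dt / Tper
    as.vector(atan2(ys - (21 + r * sin(ang)), xs - (21 + r * cos(ang))))
  })
  pm$phase <- base
  wr <- suppressWarnings(compute_wavelength_and_rotation(rec, pm))
  v_true <- 2 * pi * r * rec$geometry$dx / (Tper / 1000)
  expect_equal(wr[["Rotation_rate"]], v_true, tolerance = 0.08)
})

test_that("the assembled feature vector has the 12 named fields and is deterministic", {
  rec <- spiral_movie(n_frames = 2048, period_ms = 175)
  rec$cai <- pmax(rec$vm, 0) * 1e-5
  f1 <- suppressWarnings(assemble_feature_vector(rec))
  f2 <- suppressWarnings(assemble_feature_vector(rec))
  expect_length(f1, 12)
  expect_identical(names(f1), feature_names())
  expect_identical(unclass(f1), unclass(f2))
  expect_true(attr(f1, "filament_from_single_layer"))
  # a single stable spiral: one singularity, no variability
  expect_equal(f1[["PS"]], 1)
  expect_equal(f1[["PS_std"]], 0)
  expect_equal(f1[["Filament"]], 1)
  expect_equal(f1[["Filament_PS_ratio"]], 1)
  # DF of a rigidly rotating spiral equals its rotation frequency (one bin)
  bin <- 1000 / (2048 * 1)
  expect_lt(abs(f1[["DF_mean"]] - 1000 / 175), bin + 1e-9)
})
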
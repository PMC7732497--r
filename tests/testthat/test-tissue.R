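test_that("geometry and protocol constructors validate their inputs", {
  expect_error(tissue_geometry(8, 64), "nx")
  expect_error(build_s1s2_protocol(tissue_geometry(64, 64), "apex", 300),
               "LV-whole")
  g <- tissue_geometry(64, 64)
  # S2 site masks: definitions on a 64x64 sheet
  masks <- lapply(c("LV-whole", "LV-lower", "RV-whole", "RV-lower"),
                  function(s) build_s1s2_protocol(g, s, 300)$s2$nodes)
  lv <- masks[[1]]
  xcol <- ((lv - 1) %% 64) + 1
  expect_true(all(xcol <= 32))          # exactly the 32 left columns
  expect_equal(length(lv), 32 * 64)
  lvlow <- masks[[2]]
  expect_equal(length(lvlow), 32 * 32)  # lower-left quadrant
  expect_true(all(((lvlow - 1) %/% 64) + 1 <= 32))
  # pairwise distinct
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(masks[[i]], masks[[j]]))
})

test_that("the stability bound is enforced with a suggested step", {
  g <- tissue_geometry(16, 16, dx = 0.0125, D = 2e-4)
  expect_error(run_monodomain(g, cell_params(), NULL, duration_ms = 1,
                              dt_ms = 0.3), "stability")
})

test_that("unstimulated tissue stays at rest", {
  g <- tissue_geometry(16, 16)
  rec <- run_monodomain(g, cell_params(), NULL, duration_ms = 300)
  expect_true(all(abs(rec$vm - rec$vm[1, 1]) < 2))
})

test_that("a passive membrane conserves the spatial mean under diffusion", {
  g <- tissue_geometry(24, 24)
  nn <- 24 * 24
  s0 <- matrix(tt_rest_state(), nn, 17, byrow = TRUE)
  s0[, 1] <- rnorm(nn, -60, 15)  # arbitrary voltage pattern
  rec <- run_monodomain(g, cell_params(), NULL, duration_ms = 100,
                        init_state = s0, passive = TRUE)
  means <- colMeans(rec$vm)
  expect_true(all(abs(means - means[1]) < 1e-6))
  # and the pattern relaxes toward uniformity
  expect_lt(sd(rec$vm[, ncol(rec$vm)]), sd(rec$vm[, 1]))
})

test_that("plane-wave activation propagates at the 1D-cable speed", {
  # 1D cable reference at the same D
  g1 <- tissue_geometry(96, 1)
  pr1 <- list(list(nodes = 1:2, start = 5, duration = 2, amplitude = 52))
  rec1 <- run_monodomain(g1, cell_params(), pr1, duration_ms = 120)
  at1 <- vtmech:::.activation_times(rec1$time, rec1$vm)
  # speed from the middle stretch, away from ends
  cv_cable <- (40 - 20) * g1$dx / (at1[40] - at1[20]) * 1000

  g2 <- tissue_geometry(48, 16)
  pr2 <- build_s1s2_protocol(g2, "LV-whole", coupling_interval_ms = 1e6,
                             s1_time_ms = 5)
  rec2 <- run_monodomain(g2, cell_params(), pr2, duration_ms = 120)
  at2 <- vtmech:::.activation_times(rec2$time, rec2$vm)
  A <- matrix(at2, 48, 16)
  # activation time strictly increases with distance from the left edge
  prof <- rowMeans(A[3:46, ])
  expect_true(all(diff(prof) > 0))
  cv_sheet <- conduction_velocity(rec2)
  expect_gt(cv_sheet, 0)
  expect_lt(abs(cv_sheet - cv_cable) / cv_cable, 0.2)
})

test_that("reentry onset is found on a re-activated sheet and is shift-consistent", {
  # synthetic recording: an S2-masked node activates (wave passage) and
  # later re-activates without stimulus -> onset at the re-activation
  g <- tissue_geometry(16, 16)
  pr <- build_s1s2_protocol(g, "LV-lower", coupling_interval_ms = 100,
                            s1_time_ms = 10)
  nfr <- 600
  mk <- function(t0) {
    vm <- matrix(-80, 256, nfr)
    tt <- seq_len(nfr) - 1 + t0
    for (i in 1:256) {
      vm[i, tt >= 130 & tt < 180] <- 10   # S2 wave passage
      vm[i, tt >= 300 & tt < 350] <- 10   # re-activation
    }
    rec <- make_recording(vm, 16, 16, t0 = t0)
    rec$protocol <- pr
    rec
  }
  on <- detect_reentry_onset(mk(0))
  expect_equal(on, 300, tolerance = 2)
  # appending quiescent pre-S1 padding (time axis shifted back) is a no-op
  on2 <- detect_reentry_onset(mk(-50))
  expect_equal(on2, on)

  # extinguished: no second activation -> NA
  vm <- matrix(-80, 256, nfr)
  vm[, 131:180] <- 10
  rec <- make_recording(vm, 16, 16)
  rec$protocol <- pr
  expect_true(is.na(detect_reentry_onset(rec)))

  # recording shorter than S2 -> error
  rec3 <- make_recording(matrix(-80, 256, 50), 16, 16)
  rec3$protocol <- pr
  expect_error(detect_reentry_onset(rec3), "S2")
})

test_that("recordings round-trip through the plain-text archive", {
  g <- tissue_geometry(16, 16)
  rec <- run_monodomain(g, cell_params(), NULL, duration_ms = 20)
  d <- file.path(tempdir(), "rec_archive")
  write_recording(rec, d)
  expect_true(all(file.exists(file.path(d, c("time.csv", "vm.csv",
                                             "cai.csv", "meta.json")))))
  vm2 <- as.matrix(utils::read.csv(file.path(d, "vm.csv")))
  expect_equal(unname(vm2), unname(rec$vm), tolerance = 1e-8)
  unlink(d, recursive = TRUE)
})
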
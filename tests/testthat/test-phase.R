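test_that("analytic-signal phase of a cosine advances at the signal frequency", {
  tt <- seq(0, 2047)
  w <- 2 * pi / 128
  vm <- matrix(cos(w * tt), 1)
  pm <- compute_phase_map(vm)
  ph <- pm$phase[1, ]
  # unwrap and fit the slope away from the window edges
  un <- ph + 2 * pi * cumsum(c(0, diff(ph) < -pi)) -
    2 * pi * cumsum(c(0, diff(ph) > pi))
  mid <- 200:1800
  slope <- coef(lm(un[mid] ~ tt[mid]))[2]
  expect_equal(as.numeric(slope), w, tolerance = 0.02)
})

test_that("constant-signal nodes are masked with phase zero", {
  vm <- rbind(cos(seq(0, 50, by = 0.1)) * 30, rep(-80, 501))
  pm <- compute_phase_map(vm)
  expect_false(pm$mask[2])
  expect_true(pm$mask[1])
  expect_true(all(pm$phase[2, ] == 0))
})

test_that("negating the signal shifts phase by pi (mod 2 pi)", {
  tt <- seq(0, 1023)
  vm <- matrix(cos(2 * pi * tt / 100) + 0.3 * sin(2 * pi * tt / 57), 1)
  p1 <- compute_phase_map(vm)$phase[1, ]
  p2 <- compute_phase_map(-vm)$phase[1, ]
  d <- atan2(sin(p1 - p2), cos(p1 - p2))
  expect_true(all(abs(abs(d) - pi) < 1e-8))
})

test_that("a single point charge yields exactly one +1 singularity at its centre", {
  nx <- 21; ny <- 21
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ph <- atan2(ys - 10.5, xs - 10.5)
  ps <- detect_phase_singularities(ph)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$x, 10.5)
  expect_equal(ps$y, 10.5)
  expect_equal(ps$charge, 1)
  # uniform phase: none
  expect_equal(nrow(detect_phase_singularities(matrix(1.2, 16, 16))), 0)
})

test_that("a counter-rotating pair has two singularities of opposite charge", {
  xs <- matrix(seq_len(28), 28, 28)
  ys <- matrix(seq_len(28), 28, 28, byrow = TRUE)
  ph <- atan2(ys - 14.25, xs - 8.25) - atan2(ys - 14.25, xs - 20.25)
  ph <- atan2(sin(ph), cos(ph))
  ps <- detect_phase_singularities(ph)
  expect_equal(nrow(ps), 2)
  expect_equal(sum(ps$charge), 0)
})

test_that("the detector agrees with the brute-force winding oracle", {
  for (seed in 1:100) {
    nx <- sample(8:32, 1); ny <- sample(8:32, 1)
    ph <- random_charge_field(nx, ny, sample(0:4, 1), seed = seed)
    got <- detect_phase_singularities(ph)
    ref <- winding_oracle(ph)
    expect_equal(nrow(got), nrow(ref))
    if (nrow(ref)) {
      o1 <- order(got$x, got$y); o2 <- order(ref$x, ref$y)
      expect_equal(got$x[o1], ref$x[o2])
      expect_equal(got$y[o1], ref$y[o2])
      expect_equal(got$charge[o1], ref$charge[o2])
    }
  }
})

test_that("total topological charge matches the signed singularity sum", {
  for (seed in 101:110) {
    ph <- random_charge_field(24, 24, sample(1:4, 1), seed = seed)
    ps <- detect_phase_singularities(ph)
    # winding of the domain boundary loop
    edge <- c(ph[1:23, 1], ph[24, 1:23], ph[24:2, 24], ph[1, 24:2], ph[1, 1])
    w <- sum(atan2(sin(diff(edge)), cos(diff(edge)))) / (2 * pi)
    expect_equal(round(w), sum(ps$charge))
  }
})

test_that("singularity count statistics are mean and population SD", {
  ph1 <- random_charge_field(20, 20, 1, seed = 5)
  ph2 <- random_charge_field(20, 20, 3, seed = 6)
  pm <- list(phase = cbind(as.vector(ph1), as.vector(ph2)))
  class(pm) <- "phase_map"
  st <- ps_statistics(pm, frames = 1:2, dims = c(20, 20))
  cnt <- attr(st, "counts")
  expect_equal(st[["PS"]], mean(cnt))
  expect_equal(st[["PS_std"]], sqrt(mean((cnt - mean(cnt))^2)))
  expect_error(ps_statistics(pm, frames = integer(0), dims = c(20, 20)),
               "no frames")
})

test_that("a transmural singularity column is one filament of nz elements", {
  nx <- 17; ny <- 17; nz <- 8
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  layer <- atan2(ys - 8.5, xs - 8.5)
  slab <- array(rep(layer, nz), dim = c(nx, ny, nz))
  f <- detect_filaments(slab)
  expect_equal(f[["elements"]], 8)
  expect_equal(f[["filaments"]], 1)

  # two disjoint columns: 16 elements, 2 filaments
  two <- atan2(ys - 8.5, xs - 4.25) - atan2(ys - 8.5, xs - 12.75)
  two <- atan2(sin(two), cos(two))
  slab2 <- array(rep(two, nz), dim = c(nx, ny, nz))
  f2 <- detect_filaments(slab2)
  expect_equal(f2[["elements"]], 16)
  expect_equal(f2[["filaments"]], 2)

  # quiescent slab: nothing
  f0 <- detect_filaments(array(0.3, dim = c(nx, ny, nz)))
  expect_equal(unname(f0), c(0, 0))

  # 2D input is redirected to the PS path
  expect_error(detect_filaments(layer), "ps_statistics")
})
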
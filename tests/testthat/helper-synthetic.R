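# Synthetic builders shared across tests.  Everything is generated in code;
# no fixture files.

# Wrap a nodes x frames voltage matrix as a minimal vt_recording.
make_recording <- function(vm, nx, ny, nz = 1, dt = 1, dx = 0.0125,
                           cai = NULL, t0 = 0) {
  rec <- list(time = t0 + (seq_len(ncol(vm)) - 1) * dt, vm = vm,
              cai = if (is.null(cai)) pmax(vm * 0, 0) else cai,
              geometry = tissue_geometry(max(nx, 16), max(ny, 16),
                                         max(nz, 1), dx = dx),
              protocol = NULL, dt_ms = dt, reentry_onset_ms = NA_real_)
  rec$geometry$nx <- as.integer(nx); rec$geometry$ny <- as.integer(ny)
  rec$geometry$nz <- as.integer(nz)
  class(rec) <- "vt_recording"
  rec
}

# Triangular action potential: rest, instant upstroke, linear repolarization.
triangle_trace <- function(rest = -86, peak = 40, fall_ms = 300,
                           dt = 0.01, pre_ms = 50, post_ms = 50) {
  t1 <- seq(0, pre_ms, by = dt)
  t2 <- seq(dt, fall_ms, by = dt)
  t3 <- seq(dt, post_ms, by = dt)
  vm <- c(rep(rest, length(t1)),
          peak + (rest - peak) * t2 / fall_ms,
          rep(rest, length(t3)))
  list(time = seq_along(vm) * dt, Vm = vm)
}

# Plane-wave tissue recording built by tiling a single-cell trace with a
# constant conduction delay per column (the single-cell APD is the oracle
# for the tissue APD feature).
plane_wave_recording <- function(cell, nx = 24, ny = 16, delay_ms = 1,
                                 dt = 1) {
  tmax <- max(cell$time)
  tgrid <- seq(0, tmax - (nx - 1) * delay_ms, by = dt)
  vm <- matrix(NA_real_, nx * ny, length(tgrid))
  for (x in seq_len(nx)) {
    v <- approx(cell$time, cell$Vm, xout = tgrid + (x - 1) * delay_ms,
                rule = 2)$y
    for (y in seq_len(ny)) vm[(y - 1) * nx + x, ] <- v
  }
  make_recording(vm, nx, ny, dt = dt)
}

# Rigidly rotating spiral: phase field atan2(y-yc, x-xc) - omega t; the
# voltage movie cos(phase) has DF = rotation frequency at every node.
spiral_movie <- function(nx = 33, ny = 33, n_frames = 2048, dt = 1,
                         period_ms = 175, xc = (nx + 1) / 2,
                         yc = (ny + 1) / 2, amp = 50) {
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  base <- atan2(ys - yc, xs - xc)
  vm <- matrix(NA_real_, nx * ny, n_frames)
  for (f in seq_len(n_frames)) {
    ph <- base - 2 * pi * (f - 1) * dt / period_ms
    vm[, f] <- amp * cos(as.vector(ph))
  }
  make_recording(vm, nx, ny, dt = dt)
}

# Brute-force winding-number oracle: explicit loops and an independent
# angle-wrapping rule (shift by multiples of 2*pi into (-pi, pi]).
winding_oracle <- function(ph, eps = 0.05) {
  wrap <- function(d) {
    d <- d %% (2 * pi)
    d[d > pi] <- d[d > pi] - 2 * pi
    d
  }
  nx <- nrow(ph); ny <- ncol(ph)
  hits <- NULL
  for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) {
    s <- wrap(ph[i + 1, j] - ph[i, j]) + wrap(ph[i + 1, j + 1] - ph[i + 1, j]) +
      wrap(ph[i, j + 1] - ph[i + 1, j + 1]) + wrap(ph[i, j] - ph[i, j + 1])
    if (abs(s) >= 2 * pi * (1 - eps))
      hits <- rbind(hits, c(x = i + 0.5, y = j + 0.5, charge = sign(s)))
  }
  if (is.null(hits)) data.frame(x = numeric(0), y = numeric(0),
                                charge = numeric(0))
  else as.data.frame(hits)
}

# Smooth random phase field (superposition of a few point charges), which
# carries a known set of singularities.
random_charge_field <- function(nx, ny, n_charges, seed) {
  set.seed(seed)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  ph <- matrix(0, nx, ny)
  for (k in seq_len(n_charges)) {
    xc <- runif(1, 2, nx - 1) + 0.25; yc <- runif(1, 2, ny - 1) + 0.25
    q <- sample(c(-1, 1), 1)
    ph <- ph + q * atan2(ys - yc, xs - xc)
  }
  atan2(sin(ph), cos(ph))
}
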
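#' Tissue geometry
#'
#' A regular sheet (or thin slab) of ventricular tissue with isotropic
#' diffusion and no-flux boundaries.  The slab mode (`nz > 1`) exists to
#' give scroll-wave filaments a meaningful 3D definition; the 2D sheet is
#' the default everywhere else.
#'
#' The default spacing and diffusion are desk-scale choices: conduction is
#' slowed (D = 2e-4 cm^2/ms, CV ~ 22 cm/s) so that the excitation
#' wavelength fits a few-centimetre sheet and reentry can be sustained,
#' and dx = 0.0125 cm keeps the wavefront resolved at that speed.
#'
#' @param nx,ny,nz grid dimensions (nx, ny >= 16; nz >= 1; `ny = 1` is
#'   allowed as an explicit 1D-cable mode for convergence references).
#' @param dx grid spacing (cm).
#' @param D diffusion coefficient (cm^2/ms).
#' @return object of class `tissue_geometry`.
#' @export
tissue_geometry <- function(nx = 192, ny = 192, nz = 1, dx = 0.0125,
                            D = 2e-4) {
  stopifnot(nx >= 16, ny == 1 || ny >= 16, nz >= 1, dx > 0, D > 0)
  g <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
            dx = dx, D = D, boundary = "no-flux")
  class(g) <- "tissue_geometry"
  g
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf("<tissue_geometry> %dx%d%s, dx = %g cm, D = %g cm^2/ms, %s boundaries\n",
              x$nx, x$ny, if (x$nz > 1) paste0("x", x$nz) else "",
              x$dx, x$D, x$boundary))
  invisible(x)
}

# node indices (1-based, x fastest) of a rectangular block
.block_nodes <- function(g, xr, yr) {
  idx <- integer(0)
  for (z in seq_len(g$nz)) for (y in yr)
    idx <- c(idx, (z - 1) * g$nx * g$ny + (y - 1) * g$nx + xr)
  sort(idx)
}

#' S1-S2 cross-field stimulation protocol
#'
#' S1 is a plane-wave stimulus along the full left edge of the sheet; S2 is
#' a premature regional stimulus delivered a coupling interval after S1 at
#' one of four sites mapping the anatomical S2 positions (whole/lower left
#' ventricle, whole/lower right ventricle) onto the sheet: left half,
#' lower-left quadrant, right half, lower-right quadrant.
#'
#' @param geometry `tissue_geometry`.
#' @param s2_site_id one of `"LV-whole"`, `"LV-lower"`, `"RV-whole"`,
#'   `"RV-lower"`.
#' @param coupling_interval_ms S1-to-S2 interval (ms), > 0.
#' @param s1_time_ms S1 onset (ms).
#' @param amplitude_pA_pF stimulus amplitude (applies to S1 and S2).
#' @param duration_ms stimulus duration (ms).
#' @return object of class `stimulus_protocol` with 1-based node masks.
#' @export
build_s1s2_protocol <- function(geometry, s2_site_id,
                                coupling_interval_ms,
                                s1_time_ms = 10, amplitude_pA_pF = 52,
                                duration_ms = 2) {
  sites <- c("LV-whole", "LV-lower", "RV-whole", "RV-lower")
  if (!s2_site_id %in% sites)
    stop("invalid S2 site '", s2_site_id, "'; valid sites: ",
         paste(sites, collapse = ", "))
  stopifnot(coupling_interval_ms > 0, amplitude_pA_pF > 0)
  g <- geometry
  lx <- seq_len(floor(g$nx / 2)); rx <- (floor(g$nx / 2) + 1):g$nx
  loy <- seq_len(floor(g$ny / 2)); ally <- seq_len(g$ny)
  s2_nodes <- switch(s2_site_id,
                     "LV-whole" = .block_nodes(g, lx, ally),
                     "LV-lower" = .block_nodes(g, lx, loy),
                     "RV-whole" = .block_nodes(g, rx, ally),
                     "RV-lower" = .block_nodes(g, rx, loy))
  p <- list(
    s1 = list(nodes = .block_nodes(g, 1:2, ally), time = s1_time_ms,
              amplitude = amplitude_pA_pF, duration = duration_ms),
    s2 = list(nodes = s2_nodes, time = s1_time_ms + coupling_interval_ms,
              amplitude = amplitude_pA_pF, duration = duration_ms),
    s2_site_id = s2_site_id, coupling_interval_ms = coupling_interval_ms,
    geometry = g)
  class(p) <- "stimulus_protocol"
  p
}

#' Run a monodomain tissue simulation
#'
#' Explicit monodomain reaction-diffusion:
#' `dVm/dt = D lap(Vm) - I_ion/Cm`, no-flux boundaries, forward Euler with
#' Rush-Larsen gating.  The explicit scheme requires `D dt / dx^2 < 0.25`
#' (0.25 is the 2D von Neumann bound divided by a safety factor of ~2);
#' violating it is refused with the required step size.
#'
#' @param geometry `tissue_geometry`.
#' @param params `cell_params` (uniform over the grid).
#' @param protocol a `stimulus_protocol`, a list of raw stimuli (each with
#'   1-based `nodes`, `start`, `duration`, `amplitude`), or `NULL`.
#' @param duration_ms simulated duration.
#' @param dt_ms integration step (ms).
#' @param record_every_ms recording interval (ms), default 1.
#' @param init_state optional nodes x 17 state matrix to resume from.
#' @param t0_ms absolute time of the first sample (for resumed segments).
#' @param passive if TRUE the membrane is a pure capacitor (no ionic
#'   currents) -- used for diffusion-only conservation checks.
#' @return object of class `vt_recording`: `time` (ms), `vm` and `cai`
#'   (nodes x frames), `geometry`, `protocol`, final `state`, and
#'   `reentry_onset_ms` (NA until [detect_reentry_onset()] is run).
#' @export
run_monodomain <- function(geometry, params, protocol = NULL, duration_ms,
                           dt_ms = 0.02, record_every_ms = 1,
                           init_state = NULL, t0_ms = 0, passive = FALSE) {
  stopifnot(inherits(geometry, "tissue_geometry"))
  g <- geometry
  cfl <- g$D * dt_ms / g$dx^2
  if (cfl >= 0.25)
    stop(sprintf(
      "stability bound violated: D*dt/dx^2 = %.3f >= 0.25; use dt < %.4g ms",
      cfl, 0.25 * g$dx^2 / g$D))
  nn <- g$nx * g$ny * g$nz
  stims <- list()
  if (inherits(protocol, "stimulus_protocol")) {
    stims <- list(
      list(nodes = protocol$s1$nodes - 1L, start = protocol$s1$time - t0_ms,
           duration = protocol$s1$duration, amplitude = protocol$s1$amplitude),
      list(nodes = protocol$s2$nodes - 1L, start = protocol$s2$time - t0_ms,
           duration = protocol$s2$duration, amplitude = protocol$s2$amplitude))
  } else if (!is.null(protocol)) {
    stims <- lapply(protocol, function(s)
      list(nodes = as.integer(s$nodes) - 1L, start = s$start - t0_ms,
           duration = s$duration, amplitude = s$amplitude))
  }
  stims <- Filter(function(s) s$start + s$duration > 0, stims)
  s0 <- if (is.null(init_state))
    matrix(tt_rest_state(), nn, 17, byrow = TRUE) else init_state
  out <- tt_monodomain(c(g$nx, g$ny, g$nz), dx = g$dx, Dcoef = g$D,
                       pars = unclass(params), state0 = s0, stims = stims,
                       duration = duration_ms, dt = dt_ms,
                       record_every = record_every_ms, passive = passive)
  rec <- list(time = out$time + t0_ms, vm = out$vm, cai = out$cai,
              geometry = g, protocol = protocol, params = params,
              dt_ms = dt_ms, state = out$state, reentry_onset_ms = NA_real_)
  class(rec) <- "vt_recording"
  rec
}

#' @export
print.vt_recording <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<vt_recording> %dx%d%s grid, %d frames (%.0f-%.0f ms), Vm range [%.1f, %.1f] mV\n",
              g$nx, g$ny, if (g$nz > 1) paste0("x", g$nz) else "",
              ncol(x$vm), min(x$time), max(x$time), min(x$vm), max(x$vm)))
  if (!is.na(x$reentry_onset_ms))
    cat("  reentry onset:", x$reentry_onset_ms, "ms\n")
  invisible(x)
}

#' Extract one frame as a spatial matrix
#'
#' @param recording `vt_recording`.
#' @param frame frame index.
#' @param what `"vm"` or `"cai"`.
#' @param layer z-layer for slab recordings.
#' @return nx x ny matrix.
#' @export
frame_matrix <- function(recording, frame, what = c("vm", "cai"), layer = 1) {
  what <- match.arg(what)
  g <- recording$geometry
  a <- array(recording[[what]][, frame], dim = c(g$nx, g$ny, g$nz))
  a[, , layer]
}

#' Detect the onset of reentry
#'
#' A node "re-depolarizes" when its membrane potential crosses -20 mV
#' upwards, with no stimulus active, after it has already been activated
#' once following S2 (the first post-S2 activation is the S2/S1 wave
#' passage itself).  The reentry onset is the earliest such re-activation;
#' the episode is reported reentry-free (`NA`) if no re-activation occurs
#' and activity extinguishes (all nodes below -70 mV) within 500 ms of S2.
#'
#' @param recording `vt_recording` whose protocol contains an S2 stimulus.
#' @param threshold_mV activation threshold; default -20.
#' @return onset time in ms, or `NA` if reentry never formed.  The
#'   recording's copy is not modified; assign the result to
#'   `recording$reentry_onset_ms` if wanted.
#' @export
detect_reentry_onset <- function(recording, threshold_mV = -20) {
  pr <- recording$protocol
  if (is.null(pr) || !inherits(pr, "stimulus_protocol"))
    stop("recording carries no S1-S2 protocol")
  s2_end <- pr$s2$time + pr$s2$duration
  tt <- recording$time
  if (max(tt) <= s2_end) stop("recording ends before the S2 stimulus")
  vm <- recording$vm
  post <- which(tt > s2_end)
  if (length(post) < 2) stop("recording ends before the S2 stimulus")
  up <- vm[, post[-length(post)], drop = FALSE] < threshold_mV &
    vm[, post[-1], drop = FALSE] >= threshold_mV
  onset <- NA_real_
  # per node: times of upward crossings after S2; the 2nd+ crossing is reentry
  for (i in seq_len(nrow(up))) {
    w <- which(up[i, ])
    if (length(w) >= 2) {
      cand <- tt[post[w[2] + 1]]
      if (is.na(onset) || cand < onset) onset <- cand
    }
  }
  if (is.na(onset)) {
    # no re-activation; confirm extinction within 500 ms of S2
    late <- which(tt >= s2_end & tt <= s2_end + 500)
    if (length(late) && all(vm[, late[length(late)]] < -70)) return(NA_real_)
    return(NA_real_)
  }
  onset
}

#' Write a recording to a directory of plain-text datasets
#'
#' Datasets `time.csv`, `vm.csv`, `cai.csv` plus a JSON sidecar with the
#' geometry and protocol metadata.
#'
#' @param recording `vt_recording`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(data.frame(time_ms = recording$time),
                   file.path(dir, "time.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(recording$vm), file.path(dir, "vm.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(recording$cai), file.path(dir, "cai.csv"),
                   row.names = FALSE)
  g <- recording$geometry
  meta <- list(nx = g$nx, ny = g$ny, nz = g$nz, dx = g$dx, D = g$D,
               reentry_onset_ms = recording$reentry_onset_ms,
               s2_site = if (!is.null(recording$protocol))
                 recording$protocol$s2_site_id else NULL)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             file.path(dir, "meta.json"))
  invisible(dir)
}
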
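#' Tissue-averaged action potential duration
#'
#' Per node, the repolarization durations (APD90 by default) of every
#' complete action potential in the analysis window are measured and
#' averaged; the feature is the mean of these per-node averages over all
#' nodes that produced at least one complete action potential.  If fewer
#' than 10% of nodes yield an APD the feature is flagged unreliable.
#'
#' @param recording `vt_recording`.
#' @param window optional `c(t0, t1)` (ms).
#' @param repolarization_fraction default 0.9.
#' @return APD in ms, with attributes `n_nodes` (contributing nodes) and
#'   `unreliable` (logical).
#' @export
compute_apd_feature <- function(recording, window = NULL,
                                repolarization_fraction = 0.9) {
  tt <- recording$time; vm <- recording$vm
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]; vm <- vm[, keep, drop = FALSE]
  }
  per_node <- apply(vm, 1, function(v) {
    a <- .apd_all(tt, v, repolarization_fraction)
    if (length(a)) mean(a) else NA_real_
  })
  ok <- !is.na(per_node)
  out <- if (any(ok)) mean(per_node[ok]) else NA_real_
  attr(out, "n_nodes") <- sum(ok)
  attr(out, "unreliable") <- mean(ok) < 0.10
  out
}

#' Dominant-frequency features
#'
#' Per node, the periodogram of the mean-subtracted voltage over the whole
#' analysis window (a single full-window segment, so a 10 s window gives
#' 0.1 Hz resolution).  The dominant frequency (DF) is the frequency of
#' maximum power inside the analysis band, and the peak power is the
#' periodogram value there.  The periodogram is normalized as
#' `P(f) = 2 |X(f)|^2 / N^2`, so a unit-amplitude sinusoid at a bin
#' frequency has peak power 1/2.  Outputs are the mean and population SD
#' over nodes of DF and of peak power.
#'
#' The band floor is raised to `2 / duration` when the window is too short
#' to hold two periods of the nominal floor (with a warning); a window
#' shorter than two periods of the band ceiling is an error.
#'
#' @param recording `vt_recording` (>= 2 s long, uniform sampling).
#' @param window optional `c(t0, t1)` (ms).
#' @param band analysis band in Hz; default `c(0.5, 20)`.
#' @return named vector `c(DF_mean, DF_std, DF_peakP_mean, DF_peakP_std)`
#'   with attribute `df_per_node`.
#' @export
compute_df_features <- function(recording, window = NULL, band = c(0.5, 20)) {
  tt <- recording$time; vm <- recording$vm
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]; vm <- vm[, keep, drop = FALSE]
  }
  n <- length(tt)
  if (n < 8) stop("window too short for spectral analysis")
  dts <- diff(tt[1:2]) / 1000  # s
  dur <- (n - 1) * dts
  if (dur < 2 / band[2])
    stop("window shorter than two periods of the band ceiling")
  floor_hz <- band[1]
  if (dur < 2 / floor_hz) {
    floor_hz <- 2 / dur
    warning(sprintf("window of %.2f s cannot resolve %.2g Hz; band floor raised to %.2g Hz",
                    dur, band[1], floor_hz))
  }
  X <- stats::mvfft(t(vm - rowMeans(vm)))
  P <- 2 * (Mod(X)^2) / n^2
  freqs <- (seq_len(n) - 1) / (n * dts)
  sel <- which(freqs >= floor_hz & freqs <= band[2])
  if (length(sel) < 2) stop("analysis band holds fewer than two frequency bins")
  Pb <- P[sel, , drop = FALSE]
  imax <- max.col(t(Pb), ties.method = "first")
  df <- freqs[sel][imax]
  pk <- Pb[cbind(imax, seq_len(ncol(Pb)))]
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- c(DF_mean = mean(df), DF_std = pop_sd(df),
           DF_peakP_mean = mean(pk), DF_peakP_std = pop_sd(pk))
  attr(out, "df_per_node") <- df
  out
}

# first upward crossing of `threshold` per node within the window, linearly
# interpolated between samples; NA if none
.activation_times <- function(tt, vm, threshold = -20) {
  n <- ncol(vm)
  up <- vm[, -n, drop = FALSE] < threshold & vm[, -1, drop = FALSE] >= threshold
  vapply(seq_len(nrow(vm)), function(i) {
    w <- which(up[i, ])[1]
    if (is.na(w)) return(NA_real_)
    v0 <- vm[i, w]; v1 <- vm[i, w + 1]
    tt[w] + (tt[w + 1] - tt[w]) * (threshold - v0) / (v1 - v0)
  }, numeric(1))
}

#' Conduction velocity from activation-time gradients
#'
#' First-activation times are computed per node (upward crossing of
#' -20 mV); the local speed at each interior node is `1/|grad T|` with the
#' gradient from central differences.  The robust (median) speed over nodes
#' with a finite, non-degenerate gradient is returned in cm/s.
#'
#' @param recording `vt_recording` (2D; slab uses layer 1).
#' @param window optional `c(t0, t1)` (ms).
#' @return CV in cm/s (NA when too few nodes activate).
#' @export
conduction_velocity <- function(recording, window = NULL) {
  g <- recording$geometry
  tt <- recording$time; vm <- recording$vm
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    tt <- tt[keep]; vm <- vm[, keep, drop = FALSE]
  }
  at <- .activation_times(tt, vm)
  Tm <- matrix(at[seq_len(g$nx * g$ny)], g$nx, g$ny)
  if (mean(is.finite(Tm)) < 0.5) return(NA_real_)
  ix <- 2:(g$nx - 1); iy <- 2:(g$ny - 1)
  gx <- (Tm[ix + 1, iy] - Tm[ix - 1, iy]) / (2 * g$dx)
  gy <- if (g$ny >= 3) (Tm[ix, iy + 1] - Tm[ix, iy - 1]) / (2 * g$dx) else 0
  gmag <- sqrt(gx^2 + gy^2)       # ms/cm
  ok <- is.finite(gmag) & gmag > 1e-6
  if (!any(ok)) return(NA_real_)
  stats::median(1000 / gmag[ok])  # cm/s
}

#' Wavelength and rotor rotation rate
#'
#' Wavelength is the distance one excitation wave occupies,
#' `CV (cm/s) x APD (s)`.  The rotation rate is the mean translation speed
#' of tracked phase-singularity tips (cm/s): tips detected per frame are
#' linked greedily to the nearest tip of the previous frame (within
#' `max_jump` nodes) and the mean step speed over all links is reported.
#'
#' @param recording `vt_recording`.
#' @param phase_map matching `phase_map` (computed if missing).
#' @param window optional `c(t0, t1)` (ms).
#' @param max_jump maximum tip displacement per frame pair (node units).
#' @param stride frames between the positions differenced for speed; tip
#'   positions are quantized to plaquette centres, and differencing over a
#'   few frames keeps that quantization from inflating the speed.
#' @return named vector `c(Wavelength, Rotation_rate)`; `Rotation_rate` is
#'   `NA` with attribute `rotation_missing = TRUE` when no tips exist.
#' @export
compute_wavelength_and_rotation <- function(recording, phase_map = NULL,
                                            window = NULL, max_jump = 8,
                                            stride = 3) {
  g <- recording$geometry
  cv <- conduction_velocity(recording, window)
  apd <- compute_apd_feature(recording, window)
  wl <- cv * (as.numeric(apd) / 1000)
  if (is.null(phase_map)) phase_map <- compute_phase_map(recording)
  frames <- seq_len(ncol(phase_map$phase))
  if (!is.null(window))
    frames <- frames[phase_map$time >= window[1] & phase_map$time <= window[2]]
  dtf <- diff(phase_map$time[1:2]) / 1000  # s between frames
  tips <- lapply(frames, function(f)
    detect_phase_singularities(phase_map, f, dims = c(g$nx, g$ny)))
  # greedy frame-to-frame linking into trajectories
  trajs <- list()   # each: list(x =, y =) position series
  active <- integer(0)
  for (k in seq_along(tips)) {
    b <- tips[[k]]
    taken <- rep(FALSE, nrow(b))
    nxt <- integer(0)
    for (ti in active) {
      tr <- trajs[[ti]]
      px <- tr$x[length(tr$x)]; py <- tr$y[length(tr$y)]
      if (nrow(b)) {
        d2 <- (b$x - px)^2 + (b$y - py)^2
        d2[taken] <- Inf
        j <- which.min(d2)
        if (is.finite(d2[j]) && sqrt(d2[j]) <= max_jump) {
          taken[j] <- TRUE
          trajs[[ti]]$x <- c(tr$x, b$x[j]); trajs[[ti]]$y <- c(tr$y, b$y[j])
          nxt <- c(nxt, ti)
        }
      }
    }
    if (nrow(b)) for (j in which(!taken)) {
      trajs[[length(trajs) + 1]] <- list(x = b$x[j], y = b$y[j])
      nxt <- c(nxt, length(trajs))
    }
    active <- nxt
  }
  speeds <- unlist(lapply(trajs, function(tr) {
    m <- length(tr$x)
    if (m <= stride) return(numeric(0))
    i <- seq_len(m - stride)
    sqrt((tr$x[i + stride] - tr$x[i])^2 + (tr$y[i + stride] - tr$y[i])^2) *
      g$dx / (stride * dtf)
  }))
  rot <- if (length(speeds)) mean(speeds) else NA_real_
  out <- c(Wavelength = wl, Rotation_rate = rot)
  if (!length(speeds)) attr(out, "rotation_missing") <- TRUE
  out
}

#' Feature-vector column names
#' @return character vector of the 12 electrical feature names, fixed order.
#' @export
feature_names <- function() c(
  "APD", "Wavelength", "Rotation_rate", "DF_mean", "DF_std",
  "DF_peakP_mean", "DF_peakP_std", "PS", "PS_std", "Filament",
  "Filament_std", "Filament_PS_ratio")

#' Assemble the 12-feature electrical-instability vector
#'
#' Runs all feature extractors on the analysis window (reentry onset to the
#' end of the recording when the onset is known, else the whole recording)
#' and returns the 12 features in fixed order: APD, Wavelength,
#' Rotation_rate, DF_mean, DF_std, DF_peakP_mean, DF_peakP_std, PS, PS_std,
#' Filament, Filament_std, Filament_PS_ratio.
#'
#' For 2D recordings the filament element count of a frame degenerates to
#' its PS count (a single-layer slab); this is flagged in the
#' `filament_from_single_layer` attribute.  `Filament_PS_ratio` is the
#' ratio of the average filament element count to the average PS count.
#'
#' @param recording `vt_recording`.
#' @param window optional `c(t0, t1)` (ms); default: reentry onset to end.
#' @param phase_method passed to [compute_phase_map()].
#' @return named numeric vector of length 12 (class `feature_vector`).
#' @export
assemble_feature_vector <- function(recording, window = NULL,
                                    phase_method = "hilbert") {
  g <- recording$geometry
  if (is.null(window)) {
    t0 <- if (!is.na(recording$reentry_onset_ms)) recording$reentry_onset_ms
          else min(recording$time)
    window <- c(t0, max(recording$time))
  }
  pm <- compute_phase_map(recording, method = phase_method)
  frames <- which(pm$time >= window[1] & pm$time <= window[2])

  apd <- compute_apd_feature(recording, window)
  dfs <- compute_df_features(recording, window)
  wlr <- compute_wavelength_and_rotation(recording, pm, window)
  pss <- ps_statistics(pm, frames, dims = c(g$nx, g$ny))

  if (g$nz > 1) {
    fil <- vapply(frames, function(f)
      detect_filaments(pm, f)[["elements"]], numeric(1))
    single_layer <- FALSE
  } else {
    fil <- attr(pss, "counts")
    single_layer <- TRUE
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  fv <- c(APD = as.numeric(apd),
          wlr[["Wavelength"]], wlr[["Rotation_rate"]],
          dfs[["DF_mean"]], dfs[["DF_std"]],
          dfs[["DF_peakP_mean"]], dfs[["DF_peakP_std"]],
          pss[["PS"]], pss[["PS_std"]],
          mean(fil), pop_sd(fil),
          if (pss[["PS"]] > 0) mean(fil) / pss[["PS"]] else NA_real_)
  names(fv) <- feature_names()
  attr(fv, "filament_from_single_layer") <- single_layer
  attr(fv, "apd_unreliable") <- isTRUE(attr(apd, "unreliable"))
  class(fv) <- c("feature_vector", class(fv))
  fv
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector>\n")
  print(round(unclass(x), 4))
  invisible(x)
}
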
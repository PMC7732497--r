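#' Lumped-parameter circulation parameters
#'
#' A closed-loop circulation with four elastance chambers (LA, LV, RA, RV),
#' four vascular compartments (systemic artery SA, systemic vein SV,
#' pulmonary artery PA, pulmonary vein PV) and four ideal one-way valves
#' (mitral MI, aortic AO, tricuspid TR, pulmonary PU).  Ventricular
#' contraction is driven by spatial-mean active tension through a
#' time-varying elastance, `E_LV(t) = E_lv_base + k_lv * T(t)` (mmHg/mL,
#' T in kPa); this elastance surrogate replaces finite-element wall
#' mechanics.  The atria follow a fixed low-amplitude timing function.
#'
#' Defaults are tuned so that a normal 1 Hz twitch drive produces a stroke
#' volume of roughly 60-80 mL, while the weak, disorganized tension of
#' fibrillating tissue produces stroke volumes near zero.
#'
#' @param ... overrides of any default constant (see the function body for
#'   the complete list: compliances `C_*` (mL/mmHg), resistances `R_*`
#'   (mmHg s/mL), base elastances `E_*_base` (mmHg/mL), tension gains
#'   `k_lv`, `k_rv` (mmHg/mL/kPa), unstressed volumes `V0_*` (mL), initial
#'   volumes `Vinit_*` (mL), atrial timing constants).
#' @return object of class `circulation_params`.
#' @export
circulation_params <- function(...) {
  p <- list(
    # valves
    R_MI = 0.005, R_AO = 0.006, R_TR = 0.005, R_PU = 0.006,
    # vascular resistances and compliances
    R_sys = 1.0, R_ven = 0.05, R_pul = 0.08, R_pvein = 0.01,
    C_SA = 1.5, C_SV = 50, C_PA = 4, C_PV = 10,
    # chamber elastances
    E_lv_base = 0.08, E_rv_base = 0.05,
    E_la_base = 0.15, E_la_amp = 0.12,
    E_ra_base = 0.12, E_ra_amp = 0.10,
    k_lv = 0.07, k_rv = 0.018,
    atrial_period_ms = 800, atrial_duration_ms = 150,
    # unstressed volumes
    V0_LV = 10, V0_RV = 10, V0_LA = 5, V0_RA = 5,
    V0_SA = 600, V0_SV = 2800, V0_PA = 100, V0_PV = 400,
    # initial volumes
    Vinit_LV = 120, Vinit_RV = 120, Vinit_LA = 60, Vinit_RA = 60,
    Vinit_SA = 700, Vinit_SV = 3000, Vinit_PA = 140, Vinit_PV = 500
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown circulation parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  vals <- unlist(p)
  if (any(!is.finite(vals)))
    stop("circulation parameters must be finite")
  pos <- unlist(p[grep("^(R|C|E|k)_", names(p))])
  if (any(pos <= 0)) stop("compliances, resistances, elastances and gains must be > 0")
  p$total_volume <- with(p, Vinit_LV + Vinit_RV + Vinit_LA + Vinit_RA +
                           Vinit_SA + Vinit_SV + Vinit_PA + Vinit_PV)
  class(p) <- "circulation_params"
  p
}

#' Run the closed-loop circulation
#'
#' Forward-Euler integration of the eight compartment volumes.  Chamber
#' pressures are `E(t) (V - V0)`; vessel pressures `(V - V0)/C`; valve
#' flows are one-way (`max(dP, 0)/R`), inter-vessel flows bidirectional.
#' Total blood volume is conserved exactly by construction (every flow
#' leaves one compartment and enters another).
#'
#' @param params `circulation_params`.
#' @param driving_tension either a function of time (ms -> kPa) or a list
#'   with `time` (ms) and `tension` (kPa, spatial-mean active tension),
#'   linearly interpolated.  Must be >= 0.
#' @param duration_ms simulated duration (ms).
#' @param dt_ms step, must be <= 1 ms.
#' @return object of class `hemo_trace`: data frame with time (ms),
#'   per-compartment pressures (mmHg) and volumes (mL) and valve flows
#'   (mL/s), plus attribute `params`.
#' @export
#' @examples
#' drv <- function(t) 30 * pmax(sin(2 * pi * t / 1000), 0)^2
#' h <- run_circulation(circulation_params(), drv, duration_ms = 3000)
#' stroke_volume(h)
run_circulation <- function(params = circulation_params(), driving_tension,
                            duration_ms, dt_ms = 1) {
  stopifnot(inherits(params, "circulation_params"), dt_ms <= 1, dt_ms > 0)
  p <- params
  tfun <- if (is.function(driving_tension)) driving_tension else {
    tt <- driving_tension$time; xx <- driving_tension$tension
    function(t) approx(tt, xx, xout = t, rule = 2)$y
  }
  n <- floor(duration_ms / dt_ms) + 1
  tgrid <- (seq_len(n) - 1) * dt_ms
  Tdrv <- tfun(tgrid)
  if (any(!is.finite(Tdrv)) || any(Tdrv < 0))
    stop("driving tension must be finite and >= 0")

  # atrial activation: half-cosine pulse of fixed period and duration
  phi <- (tgrid %% p$atrial_period_ms) / p$atrial_duration_ms
  act_a <- ifelse(phi < 1, 0.5 * (1 - cos(2 * pi * phi)), 0)

  nm <- c("LV", "RV", "LA", "RA", "SA", "SV", "PA", "PV")
  V <- c(p$Vinit_LV, p$Vinit_RV, p$Vinit_LA, p$Vinit_RA,
         p$Vinit_SA, p$Vinit_SV, p$Vinit_PA, p$Vinit_PV)
  names(V) <- nm
  Pr <- matrix(NA_real_, n, 8, dimnames = list(NULL, nm))
  Vo <- matrix(NA_real_, n, 8, dimnames = list(NULL, nm))
  Qv <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("MI", "AO", "TR", "PU")))
  dts <- dt_ms / 1000  # flows are in mL/s

  for (i in seq_len(n)) {
    E_lv <- p$E_lv_base + p$k_lv * Tdrv[i]
    E_rv <- p$E_rv_base + p$k_rv * Tdrv[i]
    E_la <- p$E_la_base + p$E_la_amp * act_a[i]
    E_ra <- p$E_ra_base + p$E_ra_amp * act_a[i]
    P_LV <- E_lv * (V["LV"] - p$V0_LV)
    P_RV <- E_rv * (V["RV"] - p$V0_RV)
    P_LA <- E_la * (V["LA"] - p$V0_LA)
    P_RA <- E_ra * (V["RA"] - p$V0_RA)
    P_SA <- (V["SA"] - p$V0_SA) / p$C_SA
    P_SV <- (V["SV"] - p$V0_SV) / p$C_SV
    P_PA <- (V["PA"] - p$V0_PA) / p$C_PA
    P_PV <- (V["PV"] - p$V0_PV) / p$C_PV

    q_MI <- max(P_LA - P_LV, 0) / p$R_MI
    q_AO <- max(P_LV - P_SA, 0) / p$R_AO
    q_TR <- max(P_RA - P_RV, 0) / p$R_TR
    q_PU <- max(P_RV - P_PA, 0) / p$R_PU
    q_sys <- (P_SA - P_SV) / p$R_sys
    q_ven <- (P_SV - P_RA) / p$R_ven
    q_pul <- (P_PA - P_PV) / p$R_pul
    q_pv  <- (P_PV - P_LA) / p$R_pvein

    Pr[i, ] <- c(P_LV, P_RV, P_LA, P_RA, P_SA, P_SV, P_PA, P_PV)
    Vo[i, ] <- V
    Qv[i, ] <- c(q_MI, q_AO, q_TR, q_PU)

    V["LV"] <- V["LV"] + dts * (q_MI - q_AO)
    V["SA"] <- V["SA"] + dts * (q_AO - q_sys)
    V["SV"] <- V["SV"] + dts * (q_sys - q_ven)
    V["RA"] <- V["RA"] + dts * (q_ven - q_TR)
    V["RV"] <- V["RV"] + dts * (q_TR - q_PU)
    V["PA"] <- V["PA"] + dts * (q_PU - q_pul)
    V["PV"] <- V["PV"] + dts * (q_pul - q_pv)
    V["LA"] <- V["LA"] + dts * (q_pv - q_MI)

    if (any(V < 0)) {
      neg <- nm[which(V < 0)[1]]
      stop("circulation failure: negative volume in compartment ", neg,
           " at t = ", round(tgrid[i], 1), " ms")
    }
  }
  res <- list(time = tgrid, pressures = Pr, volumes = Vo, valve_flows = Qv,
              tension = Tdrv, params = p)
  class(res) <- "hemo_trace"
  res
}

#' @export
print.hemo_trace <- function(x, ...) {
  cat(sprintf("<hemo_trace> %.0f ms; LV volume [%.1f, %.1f] mL; LV pressure [%.1f, %.1f] mmHg\n",
              max(x$time), min(x$volumes[, "LV"]), max(x$volumes[, "LV"]),
              min(x$pressures[, "LV"]), max(x$pressures[, "LV"])))
  invisible(x)
}

#' Export a hemodynamic trace as CSV
#' @param trace `hemo_trace`; @param file output path.
#' @return `file`, invisibly.
#' @export
write_hemo_trace <- function(trace, file) {
  df <- data.frame(time_ms = trace$time)
  for (n in colnames(trace$pressures)) df[[paste0("P_", n)]] <- trace$pressures[, n]
  for (n in colnames(trace$volumes)) df[[paste0("V_", n)]] <- trace$volumes[, n]
  for (n in colnames(trace$valve_flows)) df[[paste0("Q_", n)]] <- trace$valve_flows[, n]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Meaningful ejection periods of the left ventricle
#'
#' Finds (end-diastole, end-systole) pairs on the LV volume trace: local
#' maxima (EDV) with prominence at least `prominence_frac * resting_edv`,
#' each paired with the following local minimum (ESV).  Small ripples below
#' the prominence threshold are ignored, so only ejections during which
#' blood meaningfully moved in and out of the ventricle are counted.
#'
#' @param lv_volume a `hemo_trace` or a list with `time` and `volume`.
#' @param prominence_frac prominence threshold as a fraction of
#'   `resting_edv`; default 0.02.
#' @param resting_edv reference end-diastolic volume (mL); default 120.
#' @return data frame with columns `t_ed`, `t_es`, `edv`, `esv` (possibly
#'   zero rows).
#' @export
meaningful_ejection_periods <- function(lv_volume, prominence_frac = 0.02,
                                        resting_edv = 120) {
  if (inherits(lv_volume, "hemo_trace")) {
    tt <- lv_volume$time; v <- lv_volume$volumes[, "LV"]
  } else { tt <- lv_volume$time; v <- lv_volume$volume }
  stopifnot(length(v) == length(tt), length(v) > 2)
  thr <- prominence_frac * resting_edv
  v <- as.numeric(v)
  pk <- find_peaks(v, min_prominence = thr)
  tr <- find_peaks(-v, min_prominence = thr)
  empty <- data.frame(t_ed = numeric(0), t_es = numeric(0),
                      edv = numeric(0), esv = numeric(0))
  if (!length(pk) || !length(tr)) return(empty)
  out <- empty
  for (i in seq_along(pk)) {
    ied <- pk[i]
    nxt <- tr[tr > ied]
    if (!length(nxt)) break
    # the minimum must precede the next retained maximum
    if (i < length(pk) && nxt[1] > pk[i + 1]) next
    out <- rbind(out, data.frame(t_ed = tt[ied], t_es = tt[nxt[1]],
                                 edv = v[ied], esv = v[nxt[1]]))
  }
  out
}

#' Local maxima with a prominence threshold
#'
#' Indices of local maxima whose topographic prominence (height above the
#' higher of the two bounding saddles, where a saddle is the minimum
#' between the peak and the nearest higher point on that side, or the trace
#' end) reaches `min_prominence`.
#'
#' @param x numeric vector.
#' @param min_prominence minimum prominence (same units as `x`).
#' @return integer vector of peak indices.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(x))) < 0) + 1
  # plateaus: keep the first sample of any flat top
  cand <- cand[x[cand] > x[cand - 1] | x[cand] > x[cand + 1]]
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- x[i]
    j <- i - 1; lmin <- h
    while (j >= 1 && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1 }
    if (j < 1) lmin <- min(x[1:i])
    j <- i + 1; rmin <- h
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1 }
    if (j > n) rmin <- min(x[i:n])
    keep[k] <- (h - max(lmin, rmin)) >= min_prominence
  }
  cand[keep]
}

#' Stroke volume over meaningful ejection periods
#'
#' Mean of (EDV - ESV) over the meaningful ejection periods of the LV
#' volume trace; 0 if there are none (a fibrillating ventricle that never
#' meaningfully ejects).
#'
#' @inheritParams meaningful_ejection_periods
#' @return stroke volume (mL).
#' @export
stroke_volume <- function(lv_volume, prominence_frac = 0.02,
                          resting_edv = 120) {
  per <- meaningful_ejection_periods(lv_volume, prominence_frac, resting_edv)
  if (!nrow(per)) return(0)
  mean(per$edv - per$esv)
}
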
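#' Crossbridge model parameters
#'
#' Parameters of the calcium-driven four-state crossbridge scheme
#' N_xb <-> P_xb <-> XB_PreR <-> XB_PostR used to convert intracellular
#' calcium into active tension.  The non-permissive/permissive transition is
#' steeply cooperative in bound troponin calcium: the forward rate is
#' `K_np * (TCa/TCa_ref)^7.5` and the backward rate
#' `K_pn * (TCa/TCa_ref)^-7.5`, both clipped at `rate_cap` (the negative
#' exponent diverges as TCa -> 0).  Crossbridge cycling uses attachment
#' `f_aapT`, reverse attachment `g_aapT`, forward/backward rotation
#' `h_fT`/`h_bT` and ATP-consuming detachment `g_xbT`.  Bound troponin
#' calcium follows a single-site buffer ODE
#' `dTCa/dt = k_on Cai (1 - TCa) - k_off TCa`.  The model is isometric:
#' tension is proportional to the post-rotation occupancy,
#' `T = tension_scale * XB_PostR`.
#'
#' @param f_aapT,g_aapT,h_fT,h_bT,g_xbT crossbridge cycling rates (1/ms).
#' @param K_np,K_pn permissivity transition rate scales (1/ms).
#' @param coop_exponent cooperativity exponent (7.5).
#' @param TCa_ref reference troponin saturation at which the permissivity
#'   rates equal their scales.
#' @param rate_cap upper clip for the cooperative rates (1/ms).
#' @param k_on troponin calcium on-rate (1/(mM ms)).
#' @param k_off troponin calcium off-rate (1/ms).
#' @param tension_scale tension per unit XB_PostR occupancy (kPa).
#' @return object of class `xb_params`.
#' @export
xb_params <- function(f_aapT = 0.5, g_aapT = 0.07, h_fT = 2.0, h_bT = 0.4,
                      g_xbT = 0.07, K_np = 0.04, K_pn = 0.03,
                      coop_exponent = 7.5, TCa_ref = 0.25, rate_cap = 5,
                      k_on = 40, k_off = 0.06, tension_scale = 60) {
  p <- list(f_aapT = f_aapT, g_aapT = g_aapT, h_fT = h_fT, h_bT = h_bT,
            g_xbT = g_xbT, K_np = K_np, K_pn = K_pn,
            coop_exponent = coop_exponent, TCa_ref = TCa_ref,
            rate_cap = rate_cap, k_on = k_on, k_off = k_off,
            tension_scale = tension_scale)
  rates <- unlist(p[c("f_aapT", "g_aapT", "h_fT", "h_bT", "g_xbT",
                      "K_np", "K_pn", "k_on", "k_off")])
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all crossbridge rates must be finite and >= 0")
  class(p) <- "xb_params"
  p
}

.xb_perm_rates <- function(tca, p) {
  x <- pmax(tca, 1e-12) / p$TCa_ref
  xe <- x^p$coop_exponent
  list(knp = pmin(p$K_np * xe, p$rate_cap),
       kpn = pmin(p$K_pn / xe, p$rate_cap))
}

#' Simulate active tension from a calcium transient
#'
#' Integrates the four-state crossbridge chain (forward Euler, occupancy
#' conservation enforced exactly by tracking three states and setting
#' `N_xb = 1 - P_xb - XB_PreR - XB_PostR`) for one cell or a population of
#' cells sharing a time axis.  Calcium is linearly interpolated onto the
#' integration grid.
#'
#' @param ca_trace either a list with `time` (ms) and `cai` (mM, vector for
#'   one cell or matrix cells x time), or a `cell_trace` (its `Cai` is used).
#' @param params `xb_params`.
#' @param dt_ms integration step, must be <= 0.1 ms.
#' @param output_every_ms output sampling of the tension trace (default:
#'   the calcium trace's own grid).
#' @return object of class `tension_trace`: list with `time` (ms),
#'   `tension` (kPa, cells x time matrix), and final `state` (list of
#'   occupancy vectors `P`, `PreR`, `PostR`, `N`, `TCa`).
#' @export
simulate_tension <- function(ca_trace, params = xb_params(), dt_ms = 0.05,
                             output_every_ms = NULL) {
  stopifnot(dt_ms <= 0.1, dt_ms > 0)
  if (inherits(ca_trace, "cell_trace"))
    ca_trace <- list(time = ca_trace$time, cai = ca_trace$Cai)
  tin <- as.numeric(ca_trace$time)
  cai <- ca_trace$cai
  if (is.null(dim(cai))) cai <- matrix(cai, nrow = 1)
  if (any(cai < 0) || any(!is.finite(cai)))
    stop("calcium must be finite and >= 0")
  nc <- nrow(cai)
  if (is.null(output_every_ms))
    tout <- tin
  else
    tout <- seq(tin[1], tin[length(tin)], by = output_every_ms)

  p <- params
  P <- numeric(nc); R1 <- numeric(nc); R2 <- numeric(nc); TCa <- numeric(nc)
  nstep <- ceiling((tin[length(tin)] - tin[1]) / dt_ms)
  tension <- matrix(NA_real_, nc, length(tout))
  iout <- 1
  tnow <- tin[1]
  # precompute interpolation indices lazily via linear mapping of uniform grid
  uniform <- length(tin) > 1 && diff(range(diff(tin))) < 1e-8
  dtin <- if (length(tin) > 1) tin[2] - tin[1] else 1
  interp_ca <- function(tq) {
    if (uniform) {
      f <- (tq - tin[1]) / dtin
      i0 <- pmin(floor(f) + 1, length(tin) - 1)
      w <- f - (i0 - 1)
      cai[, i0] * (1 - w) + cai[, i0 + 1] * w
    } else {
      apply(cai, 1, function(r) approx(tin, r, xout = tq, rule = 2)$y)
    }
  }
  if (length(tin) == 1) interp_ca <- function(tq) cai[, 1]

  for (k in seq_len(nstep + 1)) {
    # output before stepping so t = tin[1] is recorded
    while (iout <= length(tout) && tout[iout] <= tnow + dt_ms / 2) {
      tension[, iout] <- p$tension_scale * R2
      iout <- iout + 1
    }
    if (k > nstep) break
    ca <- interp_ca(tnow)
    N <- 1 - P - R1 - R2
    pr <- .xb_perm_rates(TCa, p)
    dP <- pr$knp * N - pr$kpn * P - p$f_aapT * P + p$g_aapT * R1 +
      p$g_xbT * R2
    dR1 <- p$f_aapT * P - (p$g_aapT + p$h_fT) * R1 + p$h_bT * R2
    dR2 <- p$h_fT * R1 - (p$h_bT + p$g_xbT) * R2
    dT <- p$k_on * ca * (1 - TCa) - p$k_off * TCa
    P <- P + dt_ms * dP; R1 <- R1 + dt_ms * dR1; R2 <- R2 + dt_ms * dR2
    TCa <- TCa + dt_ms * dT
    if (k %% 100 == 0 || k == nstep) {
      N <- 1 - P - R1 - R2
      if (min(P, R1, R2, N) < -1e-6 || max(P, R1, R2, N) > 1 + 1e-6)
        stop("integration failure: crossbridge occupancy left [0,1] at t = ",
             round(tnow, 3), " ms")
    }
    tnow <- tnow + dt_ms
  }
  out <- list(time = tout, tension = tension,
              state = list(P = P, PreR = R1, PostR = R2,
                           N = 1 - P - R1 - R2, TCa = TCa))
  class(out) <- "tension_trace"
  out
}

#' @export
print.tension_trace <- function(x, ...) {
  cat(sprintf("<tension_trace> %d cell(s), %.0f ms; tension range [%.3g, %.3g] kPa\n",
              nrow(x$tension), max(x$time) - min(x$time),
              min(x$tension), max(x$tension)))
  invisible(x)
}

#' Algebraic steady state of the crossbridge chain
#'
#' For a constant calcium concentration, solves the troponin buffer fixed
#' point and then the linear fixed point of the four-state rate matrix
#' exactly.  Serves as the independent oracle for the time integrator: the
#' simulated plateau under constant calcium must agree with this solution.
#'
#' @param params `xb_params`.
#' @param cai constant calcium (mM).
#' @return list with `TCa`, occupancies `N`, `P`, `PreR`, `PostR`, and
#'   `tension` (kPa).
#' @export
xb_steady_state <- function(params = xb_params(), cai) {
  p <- params
  tca <- p$k_on * cai / (p$k_on * cai + p$k_off)
  pr <- .xb_perm_rates(tca, p)
  # unknowns x = (N, P, PreR, PostR); rows: 3 balance equations + conservation
  A <- rbind(
    c(-pr$knp, pr$kpn, 0, 0),                                   # N balance
    c(pr$knp, -(pr$kpn + p$f_aapT), p$g_aapT, p$g_xbT),         # P balance
    c(0, p$f_aapT, -(p$g_aapT + p$h_fT), p$h_bT),               # PreR balance
    c(1, 1, 1, 1))
  b <- c(0, 0, 0, 1)
  x <- solve(A, b)
  list(TCa = tca, N = x[1], P = x[2], PreR = x[3], PostR = x[4],
       tension = p$tension_scale * x[4])
}

#' Tension-variability output (ampTens)
#'
#' The per-cell standard deviation of active tension over the analysis
#' window, averaged across cells.  The population (denominator n) standard
#' deviation is used so that, e.g., a sinusoid of amplitude A sampled over
#' whole periods gives exactly A/sqrt(2).
#'
#' @param tension a `tension_trace`, or a cells x time numeric matrix.
#' @param window optional `c(t0, t1)` (ms) restricting the analysis window
#'   (requires a `tension_trace`).
#' @return ampTens in kPa.
#' @export
amp_tens <- function(tension, window = NULL) {
  if (inherits(tension, "tension_trace")) {
    m <- tension$tension
    if (!is.null(window)) {
      keep <- tension$time >= window[1] & tension$time <= window[2]
      m <- m[, keep, drop = FALSE]
    }
  } else m <- as.matrix(tension)
  if (!length(m) || nrow(m) < 1 || ncol(m) < 1)
    stop("amp_tens needs at least one cell and one sample")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  mean(apply(m, 1, pop_sd))
}
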
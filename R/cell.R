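#' Ionic-model parameters for a human ventricular cell
#'
#' Builds the parameter set of the ten Tusscher-type human ventricular
#' ionic model used throughout the package: maximal conductances of the
#' major sarcolemmal currents, pump/exchanger maxima, and the SERCA uptake
#' rate.  Baseline values are the published epicardial set; the endocardial
#' and mid-myocardial variants differ in the transient-outward and
#' slow-delayed-rectifier conductances and the inactivation kinetics of the
#' transient-outward current.
#'
#' @param cell_type one of `"epi"`, `"endo"`, `"M"`.
#' @param multipliers named list of positive scalars applied to conductances
#'   (normally `g_Ks` / `g_Kr`; see [apply_conductance_multipliers()]).
#' @param mutation_id optional name of a mutation preset already applied to
#'   this parameter set (bookkeeping only).
#' @param ... baseline parameter overrides (e.g. `g_Ks = 0.5`).
#'
#' @return An object of class `cell_params`: a named list of conductances
#'   (nS/pF), pump maxima, membrane capacitance `Cm` (uF/cm^2), the
#'   multiplier map and the cell type.
#' @export
#' @examples
#' p <- cell_params()
#' p$g_Ks
cell_params <- function(cell_type = c("epi", "endo", "M"),
                        multipliers = list(), mutation_id = NULL, ...) {
  cell_type <- match.arg(cell_type)
  base <- list(
    g_Na   = 14.838,
    g_CaL  = 0.000175,
    g_to   = switch(cell_type, epi = 0.294, endo = 0.073, M = 0.294),
    g_Ks   = switch(cell_type, epi = 0.245, endo = 0.245, M = 0.062),
    g_Kr   = 0.096,
    g_K1   = 5.405,
    p_NaK  = 1.362,
    k_NaCa = 1000,
    g_pCa  = 0.825,
    g_pK   = 0.0146,
    g_bNa  = 0.00029,
    g_bCa  = 0.000592,
    V_maxup = 0.000425,
    Cm     = 1.0
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(base))
    if (length(unknown))
      stop("unknown cell parameter(s): ", paste(unknown, collapse = ", "))
    base[names(dots)] <- dots
  }
  p <- c(base, list(cell_type = cell_type, multipliers = list(),
                    mutation_id = mutation_id))
  class(p) <- "cell_params"
  p <- .apply_mults(p, multipliers, record = TRUE)
  validate_cell_params(p)
  p
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> ", x$cell_type, " ventricular cell\n", sep = "")
  cat(sprintf("  g_Na %.3f  g_CaL %.3g  g_to %.3f  g_Ks %.4g  g_Kr %.4g  g_K1 %.3f\n",
              x$g_Na, x$g_CaL, x$g_to, x$g_Ks, x$g_Kr, x$g_K1))
  if (length(x$multipliers))
    cat("  multipliers:", paste(names(x$multipliers),
                                unlist(x$multipliers), sep = "x", collapse = ", "), "\n")
  if (!is.null(x$mutation_id)) cat("  mutation preset:", x$mutation_id, "\n")
  invisible(x)
}

#' Validate a cell parameter set
#'
#' Checks non-negativity of all conductances and positivity of the
#' multiplier map; called by every constructor and preset loader.
#'
#' @param p a `cell_params` object.
#' @return `p`, invisibly, or an error.
#' @export
validate_cell_params <- function(p) {
  stopifnot(inherits(p, "cell_params"))
  gfields <- c("g_Na", "g_CaL", "g_to", "g_Ks", "g_Kr", "g_K1", "p_NaK",
               "k_NaCa", "g_pCa", "g_pK", "g_bNa", "g_bCa", "V_maxup", "Cm")
  vals <- unlist(p[gfields])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("cell parameters must be finite and >= 0")
  if (length(p$multipliers) && any(unlist(p$multipliers) <= 0))
    stop("conductance multipliers must be > 0")
  invisible(p)
}

.apply_mults <- function(params, mults, record = TRUE) {
  if (!length(mults)) return(params)
  for (ch in names(mults)) {
    m <- mults[[ch]]
    if (!is.numeric(m) || length(m) != 1 || !is.finite(m) || m <= 0)
      stop("multiplier for ", ch, " must be a positive scalar")
    if (is.null(params[[ch]]))
      stop("unknown channel: ", ch)
    params[[ch]] <- params[[ch]] * m
    if (record) {
      prev <- params$multipliers[[ch]]
      params$multipliers[[ch]] <- if (is.null(prev)) m else prev * m
    }
  }
  params
}

#' Scale potassium-channel conductances
#'
#' Returns a new parameter set with the listed conductances multiplied by
#' positive factors.  By default only the delayed-rectifier conductances
#' `g_Ks` and `g_Kr` may be scaled, matching the study design in which
#' tachyarrhythmia variability is created by up-scaling those channels
#' 2- to 100-fold; set `allow_any = TRUE` to scale other channels (used by
#' the mutation presets).
#'
#' @param params a `cell_params` object.
#' @param mults named list or vector, e.g. `list(g_Ks = 100, g_Kr = 2)`.
#' @param allow_any allow channels other than `g_Ks`/`g_Kr`.
#' @return a new `cell_params` object; the input is not modified.
#' @export
#' @examples
#' p <- apply_conductance_multipliers(cell_params(), list(g_Ks = 2))
apply_conductance_multipliers <- function(params, mults, allow_any = FALSE) {
  stopifnot(inherits(params, "cell_params"))
  mults <- as.list(mults)
  if (!length(mults)) return(params)
  if (is.null(names(mults)) || any(!nzchar(names(mults))))
    stop("multipliers must be named by channel")
  if (!allow_any) {
    bad <- setdiff(names(mults), c("g_Ks", "g_Kr"))
    if (length(bad))
      stop("only g_Ks and g_Kr may be scaled (got ",
           paste(bad, collapse = ", "), "); use allow_any = TRUE to override")
  }
  out <- .apply_mults(params, mults, record = TRUE)
  validate_cell_params(out)
  out
}

#' Mutation preset catalogue
#'
#' The five inherited channelopathies studied (three KCNQ1 variants acting
#' on the slow delayed rectifier and two hERG variants acting on the rapid
#' delayed rectifier) ship as an editable JSON catalogue of conductance-level
#' overrides.  The kinetic detail of each variant lives in the primary
#' electrophysiology literature; the bundled defaults are deliberately
#' coarse gain-of-function approximations (each entry carries a `note`
#' saying so) and can be edited or replaced via `file`.
#'
#' @param file path to a preset JSON file; defaults to the bundled catalogue.
#' @return named list of presets; each preset has `multipliers` (channel ->
#'   scalar) and a `note` string.
#' @export
mutation_presets <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "mutation_presets.json", package = "vtmech",
                        mustWork = TRUE)
  jsonlite::fromJSON(file, simplifyVector = FALSE)
}

#' Look up one mutation preset
#'
#' @param name preset name, one of the catalogue entries
#'   (`"KCNQ1-S140G"`, `"KCNQ1-V241F"`, `"KCNQ1-G229D"`, `"hERG-L532P"`,
#'   `"hERG-N588K"` in the bundled file).
#' @param file optional alternative catalogue file.
#' @return the preset's parameter-override map (a named list of multipliers).
#' @export
mutation_preset <- function(name, file = NULL) {
  cat <- mutation_presets(file)
  if (!name %in% names(cat))
    stop("unknown mutation preset '", name, "'; valid presets: ",
         paste(names(cat), collapse = ", "))
  cat[[name]]
}

#' Apply a mutation preset to a parameter set
#'
#' @param params a `cell_params` object.
#' @param name preset name (see [mutation_preset()]).
#' @param file optional alternative catalogue file.
#' @return a new `cell_params` with the preset's overrides applied and
#'   `mutation_id` set.
#' @export
apply_mutation <- function(params, name, file = NULL) {
  pre <- mutation_preset(name, file)
  out <- apply_conductance_multipliers(params, pre$multipliers,
                                       allow_any = TRUE)
  out$mutation_id <- name
  validate_cell_params(out)
  out
}

#' Simulate a paced single cell
#'
#' Integrates the ionic model for `n_beats` cycles of periodic current-clamp
#' pacing (forward Euler for voltage/concentrations, Rush-Larsen for the
#' voltage gates).  The final beat is the steady-state measurement beat.
#'
#' @param params `cell_params`.
#' @param cycle_length_ms pacing cycle length (ms); default 1000 (1 Hz).
#' @param n_beats number of paced beats (>= 1).
#' @param dt_ms integration step (ms); default 0.02.
#' @param stim_amplitude_pA_pF depolarizing stimulus amplitude (pA/pF);
#'   0 disables pacing.
#' @param stim_duration_ms stimulus duration (ms).
#' @param record_every_ms output sampling interval (ms).
#' @param init optional initial state vector (as from `tt_rest_state()`).
#' @return `cell_trace`: list with `time` (ms), `Vm` (mV), `Cai` (mM),
#'   `stim_times`, `params`, and the final model `state`.
#' @export
#' @examples
#' tr <- simulate_cell(cell_params(), n_beats = 2)
#' measure_apd(tr)
simulate_cell <- function(params, cycle_length_ms = 1000, n_beats = 1,
                          dt_ms = 0.02, stim_amplitude_pA_pF = 52,
                          stim_duration_ms = 1, record_every_ms = 1,
                          init = NULL) {
  stopifnot(inherits(params, "cell_params"), n_beats >= 1,
            cycle_length_ms > 0, dt_ms > 0)
  duration <- n_beats * cycle_length_ms
  stim_times <- (seq_len(n_beats) - 1) * cycle_length_ms + 10
  stims <- if (stim_amplitude_pA_pF > 0) {
    lapply(stim_times, function(t0)
      list(nodes = 0L, start = t0, duration = stim_duration_ms,
           amplitude = stim_amplitude_pA_pF))
  } else list()
  s0 <- if (is.null(init)) matrix(tt_rest_state(), nrow = 1) else
    matrix(as.numeric(init), nrow = 1)
  out <- tt_monodomain(c(1L, 1L, 1L), dx = 0.025, Dcoef = 0,
                       pars = unclass(params), state0 = s0, stims = stims,
                       duration = duration, dt = dt_ms,
                       record_every = record_every_ms, passive = FALSE)
  tr <- list(time = out$time, Vm = out$vm[1, ], Cai = out$cai[1, ],
             stim_times = if (length(stims)) stim_times else numeric(0),
             cycle_length_ms = cycle_length_ms, params = params,
             state = stats::setNames(out$state[1, ], names(tt_rest_state())))
  class(tr) <- "cell_trace"
  tr
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("<cell_trace> %.0f ms, %d samples, %d stimuli; Vm range [%.1f, %.1f] mV\n",
              max(x$time), length(x$time), length(x$stim_times),
              min(x$Vm), max(x$Vm)))
  invisible(x)
}

#' Export a cell trace as CSV
#'
#' @param trace a `cell_trace`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cell_trace <- function(trace, file) {
  utils::write.csv(data.frame(time_ms = trace$time, Vm_mV = trace$Vm,
                              Cai_mM = trace$Cai),
                   file, row.names = FALSE)
  invisible(file)
}

# Detect action potentials on a (time, vm) trace and return per-AP
# repolarization durations at the given fraction.  Shared by the
# single-cell measurement and the tissue APD feature.
.apd_all <- function(time, vm, fraction = 0.9, upstroke_threshold = -40) {
  n <- length(vm)
  if (n < 3) return(numeric(0))
  up <- which(vm[-n] < upstroke_threshold & vm[-1] >= upstroke_threshold)
  if (!length(up)) return(numeric(0))
  apds <- numeric(0)
  bounds <- c(up, n)
  for (k in seq_along(up)) {
    i0 <- up[k]
    i1 <- bounds[k + 1]            # next upstroke (or end) bounds this AP
    seg <- i0:i1
    ipk <- seg[which.max(vm[seg])]
    # takeoff potential: minimum over the diastolic interval before upstroke
    j0 <- if (k == 1) 1 else up[k - 1]
    base <- min(vm[j0:i0])
    peak <- vm[ipk]
    amp <- peak - base
    if (amp < 20) next             # not a real AP
    vlev <- peak - fraction * amp
    # upward crossing of the level at/just before the upstroke
    blw <- which(vm[1:ipk] < vlev)
    if (!length(blw)) next
    iu <- max(blw)
    t_up <- time[iu] + (time[iu + 1] - time[iu]) *
      (vlev - vm[iu]) / (vm[iu + 1] - vm[iu])
    # downward crossing after the peak, before the next upstroke
    post <- ipk:i1
    dn <- post[which(vm[post][-length(post)] >= vlev &
                       vm[post][-1] < vlev)[1]]
    if (is.na(dn)) next            # incomplete repolarization
    t_dn <- time[dn] + (time[dn + 1] - time[dn]) *
      (vlev - vm[dn]) / (vm[dn + 1] - vm[dn])
    apds <- c(apds, t_dn - t_up)
  }
  apds
}

#' Action potential duration of a cell trace
#'
#' APD at a repolarization fraction (APD90 by default): the time the
#' membrane spends above the level `peak - fraction * amplitude`, with the
#' crossing times linearly interpolated between samples.  Amplitude is
#' measured per action potential from the preceding diastolic minimum to the
#' peak.  By default the last complete action potential (the steady-state
#' measurement beat) is reported.
#'
#' @param trace `cell_trace`, or a list with `time` and `Vm`.
#' @param repolarization_fraction fraction of amplitude at which the AP is
#'   considered repolarized; default 0.90.
#' @param which `"last"` (default), `"all"` or `"mean"`.
#' @return duration(s) in ms.  If no action potential is detected the
#'   result is `NA` carrying attribute `no_beat = TRUE` -- an explicit
#'   "no-beat" outcome, distinct from an APD of zero.
#' @export
measure_apd <- function(trace, repolarization_fraction = 0.9,
                        which = c("last", "all", "mean")) {
  which <- match.arg(which)
  stopifnot(repolarization_fraction > 0, repolarization_fraction < 1)
  apds <- .apd_all(trace$time, trace$Vm, repolarization_fraction)
  if (!length(apds)) {
    out <- NA_real_
    attr(out, "no_beat") <- TRUE
    return(out)
  }
  switch(which,
         last = apds[length(apds)],
         all = apds,
         mean = mean(apds))
}
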
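#' Enumerate the study configuration matrix
#'
#' The default (`"per-channel"`) design crosses the conductance levels
#' {1, 2, 4, 6, 8, 10, 20, 30, 40, 60, 80, 100} with the two delayed-
#' rectifier channels (g_Ks, g_Kr) and the four S2 sites, giving 96
#' conductance configurations, and adds the five mutation presets crossed
#' with the four S2 sites (20 more) for 116 in total.  The `"paired"`
#' alternative scales g_Ks through the levels with g_Kr fixed at 2-fold
#' (12 levels x 4 sites = 48 conductance configurations + 20 mutations).
#'
#' @param design `"per-channel"` (default) or `"paired"`.
#' @param seed base seed recorded into each configuration.
#' @return list of `study_config` objects, deterministic order; attribute
#'   `counts` gives `c(conductance, mutation)`.
#' @export
enumerate_configs <- function(design = c("per-channel", "paired"), seed = 1) {
  design <- match.arg(design)
  levels <- c(1, 2, 4, 6, 8, 10, 20, 30, 40, 60, 80, 100)
  sites <- c("LV-whole", "LV-lower", "RV-whole", "RV-lower")
  muts <- c("KCNQ1-S140G", "KCNQ1-V241F", "KCNQ1-G229D",
            "hERG-L532P", "hERG-N588K")
  cfgs <- list()
  k <- 0
  if (design == "per-channel") {
    for (ch in c("g_Ks", "g_Kr")) for (lv in levels) for (s in sites) {
      k <- k + 1
      cfgs[[k]] <- structure(list(
        kind = "conductance", channel = ch, multiplier = lv,
        mutation_id = NULL, s2_site = s, seed = seed,
        id = sprintf("cond_%s_x%g_%s", ch, lv, s)), class = "study_config")
    }
  } else {
    for (lv in levels) for (s in sites) {
      k <- k + 1
      cfgs[[k]] <- structure(list(
        kind = "conductance", channel = "g_Ks", multiplier = lv,
        g_Kr_multiplier = 2, mutation_id = NULL, s2_site = s, seed = seed,
        id = sprintf("cond_paired_g_Ks_x%g_%s", lv, s)),
        class = "study_config")
    }
  }
  ncond <- k
  for (m in muts) for (s in sites) {
    k <- k + 1
    cfgs[[k]] <- structure(list(
      kind = "mutation", channel = NULL, multiplier = NULL,
      mutation_id = m, s2_site = s, seed = seed,
      id = sprintf("mut_%s_%s", m, s)), class = "study_config")
  }
  attr(cfgs, "counts") <- c(conductance = ncond, mutation = k - ncond)
  attr(cfgs, "design") <- design
  cfgs
}

#' Cell parameters for a study configuration
#' @param config `study_config`.
#' @return `cell_params` with the configuration's scaling or preset applied.
#' @export
config_cell_params <- function(config) {
  p <- cell_params()
  if (config$kind == "conductance") {
    m <- list()
    if (config$multiplier != 1) m[[config$channel]] <- config$multiplier
    if (!is.null(config$g_Kr_multiplier))
      m[["g_Kr"]] <- (if (is.null(m[["g_Kr"]])) 1 else m[["g_Kr"]]) *
        config$g_Kr_multiplier
    if (length(m)) p <- apply_conductance_multipliers(p, m)
  } else {
    p <- apply_mutation(p, config$mutation_id)
  }
  p
}

#' Runtime options for a study case
#'
#' @param nx,ny grid size; `dx`, `D` as in [tissue_geometry()].
#' @param duration_post_onset_ms recording length after reentry onset
#'   (10000 in the production profile; the fast profile uses 2000).
#' @param dt_ms integration step.
#' @param record_every_ms recording interval.
#' @param ci_scan_offsets_ms S2 coupling intervals scanned, as offsets from
#'   the configuration's single-cell APD90 (the vulnerable window tracks
#'   the cell's repolarization).
#' @param trial_ms trial-segment length used to test each coupling interval.
#' @param fast logical shortcut: `run_options(fast = TRUE)` is the 64x64 /
#'   2 s smoke profile.
#' @return list of options.
#' @export
run_options <- function(nx = 192, ny = 192, dx = 0.0125, D = 2e-4,
                        duration_post_onset_ms = 10000, dt_ms = 0.02,
                        record_every_ms = 1,
                        ci_scan_offsets_ms = seq(-20, 120, by = 10),
                        trial_ms = 400, fast = FALSE) {
  if (fast) { nx <- 96; ny <- 96; duration_post_onset_ms <- 2000 }
  list(nx = nx, ny = ny, dx = dx, D = D,
       duration_post_onset_ms = duration_post_onset_ms, dt_ms = dt_ms,
       record_every_ms = record_every_ms,
       ci_scan_offsets_ms = ci_scan_offsets_ms, trial_ms = trial_ms)
}

#' Induce reentry by scanning the S2 coupling interval
#'
#' Runs the S1 conditioning wave once, snapshots the state, then delivers
#' S2 at each candidate coupling interval (a window around the single-cell
#' APD90) until a re-activation is detected within the trial segment.
#'
#' @param geometry `tissue_geometry`; @param params `cell_params`.
#' @param s2_site one of the four S2 site ids.
#' @param opts [run_options()].
#' @return list with `protocol`, `state` (tissue state at S2 onset), the
#'   successful `coupling_interval_ms`, trial `onset_ms`, and `scan_log`
#'   (data frame of tried intervals); or `NULL` elements plus the log when
#'   no interval induced reentry.
#' @keywords internal
.induce_reentry <- function(geometry, params, s2_site, opts) {
  cell <- simulate_cell(params, n_beats = 3, dt_ms = opts$dt_ms)
  apd <- measure_apd(cell)
  if (is.na(apd)) apd <- 250
  cis <- sort(apd + opts$ci_scan_offsets_ms)
  cis <- cis[cis > 20]
  s1_time <- 10
  t_snap <- s1_time + min(cis) - 5
  base <- run_monodomain(geometry, params,
                         protocol = build_s1s2_protocol(geometry, s2_site,
                                                        coupling_interval_ms = 1e9),
                         duration_ms = t_snap, dt_ms = opts$dt_ms,
                         record_every_ms = opts$record_every_ms)
  log <- data.frame(ci = numeric(0), onset = numeric(0))
  for (ci in cis) {
    pr <- build_s1s2_protocol(geometry, s2_site, coupling_interval_ms = ci,
                              s1_time_ms = s1_time)
    lead <- (s1_time + ci) - t_snap
    trial <- run_monodomain(geometry, params,
                            protocol = pr, duration_ms = lead + opts$trial_ms,
                            dt_ms = opts$dt_ms,
                            record_every_ms = opts$record_every_ms,
                            init_state = base$state, t0_ms = t_snap)
    onset <- detect_reentry_onset(trial)
    log <- rbind(log, data.frame(ci = ci, onset = onset))
    if (!is.na(onset))
      return(list(protocol = pr, state = base$state, t_snap = t_snap,
                  coupling_interval_ms = ci, onset_ms = onset,
                  scan_log = log))
  }
  list(protocol = NULL, state = NULL, t_snap = t_snap,
       coupling_interval_ms = NA_real_, onset_ms = NA_real_, scan_log = log)
}

#' Run one study case end to end
#'
#' Builds cell parameters from the configuration, scans the S2 coupling
#' interval to induce reentry, records the prescribed duration after
#' reentry onset, extracts the 12 electrical features, converts tissue
#' calcium to per-node tension (ampTens) and drives the lumped circulation
#' with the spatial-mean tension (stroke volume).  Episodes whose reentry
#' dies (phase singularities present in < 80% of post-onset frames) are
#' rejected rather than imputed.
#'
#' @param config `study_config`; @param opts [run_options()].
#' @param n_tension_cells number of (regularly subsampled) nodes used for
#'   the tension computation.
#' @return `episode_record`: list with `config`, `features` (12-vector),
#'   `SV`, `ampTens`, `qc` (list with `accepted`, `reason`, `ps_fraction`,
#'   `scan_log`), and the reentry onset.
#' @export
run_case <- function(config, opts = run_options(), n_tension_cells = 1024) {
  g <- tissue_geometry(opts$nx, opts$ny, dx = opts$dx, D = opts$D)
  p <- config_cell_params(config)
  ind <- .induce_reentry(g, p, config$s2_site, opts)
  rejected <- function(reason) structure(
    list(config = config, features = NULL, SV = NA_real_,
         ampTens = NA_real_, reentry_onset_ms = ind$onset_ms,
         qc = list(accepted = FALSE, reason = reason,
                   ps_fraction = NA_real_, scan_log = ind$scan_log)),
    class = "episode_record")
  if (is.null(ind$protocol))
    return(rejected("no reentry inducible across the coupling-interval scan"))

  pr <- ind$protocol
  dur <- (ind$onset_ms - ind$t_snap) + opts$duration_post_onset_ms
  rec <- run_monodomain(g, p, protocol = pr, duration_ms = dur,
                        dt_ms = opts$dt_ms,
                        record_every_ms = opts$record_every_ms,
                        init_state = ind$state, t0_ms = ind$t_snap)
  rec$reentry_onset_ms <- detect_reentry_onset(rec)
  if (is.na(rec$reentry_onset_ms))
    return(rejected("reentry not confirmed on the full recording"))

  window <- c(rec$reentry_onset_ms, max(rec$time))
  pm <- compute_phase_map(rec)
  frames <- which(pm$time >= window[1] & pm$time <= window[2])
  counts <- attr(ps_statistics(pm, frames, dims = c(g$nx, g$ny)), "counts")
  psfrac <- mean(counts > 0)
  if (psfrac < 0.80)
    return(rejected(sprintf(
      "reentry died: phase singularities in only %.0f%% of frames",
      100 * psfrac)))

  fv <- assemble_feature_vector(rec, window)

  # mechanics: tension per (subsampled) node from tissue calcium
  keep <- which(pm$time >= window[1] & pm$time <= window[2])
  nn <- nrow(rec$cai)
  cells <- unique(round(seq(1, nn, length.out = min(n_tension_cells, nn))))
  tens <- simulate_tension(list(time = rec$time[keep],
                                cai = rec$cai[cells, keep, drop = FALSE]))
  at <- amp_tens(tens)
  mean_t <- colMeans(tens$tension)
  h <- run_circulation(circulation_params(),
                       list(time = tens$time - min(tens$time), tension = mean_t),
                       duration_ms = max(tens$time) - min(tens$time))
  sv <- stroke_volume(h)

  structure(list(config = config, features = fv, SV = sv, ampTens = at,
                 reentry_onset_ms = rec$reentry_onset_ms,
                 qc = list(accepted = TRUE, reason = NULL,
                           ps_fraction = psfrac, scan_log = ind$scan_log)),
            class = "episode_record")
}

#' @export
print.episode_record <- function(x, ...) {
  cat("<episode_record>", x$config$id, "\n")
  if (x$qc$accepted) {
    cat(sprintf("  accepted; SV = %.3g mL, ampTens = %.3g kPa, onset = %.0f ms\n",
                x$SV, x$ampTens, x$reentry_onset_ms))
  } else cat("  REJECTED:", x$qc$reason, "\n")
  invisible(x)
}

#' Collect episode records into a dataset table
#'
#' @param records list of `episode_record`s.
#' @param keep_rejected include rejected episodes (features NA).
#' @return data frame with config columns, the 12 features, `SV`, `ampTens`
#'   (class `vt_dataset`).
#' @export
episodes_to_dataset <- function(records, keep_rejected = FALSE) {
  rows <- lapply(records, function(r) {
    if (!r$qc$accepted && !keep_rejected) return(NULL)
    fv <- if (is.null(r$features)) stats::setNames(
      rep(NA_real_, 12), feature_names()) else unclass(r$features)
    cbind(data.frame(id = r$config$id, kind = r$config$kind,
                     s2_site = r$config$s2_site,
                     accepted = r$qc$accepted),
          as.data.frame(as.list(fv)),
          data.frame(SV = r$SV, ampTens = r$ampTens))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("vt_dataset", class(out))
  out
}
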
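#' Reference moments of the study feature table
#'
#' Per-variable mean, SD, max, median and min of the 12 electrical features
#' and 2 mechanical outputs over the 116-episode study, used as the moment
#' targets of the emulator.  The printed maximum of `DF_peakP_mean` is
#' internally inconsistent with its mean and median (it is smaller than
#' both); it is corrected here to 2e-4, the only reading under which a
#' distribution on [min, max] can carry the stated mean.
#'
#' @return data frame with columns `variable`, `mean`, `sd`, `max`,
#'   `median`, `min`.
#' @export
feature_table_stats <- function() {
  data.frame(
    variable = c(feature_names(), "SV", "ampTens"),
    mean = c(121.5, 8.4, 5.7, 5.7, 0.1, 1.0e-4, 2.1e-5, 48, 8.0,
             13782, 4339.4, 252.5, 0.3, 0.4),
    sd = c(43.4, 3.0, 1.1, 1.0, 4.6e-2, 4.6e-5, 2.5e-5, 28, 6.1,
           19321, 5590.4, 232, 0.5, 0.3),
    max = c(237, 16.2, 7.3, 7.1, 0.3, 2.0e-4, 2.7e-4, 119, 47.3,
            138142, 38546.6, 1428, 2.7, 1.6),
    median = c(111, 7.6, 5.6, 5.8, 9.7e-2, 1.1e-4, 1.7e-5, 48, 7.2,
               9648, 2563, 192, 0.2, 0.3),
    min = c(69, 4.8, 3.4, 3.5, 1.1e-3, 4.5e-7, 3.4e-8, 5, 1.0,
            413, 276.8, 85, 0, 4.1e-2))
}

# method-of-moments Beta parameters on [a, b] for a target mean/sd
.beta_mom <- function(mean, sd, a, b) {
  m <- (mean - a) / (b - a)
  v <- (sd / (b - a))^2
  if (m <= 0 || m >= 1 || v >= m * (1 - m))
    stop("infeasible Beta moments: mean/sd incompatible with [min, max]")
  k <- m * (1 - m) / v - 1
  c(shape1 = m * k, shape2 = (1 - m) * k)
}

#' Default cross-correlation specification of the emulator
#'
#' A single-factor dependence structure: every variable loads on one latent
#' severity factor.  The four activation-scale features (APD, Wavelength,
#' Rotation_rate, DF_mean) load strongly (|r| with the mechanical outputs
#' ~0.7); the spatial-instability features (DF dispersion, PS and filament
#' statistics) load weakly (|r| ~0.3).  Longer APD and wavelength mean less
#' disorganized activation, hence positive loadings; faster rotors, higher
#' DF and more singularities/filaments mean more severe fibrillation,
#' hence negative loadings.  The mechanical targets additionally carry a
#' mild quadratic term in the factor (`nonlinearity`), giving the
#' regression bench a smooth nonlinear component.
#'
#' @param strong,weak magnitudes of the strong/weak feature loadings.
#' @param target_loading linear factor loading of SV and ampTens.
#' @param nonlinearity loading of the quadratic (second Hermite) term in
#'   the targets; 0 gives a purely Gaussian copula.
#' @return list with `loadings` (named, length 12), `target_loading`,
#'   `nonlinearity`.
#' @export
default_correlation_spec <- function(strong = 0.85, weak = 0.36,
                                     target_loading = 0.82,
                                     nonlinearity = 0.33) {
  ld <- c(APD = strong, Wavelength = strong, Rotation_rate = -strong,
          DF_mean = -strong, DF_std = -weak, DF_peakP_mean = weak,
          DF_peakP_std = -weak, PS = -weak, PS_std = -weak,
          Filament = -weak, Filament_std = -weak, Filament_PS_ratio = -weak)
  if (target_loading^2 + nonlinearity^2 >= 1)
    stop("infeasible correlation spec: target_loading^2 + nonlinearity^2 must be < 1")
  list(loadings = ld, target_loading = target_loading,
       nonlinearity = nonlinearity)
}

#' Emulate the study feature table
#'
#' Fast synthetic stand-in for the 116-episode simulation table, used by
#' the regression bench.  Dependence comes from a single-factor Gaussian
#' copula (see [default_correlation_spec()]); marginals are Beta
#' distributions on each variable's [min, max] range, moment-matched to its
#' mean/SD, sampled by mapping the copula ranks through a stratified
#' quantile grid so that sample moments are faithful at any n and every
#' sample respects the range.
#'
#' `mode = "linear_map"` replaces the copula targets by an exact linear map
#' of the (min-max scaled) features plus Gaussian noise with SD equal to
#' `linear_noise_frac` of the target SD -- the generator used for linear
#' parameter-recovery checks.
#'
#' @param n_rows number of episodes (>= 10).
#' @param seed RNG seed (the table is a deterministic function of it).
#' @param correlation_spec see [default_correlation_spec()].
#' @param mode `"default"` (copula, mild nonlinearity) or `"linear_map"`.
#' @param linear_noise_frac noise SD as a fraction of target SD in
#'   `"linear_map"` mode.
#' @return `vt_dataset` data frame: `id`, `kind`, 12 features, `SV`,
#'   `ampTens`.
#' @export
emulate_feature_table <- function(n_rows, seed = 1,
                                  correlation_spec = default_correlation_spec(),
                                  mode = c("default", "linear_map"),
                                  linear_noise_frac = 0.1) {
  mode <- match.arg(mode)
  stopifnot(n_rows >= 10)
  st <- feature_table_stats()
  ld <- correlation_spec$loadings
  if (!identical(names(ld), feature_names()))
    stop("correlation spec loadings must be named by the 12 features, in order")
  if (any(abs(ld) >= 1)) stop("feature loadings must be in (-1, 1)")
  a <- correlation_spec$target_loading
  b <- correlation_spec$nonlinearity

  set.seed(seed)
  f <- rnorm(n_rows)
  z <- sapply(seq_along(ld), function(j)
    ld[j] * f + sqrt(1 - ld[j]^2) * rnorm(n_rows))
  h <- (f^2 - 1) / sqrt(2)  # second Hermite polynomial: mean 0, var 1
  cc <- sqrt(1 - a^2 - b^2)
  zt <- sapply(1:2, function(j) a * f + b * h + cc * rnorm(n_rows))
  z <- cbind(z, zt)
  colnames(z) <- st$variable

  # stratified quantile transform: ranks -> exact Beta quantile grid
  X <- sapply(st$variable, function(v) {
    i <- match(v, st$variable)
    sh <- .beta_mom(st$mean[i], st$sd[i], st$min[i], st$max[i])
    u <- (rank(z[, v], ties.method = "first") - 0.5) / n_rows
    st$min[i] + (st$max[i] - st$min[i]) * qbeta(u, sh[1], sh[2])
  })
  X <- as.data.frame(X)

  if (mode == "linear_map") {
    fn <- feature_names()
    rng <- lapply(fn, function(v) range(X[[v]]))
    Xs <- mapply(function(v, r) (X[[v]] - r[1]) / diff(r), fn, rng)
    w <- ld / sum(abs(ld))
    lin <- as.numeric(Xs %*% w)
    for (k in c("SV", "ampTens")) {
      i <- match(k, st$variable)
      y <- st$mean[i] + st$sd[i] * scale(lin)[, 1]
      X[[k]] <- y + rnorm(n_rows, sd = linear_noise_frac * st$sd[i])
    }
  }

  out <- cbind(data.frame(id = sprintf("emul_%05d", seq_len(n_rows)),
                          kind = "emulated", s2_site = NA_character_,
                          accepted = TRUE), X)
  class(out) <- c("vt_dataset", class(out))
  out
}
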
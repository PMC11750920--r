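# Washout statistics: per-breath expiratory curves, phase-3 slopes,
# normalized slopes, lung-unit mean concentration differences and their
# ratio to the slope.

#' Split a simulation into per-breath expiratory curves
#'
#' One curve per completed breath: expired volume since expiration onset
#' (`v_exp`, ml, proportional to time at the rectangular flow), carrier-gas
#' mole fraction at the mouth, and the phase label.  Phase III starts one
#' dead-space transit time `dt_dead = V_dead / Q_hat` after expiration
#' onset; the phase I/II boundary is placed where the expired carrier
#' fraction first exceeds 2 % of the breath's end-tidal value (the end of
#' the unmixed front from the anterior dead space).
#'
#' @param result A `simulation_result`.
#' @param pattern Breathing pattern; defaults to the simulated one.
#' @return A data.frame with columns `breath`, `time`, `t_exp`, `v_exp`,
#'   `chi_N2`, `phase`, with the dead-space transit time in
#'   `attr(, "dt_dead")`.
#' @export
extract_breaths <- function(result, pattern = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  T <- result$T
  Q <- result$system$Q_hat
  vol <- lung_volumes(result$system$model)
  dt_dead <- vol$dt_dead
  n_breaths <- floor(result$duration / T + 1e-9)
  if (n_breaths < 1) stop("simulation shorter than one breath")
  if (result$duration - n_breaths * T > result$dt / 2)
    warning("truncated final breath dropped")
  out <- vector("list", n_breaths)
  for (n in seq_len(n_breaths)) {
    onset <- (n - 1) * T + T / 2
    sel <- result$time >= onset - 1e-12 & result$time <= n * T + 1e-12
    t <- result$time[sel]
    chi_N2 <- 1 - result$mouth[sel]
    t_exp <- t - onset
    v_exp <- Q * t_exp
    phase <- ifelse(t_exp >= dt_dead, "III", "I")
    endt <- chi_N2[length(chi_N2)]
    ii <- which(phase == "I" & chi_N2 > 0.02 * max(endt, 1e-12))
    if (length(ii)) phase[ii] <- "II"
    out[[n]] <- data.frame(breath = n, time = t, t_exp = t_exp,
                           v_exp = v_exp, chi_N2 = chi_N2, phase = phase)
  }
  curves <- do.call(rbind, out)
  attr(curves, "dt_dead") <- dt_dead
  attr(curves, "V_T") <- Q * T / 2
  curves
}

#' Phase-3 slope of one expiratory curve
#'
#' Ordinary least-squares slope of the expired carrier mole fraction
#' against expired volume over the last `fraction` (default 25 %) of the
#' expired tidal volume.  Reported per litre of expired volume; the
#' per-second variant is the same slope times the expiratory flow.
#'
#' @param curve One breath of [extract_breaths()] output.
#' @param fraction Terminal fraction of the tidal volume to regress over.
#' @param per `"volume"` (1/L) or `"time"` (1/s).
#' @return The slope (scalar).
#' @export
phase3_slope <- function(curve, fraction = 0.25, per = c("volume", "time")) {
  per <- match.arg(per)
  v_t <- max(curve$v_exp)
  sel <- curve$v_exp >= (1 - fraction) * v_t
  if (sum(sel) < 2) stop("phase-3 window holds fewer than two samples")
  x <- curve$v_exp[sel] / 1000        # litres
  y <- curve$chi_N2[sel]
  slope <- stats::cov(x, y) / stats::var(x)
  if (per == "time") slope <- slope * max(curve$v_exp) / max(curve$t_exp) / 1000
  slope
}

#' Normalized phase-3 slope
#'
#' The slope divided by the time-averaged expired carrier mole fraction of
#' the same breath.
#'
#' @param curve One breath of [extract_breaths()] output.
#' @param S3 Its phase-3 slope, see [phase3_slope()].
#' @return Dimensionless-per-litre normalized slope.
#' @export
normalized_s3 <- function(curve, S3) {
  m <- mean(curve$chi_N2)
  if (!is.finite(m) || m <= 0)
    stop("mean expired concentration is zero; normalized slope undefined")
  S3 / m
}

#' Mean carrier-concentration difference between the parallel lung units
#'
#' Volume-weighted mean nitrogen mole fractions of LU1 and LU2 evaluated at
#' the per-breath sampling instants `t_n = 3.5 - dt_LU0 + (n - 1) T` (the
#' moment whose gas reaches the mouth at the phase-3 measurement window,
#' shifted by the transit time through the shared region LU0), and their
#' difference `LU1 - LU2`.
#'
#' @param result A `simulation_result` whose snapshots cover the `t_n`.
#' @param partition An [partition_lung_units()] object for the same model.
#' @param pattern Breathing pattern; defaults to the simulated one.
#' @return A data.frame `n`, `t_n`, `mean_LU1`, `mean_LU2`, `delta_chi`.
#' @export
lu_concentration_difference <- function(result, partition, pattern = NULL) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(partition, "lu_partition"))
  T <- result$T
  tn <- lu_sample_times(partition, T, result$duration)
  idx <- match(round(tn / result$dt), round(result$snapshot_times / result$dt))
  if (anyNA(idx))
    stop("simulation snapshots do not cover the lung-unit sampling times; ",
         "pass lu_sample_times() as snapshot_times")
  lu1 <- partition$label == "LU1"
  lu2 <- partition$label == "LU2"
  wmean <- function(k, sel) {
    v <- result$V[k, sel]
    sum((1 - result$chi[k, sel]) * v) / sum(v)
  }
  m1 <- vapply(idx, wmean, numeric(1), sel = lu1)
  m2 <- vapply(idx, wmean, numeric(1), sel = lu2)
  data.frame(n = seq_along(tn), t_n = tn, mean_LU1 = m1, mean_LU2 = m2,
             delta_chi = m1 - m2)
}

#' Lung-unit sampling instants
#'
#' @param partition An [partition_lung_units()] object.
#' @param T Breath period in s.
#' @param duration Simulated time in s.
#' @return The times `t_n = 3.5 - dt_LU0 + (n - 1) T` that fall inside the
#'   simulation.
#' @export
lu_sample_times <- function(partition, T = 4, duration = 200) {
  tn <- 3.5 - partition$dt_LU0 + (seq_len(ceiling(duration / T)) - 1) * T
  tn[tn >= 0 & tn <= duration]
}

#' Ratio of phase-3 slope to lung-unit concentration difference
#'
#' Elementwise `f_S3(n) = S3(n) / delta_chi(n)`.  Entries where either the
#' slope or the difference falls below `floor` are flagged unreliable
#' (division of two vanishing quantities); with the defaults this mirrors
#' restricting the ratio to the early breaths of a washout.
#'
#' @param S3 Slope series (1/L).
#' @param delta_chi Concentration-difference series, aligned on breaths.
#' @param floor Numeric reliability floor on both series.
#' @return A data.frame `n`, `f_S3`, `reliable`.
#' @export
f_s3 <- function(S3, delta_chi, floor = 1e-6) {
  stopifnot(length(S3) == length(delta_chi))
  reliable <- abs(S3) >= floor & abs(delta_chi) >= floor
  ratio <- ifelse(reliable, S3 / delta_chi, NA_real_)
  data.frame(n = seq_along(S3), f_S3 = ratio, reliable = reliable)
}

#' Breath at which the phase-3 slope peaks
#'
#' @param S3 Slope series over breaths.
#' @return The breath index of the maximum (ties toward the earlier
#'   breath).
#' @export
s3_peak_breath <- function(S3) {
  stopifnot(length(S3) >= 1)
  which.max(S3)
}

#' Full per-breath washout report
#'
#' Computes, for every completed breath: the phase-3 slope, the normalized
#' slope, the mean expired carrier fraction, the end-tidal carrier
#' fraction, and - when a lung-unit partition is given and the simulation
#' recorded the matching snapshots - the LU1-LU2 concentration difference
#' and its ratio to the slope.
#'
#' @param result A `simulation_result`.
#' @param partition Optional [partition_lung_units()] object.
#' @return A `washout_report`: data.frame with one row per breath.
#' @export
washout_report <- function(result, partition = NULL) {
  curves <- extract_breaths(result)
  n_breaths <- max(curves$breath)
  rep <- data.frame(n = seq_len(n_breaths), t_n = NA_real_,
                    S3 = NA_real_, S3_norm = NA_real_,
                    mean_chi_N2 = NA_real_, end_tidal_N2 = NA_real_,
                    delta_chi = NA_real_, f_S3 = NA_real_, reliable = NA)
  for (n in seq_len(n_breaths)) {
    cv <- curves[curves$breath == n, ]
    rep$S3[n] <- phase3_slope(cv)
    rep$mean_chi_N2[n] <- mean(cv$chi_N2)
    rep$S3_norm[n] <- if (rep$mean_chi_N2[n] > 0)
      rep$S3[n] / rep$mean_chi_N2[n] else NA_real_
    rep$end_tidal_N2[n] <- cv$chi_N2[nrow(cv)]
  }
  if (!is.null(partition)) {
    lud <- lu_concentration_difference(result, partition)
    k <- match(rep$n, lud$n)
    rep$t_n <- lud$t_n[k]
    rep$delta_chi <- lud$delta_chi[k]
    fr <- f_s3(rep$S3, rep$delta_chi)
    rep$f_S3 <- fr$f_S3
    rep$reliable <- fr$reliable
  }
  attr(rep, "dt_dead") <- attr(curves, "dt_dead")
  class(rep) <- c("washout_report", "data.frame")
  rep
}

#' Analyze a stored mouth-trace CSV
#'
#' Recomputes the per-breath phase-3 slopes and normalized slopes directly
#' from a mouth trace written by [write_mouth_csv()], without access to the
#' original simulation (the lung-unit statistics need the full state and
#' are not available from the trace alone).
#'
#' @param path CSV with columns `time_s` and `chi_N2`.
#' @param T_breath Breath period in s.
#' @param Q_hat Peak flow magnitude in cm^3/s.
#' @return A data.frame `n`, `S3`, `S3_norm`, `mean_chi_N2`.
#' @export
analyze_mouth_csv <- function(path, T_breath = 4, Q_hat = 250) {
  tr <- utils::read.csv(path)
  stopifnot(all(c("time_s", "chi_N2") %in% names(tr)))
  n_breaths <- floor(max(tr$time_s) / T_breath + 1e-9)
  out <- data.frame(n = seq_len(n_breaths), S3 = NA_real_,
                    S3_norm = NA_real_, mean_chi_N2 = NA_real_)
  for (n in seq_len(n_breaths)) {
    onset <- (n - 1) * T_breath + T_breath / 2
    sel <- tr$time_s >= onset - 1e-9 & tr$time_s <= n * T_breath + 1e-9
    cv <- data.frame(t_exp = tr$time_s[sel] - onset,
                     v_exp = Q_hat * (tr$time_s[sel] - onset),
                     chi_N2 = tr$chi_N2[sel])
    out$S3[n] <- phase3_slope(cv)
    out$mean_chi_N2[n] <- mean(cv$chi_N2)
    out$S3_norm[n] <- out$S3[n] / out$mean_chi_N2[n]
  }
  out
}

#' Write the per-breath metrics as CSV
#'
#' @param report A [washout_report()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(report, path) {
  df <- as.data.frame(report)
  names(df)[names(df) == "S3"] <- "S3_per_L"
  names(df)[names(df) == "S3_norm"] <- "S3_norm_per_L"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
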
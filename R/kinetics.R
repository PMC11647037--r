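# Mechanistic tumor-volume kinetics: exponential growth, linear-quadratic
# radiation kill, lagged exponential repopulation, and a delayed
# radiation/checkpoint-blockade synergy kill term.

#' Tumor volume from caliper measurements
#'
#' The standard ellipsoid approximation used for subcutaneous tumors:
#' volume = x * y * z / 2.
#'
#' @param x,y,z Length, width, height in mm; all positive.
#' @return Volume in mm^3.
#' @export
volume_from_calipers <- function(x, y, z) {
  if (any(!is.finite(c(x, y, z))) || any(c(x, y, z) <= 0)) {
    stop("invalid caliper measurement: all dimensions must be positive")
  }
  x * y * z / 2
}

#' Survival-endpoint test
#'
#' A tumor reaches the survival endpoint when any caliper dimension exceeds
#' 2 cm or the volume exceeds 1500 mm^3. (Ulceration, the third criterion in
#' live-animal work, is not a function of the simulated state and is not
#' modeled.)
#'
#' @param x,y,z Caliper dimensions in mm.
#' @param volume Volume in mm^3.
#' @return Logical: `TRUE` if the endpoint is reached.
#' @export
endpoint_reached <- function(x, y, z, volume) {
  if (any(!is.finite(c(x, y, z, volume))) || any(c(x, y, z, volume) <= 0)) {
    stop("invalid measurement: dimensions and volume must be positive")
  }
  any(c(x, y, z) > 20) || volume > 1500
}

#' Linear-quadratic clonogenic survival
#'
#' S(D) = exp(-(alpha * D + beta * D^2)) for dose D in Gy.
#'
#' @param dose Dose in Gy, nonnegative (vectorized).
#' @param alpha Linear coefficient, Gy^-1.
#' @param beta Quadratic coefficient, Gy^-2.
#' @return Surviving fraction in (0, 1].
#' @export
lq_survival <- function(dose, alpha, beta) {
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be nonnegative")
  exp(-(alpha * dose + beta * dose^2))
}

#' Kinetic parameters of the simulated tumor model
#'
#' Defaults describe a fast-growing, immunologically cold murine tumor line:
#' roughly 4-day volume doubling, repopulation resuming one day after a
#' pulse with a five-day half-time, and a checkpoint-blockade synergy kill
#' that peaks five days after the most recent pulse. Because the
#' linear-quadratic factor multiplies the measured gross volume rather than
#' a clonogen count, the default alpha and beta are volume-response
#' coefficients (alpha = 0.025 per Gy, beta = 0.0025 per Gy^2, preserving
#' the standard tumor alpha/beta ratio of 10 Gy): a 20 Gy pulse shrinks the
#' gross volume to ~22%, a 40 Gy pulse near-ablates it, while clonogenic
#' coefficients (~0.3 per Gy) would implausibly shrink the measured volume
#' by eight orders of magnitude in a day.
#'
#' @param V0 Initial volume at the first measurement, mm^3.
#' @param lam Per-day exponential growth rate.
#' @param alpha,beta Linear-quadratic survival coefficients (Gy^-1, Gy^-2).
#' @param repop_halftime Half-time of post-pulse repopulation recovery, days.
#' @param repop_lag Days after a pulse during which regrowth is fully
#'   suppressed.
#' @param drug_kill Peak per-day kill rate of the anti-PD-L1 synergy term.
#' @param synergy_lag Days from a pulse to peak immune synergy.
#' @param synergy_width Characteristic width of the synergy window, days;
#'   the kernel is truncated at 3 * synergy_width after a pulse.
#' @param seed Base seed used when cohorts are generated from these
#'   parameters.
#' @return A `tumor_kinetics_params` list.
#' @export
tumor_kinetics_params <- function(V0 = 100, lam = 0.18, alpha = 0.025, beta = 0.0025,
                                  repop_halftime = 5, repop_lag = 1,
                                  drug_kill = 0.15, synergy_lag = 5,
                                  synergy_width = 3, seed = 20251L) {
  p <- list(V0 = V0, lam = lam, alpha = alpha, beta = beta,
            repop_halftime = repop_halftime, repop_lag = repop_lag,
            drug_kill = drug_kill, synergy_lag = synergy_lag,
            synergy_width = synergy_width, seed = as.integer(seed))
  nonneg <- c("lam", "alpha", "beta", "repop_halftime", "repop_lag",
              "drug_kill", "synergy_lag", "synergy_width")
  for (f in nonneg) {
    if (is.na(p[[f]]) || p[[f]] < 0) stop(f, " must be nonnegative")
  }
  if (!is.finite(V0) || V0 <= 0) stop("V0 must be positive")
  structure(p, class = "tumor_kinetics_params")
}

#' Radiation/immunotherapy synergy kernel
#'
#' Dimensionless gamma-like kernel of the time since the most recent pulse:
#' g(tau) = (tau / synergy_lag) * exp(1 - tau / synergy_lag), peaking at 1
#' when tau = synergy_lag and truncated to 0 beyond 3 * synergy_width.
#' Captures an adaptive immune response that takes days to build after a
#' pulse rather than acting instantaneously.
#'
#' @param tau Days since the most recent radiation pulse (vectorized).
#' @param synergy_lag Days to peak.
#' @param synergy_width Truncation scale, days.
#' @return Kernel values in `[0, 1]`.
#' @export
synergy_kernel <- function(tau, synergy_lag, synergy_width) {
  if (synergy_lag <= 0) return(rep(0, length(tau)))
  g <- (tau / synergy_lag) * exp(1 - tau / synergy_lag)
  g[tau < 0 | tau > 3 * synergy_width] <- 0
  g
}

#' A sparse tumor-volume trajectory
#'
#' @param days Integer measurement days relative to the first pulse.
#' @param volumes Volumes in mm^3, same length as `days`, all positive.
#' @param censored_from Optional relative day at which the survival endpoint
#'   first held; measurements at or after it are absent.
#' @param group_id Optional group label.
#' @return A `trajectory` object.
#' @export
trajectory <- function(days, volumes, censored_from = NULL, group_id = NULL) {
  days <- as.integer(days)
  if (length(days) != length(volumes)) stop("days and volumes must have equal length")
  if (length(days) > 1L && any(diff(days) <= 0L)) stop("days must be strictly increasing")
  if (any(volumes <= 0)) stop("volumes must be positive")
  if (!is.null(censored_from) && any(days >= censored_from)) {
    stop("measurements at or after censored_from must be absent")
  }
  structure(list(days = days, volumes = as.numeric(volumes),
                 censored_from = censored_from, group_id = group_id),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory>%s %d measurements%s\n",
              if (is.null(x$group_id)) "" else paste0(" ", x$group_id),
              length(x$days),
              if (is.null(x$censored_from)) "" else sprintf(", censored from day %d", x$censored_from)))
  print(data.frame(day = x$days, volume_mm3 = x$volumes))
  invisible(x)
}

#' Simulate the group-mean tumor-volume trajectory
#'
#' Runs the daily mechanistic update over the 28-step axis. Each day the
#' viable volume is multiplied by `exp(lam_eff - k_drug)`; on a pulse day the
#' viable fraction is first multiplied by the linear-quadratic survival of
#' the delivered dose (the measurement on a pulse day precedes irradiation).
#' `lam_eff` is 0 for `repop_lag` days after the most recent pulse and then
#' relaxes toward `lam` with half-time `repop_halftime`; `k_drug` is active
#' only once an anti-PD-L1 dose has been given and is `drug_kill` scaled by
#' [synergy_kernel()] of the time since the most recent pulse. The
#' trajectory is reported at the schedule's measurement days and truncated
#' by endpoint censoring, with caliper dimensions back-derived from volume
#' assuming a cube-equivalent side (2V)^(1/3).
#'
#' @param schedule A [treatment_schedule()].
#' @param params A [tumor_kinetics_params()].
#' @return A [trajectory()] with attribute `daily` holding the full 28-day
#'   volume curve.
#' @export
simulate_mean_trajectory <- function(schedule, params) {
  stopifnot(inherits(schedule, "treatment_schedule"),
            inherits(params, "tumor_kinetics_params"))
  n <- PULSAR_SEQ_LEN
  pulse_step <- vapply(schedule$radiation, function(e) treatment_day_to_step(e$day), integer(1))
  pulse_dose <- vapply(schedule$radiation, function(e) e$dose, numeric(1))
  drug_steps <- vapply(Filter(function(e) e$agent == "anti-PD-L1", schedule$drug),
                       function(e) treatment_day_to_step(e$day), integer(1))
  drug_on_from <- if (length(drug_steps)) min(drug_steps) else Inf

  V <- numeric(n)
  V[1] <- params$V0
  last_pulse <- -Inf
  for (t in seq_len(n - 1L)) {
    v <- V[t]
    hit <- which(pulse_step == t)
    if (length(hit)) {
      v <- v * lq_survival(pulse_dose[hit], params$alpha, params$beta)
      last_pulse <- t
    }
    # effective growth rate over [t, t+1]
    if (is.infinite(last_pulse) && last_pulse < 0) {
      lam_eff <- params$lam
    } else {
      tau <- t - last_pulse
      if (tau < params$repop_lag) {
        lam_eff <- 0
      } else if (params$repop_halftime == 0) {
        lam_eff <- params$lam
      } else {
        lam_eff <- params$lam * (1 - 2^(-(tau - params$repop_lag) / params$repop_halftime))
      }
    }
    k_drug <- 0
    if (t >= drug_on_from && is.finite(last_pulse)) {
      k_drug <- params$drug_kill *
        synergy_kernel(t - last_pulse, params$synergy_lag, params$synergy_width)
    }
    V[t + 1L] <- v * exp(lam_eff - k_drug)
  }
  # a pulse on the final step affects nothing observable: every measurement
  # precedes same-day irradiation and no later day exists
  meas_steps <- relative_day_to_step(schedule$measurement_days)
  vols <- V[meas_steps]
  side <- (2 * vols)^(1 / 3)
  hit_end <- vapply(seq_along(vols), function(i)
    endpoint_reached(side[i], side[i], side[i], vols[i]), logical(1))
  censored_from <- NULL
  keep <- seq_along(vols)
  if (any(hit_end)) {
    first <- which(hit_end)[1]
    censored_from <- schedule$measurement_days[first]
    keep <- seq_len(first - 1L)
  }
  out <- trajectory(schedule$measurement_days[keep], vols[keep],
                    censored_from = censored_from, group_id = schedule$group_id)
  attr(out, "daily") <- V
  out
}

#' An augmented cohort of replicate trajectories
#'
#' @param group_id Group label.
#' @param samples List of [trajectory()] replicates.
#' @param noise_level Half-width of the uniform sampling interval, as a
#'   fraction of the mean.
#' @return A `cohort` object.
#' @export
cohort <- function(group_id, samples, noise_level) {
  structure(list(group_id = group_id, samples = samples,
                 noise_level = noise_level), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s: %d replicates, noise level %.3g\n",
              x$group_id, length(x$samples), x$noise_level))
  invisible(x)
}

#' Augment a group-mean trajectory by uniform sampling
#'
#' Each replicate draws its volume at every measurement day independently
#' and uniformly from `[mean * (1 - noise_level), mean * (1 + noise_level)]`,
#' emulating inter-animal variation around the group mean. All replicates
#' share the mean's measurement days and censoring status.
#'
#' @param mean_traj The group-mean [trajectory()].
#' @param n Number of replicates.
#' @param noise_level Fraction in `[0, 1)`.
#' @param seed Integer seed; identical seeds reproduce identical cohorts.
#' @return A [cohort()] of `n` replicates.
#' @export
augment_group <- function(mean_traj, n, noise_level, seed) {
  stopifnot(inherits(mean_traj, "trajectory"))
  if (length(mean_traj$days) == 0L) stop("cannot augment an empty mean trajectory")
  if (n < 1L) stop("n must be at least 1")
  if (noise_level < 0 || noise_level >= 1) stop("noise_level must be in [0, 1)")
  set.seed(as.integer(seed))
  m <- length(mean_traj$volumes)
  samples <- lapply(seq_len(n), function(i) {
    u <- stats::runif(m, -1, 1)
    trajectory(mean_traj$days, mean_traj$volumes * (1 + noise_level * u),
               censored_from = mean_traj$censored_from,
               group_id = mean_traj$group_id)
  })
  cohort(mean_traj$group_id, samples, noise_level)
}

#' Simulate augmented cohorts for a roster of groups
#'
#' @param groups Named list of schedules, e.g. [build_default_groups()].
#' @param params Shared [tumor_kinetics_params()].
#' @param n_replicates Replicates per group (default 50).
#' @param noise_level Uniform augmentation level (default 0.02, the level
#'   used for attention analysis).
#' @param seed Master seed; each group's augmentation uses a fixed offset
#'   from it.
#' @return Named list of [cohort()] objects.
#' @export
simulate_cohorts <- function(groups, params = tumor_kinetics_params(),
                             n_replicates = 50L, noise_level = 0.02,
                             seed = params$seed) {
  out <- lapply(seq_along(groups), function(i) {
    mt <- simulate_mean_trajectory(groups[[i]], params)
    augment_group(mt, n_replicates, noise_level, seed = as.integer(seed) + 1000L * i)
  })
  names(out) <- names(groups)
  out
}

#' Flatten cohorts to a long data frame
#'
#' @param cohorts Named list of [cohort()]s.
#' @return A tibble with columns `group_id`, `sample_id`, `day`,
#'   `volume_mm3`.
#' @export
cohorts_to_df <- function(cohorts) {
  rows <- lapply(cohorts, function(co) {
    do.call(rbind, lapply(seq_along(co$samples), function(i) {
      s <- co$samples[[i]]
      data.frame(group_id = co$group_id,
                 sample_id = sprintf("%s_s%03d", co$group_id, i),
                 day = s$days, volume_mm3 = s$volumes)
    }))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Write cohorts to a trajectory CSV
#'
#' @param cohorts Named list of [cohort()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohorts <- function(cohorts, path) {
  utils::write.csv(cohorts_to_df(cohorts), path, row.names = FALSE)
  invisible(path)
}
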
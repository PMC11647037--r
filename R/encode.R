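# Token encoding: treatment schedules and sparse trajectories onto the
# 28-step day axis as 5-wide tokens (1 signal channel + 4 positional
# channels) and zero-padded masked volume-change targets.

#' Maximum radiation dose used for signal normalization (Gy)
#' @export
PULSAR_MAX_DOSE <- 40

#' Sinusoidal positional code for one day step
#'
#' Four-dimensional sinusoidal code with two frequency pairs
#' (1 and 1/100 rad/day): `[sin(d), cos(d), sin(d/100), cos(d/100)]` for
#' 0-based day index d. All 28 positions map to distinct codes, every
#' component lies in `[-1, 1]`, and the code is shared by all token
#' sequences at the same step.
#'
#' @param day_index 0-based step index, 0..27.
#' @return Numeric vector of length 4.
#' @export
positional_code <- function(day_index) {
  if (length(day_index) != 1L || is.na(day_index) ||
      day_index != as.integer(day_index) ||
      day_index < 0L || day_index >= PULSAR_SEQ_LEN) {
    stop("day_index must be an integer in 0..", PULSAR_SEQ_LEN - 1L)
  }
  d <- as.numeric(day_index)
  c(sin(d), cos(d), sin(d / 100), cos(d / 100))
}

#' Positional sub-matrix shared by all token sequences
#' @return 28 x 4 matrix, row s = positional_code(s - 1).
#' @keywords internal
positional_matrix <- function() {
  t(vapply(0:(PULSAR_SEQ_LEN - 1L), positional_code, numeric(4)))
}

token_sequence <- function(signal) {
  stopifnot(length(signal) == PULSAR_SEQ_LEN)
  m <- cbind(signal = signal, positional_matrix())
  colnames(m) <- c("signal", paste0("pos_", 0:3))
  m
}

#' Encode a schedule's radiation sequence
#'
#' The signal channel carries `dose / 40` (normalized by the maximum dose in
#' the design so inputs stay in `[0, 1]`) at each pulse's step and 0
#' elsewhere; the remaining four channels are the shared positional code.
#'
#' @param schedule A [treatment_schedule()].
#' @return 28 x 5 numeric matrix.
#' @export
encode_radiation <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  signal <- numeric(PULSAR_SEQ_LEN)
  for (e in schedule$radiation) {
    s <- treatment_day_to_step(e$day)
    if (signal[s] != 0) stop("two radiation pulses on the same day")
    signal[s] <- e$dose / PULSAR_MAX_DOSE
  }
  token_sequence(signal)
}

#' Encode a schedule's drug sequence
#'
#' The signal channel is 1 at steps with an anti-PD-L1 administration and 0
#' otherwise; isotype-control administrations encode as 0 (they are the
#' no-blockade condition).
#'
#' @param schedule A [treatment_schedule()].
#' @return 28 x 5 numeric matrix.
#' @export
encode_drug <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  signal <- numeric(PULSAR_SEQ_LEN)
  for (e in schedule$drug) {
    if (e$agent == "anti-PD-L1") signal[treatment_day_to_step(e$day)] <- 1
  }
  token_sequence(signal)
}

#' A masked volume-change target sequence
#'
#' @param values Length-28 numeric vector, 0 wherever `mask` is `FALSE`.
#' @param mask Length-28 logical vector.
#' @return A `target_sequence` object.
#' @export
target_sequence <- function(values, mask) {
  stopifnot(length(values) == PULSAR_SEQ_LEN, length(mask) == PULSAR_SEQ_LEN)
  if (any(values[!mask] != 0)) stop("values must be 0 at unmasked steps")
  structure(list(values = as.numeric(values), mask = as.logical(mask)),
            class = "target_sequence")
}

#' Volume changes between adjacent measurements
#'
#' The i-th change `VC_i = V(d_{i+1}) - V(d_i)` is placed at the step of the
#' later measurement day (the change is known only once the second
#' measurement exists, consistent with the causal mask). Steps without an
#' assigned change carry value 0 and mask `FALSE`; a trajectory with m
#' measurements yields m - 1 masked entries. Changes may be negative.
#'
#' @param traj A [trajectory()] with at least two measurements.
#' @return A [target_sequence()] in mm^3.
#' @export
compute_volume_changes <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$days) < 2L) stop("at least two measurement points are required")
  values <- numeric(PULSAR_SEQ_LEN)
  mask <- logical(PULSAR_SEQ_LEN)
  steps <- relative_day_to_step(traj$days)
  for (i in seq_len(length(traj$days) - 1L)) {
    s <- steps[i + 1L]
    values[s] <- traj$volumes[i + 1L] - traj$volumes[i]
    mask[s] <- TRUE
  }
  target_sequence(values, mask)
}

#' Total volume change from a target sequence
#'
#' Summing the masked changes telescopes to the last-minus-first volume.
#'
#' @param target A [target_sequence()].
#' @return Total change in the target's units.
#' @export
recover_total_change <- function(target) {
  stopifnot(inherits(target, "target_sequence"))
  sum(target$values[target$mask])
}

#' Encode one (schedule, trajectory) pair as a model sample
#'
#' @param schedule The group's [treatment_schedule()].
#' @param traj One [trajectory()] (a replicate or the group mean).
#' @param sample_id Label for the replicate.
#' @param vc_scale Multiplier applied to the volume-change targets before
#'   they are seen by the model (default 1: targets in mm^3).
#' @return An `encoded_sample` with fields `radiation_seq`, `drug_seq`
#'   (28 x 5), `target` ([target_sequence()]), `group_id`, `sample_id`.
#' @export
encode_sample <- function(schedule, traj, sample_id = "s001", vc_scale = 1) {
  tgt <- compute_volume_changes(traj)
  structure(
    list(radiation_seq = encode_radiation(schedule),
         drug_seq = encode_drug(schedule),
         target = target_sequence(tgt$values * vc_scale, tgt$mask),
         group_id = schedule$group_id,
         sample_id = sample_id),
    class = "encoded_sample"
  )
}

#' Encode simulated or measured cohorts as a model-ready dataset
#'
#' Replicates with fewer than two surviving measurements (heavily censored
#' trajectories) cannot define a volume change and are dropped with a
#' warning.
#'
#' @param cohorts Named list of [cohort()]s.
#' @param groups Named list of schedules covering every cohort's group id.
#' @param vc_scale Target scale factor. The default 1e-3 expresses changes
#'   in cm^3 so targets are O(1) for the small model; predictions are
#'   converted back via the stored scale.
#' @return An `encoded_dataset`: list with `samples` (list of
#'   `encoded_sample`), `vc_scale`, and `groups` (character vector of group
#'   ids present).
#' @export
encode_dataset <- function(cohorts, groups, vc_scale = 1e-3) {
  samples <- list()
  dropped <- 0L
  for (co in cohorts) {
    if (!co$group_id %in% names(groups)) stop("no schedule for group ", co$group_id)
    sched <- groups[[co$group_id]]
    for (i in seq_along(co$samples)) {
      tr <- co$samples[[i]]
      if (length(tr$days) < 2L) { dropped <- dropped + 1L; next }
      samples[[length(samples) + 1L]] <-
        encode_sample(sched, tr, sample_id = sprintf("%s_s%03d", co$group_id, i),
                      vc_scale = vc_scale)
    }
  }
  if (dropped > 0L) warning(dropped, " replicate(s) with < 2 measurements dropped")
  structure(list(samples = samples, vc_scale = vc_scale,
                 groups = unique(vapply(samples, function(s) s$group_id, character(1)))),
            class = "encoded_dataset")
}

#' @export
print.encoded_dataset <- function(x, ...) {
  cat(sprintf("<encoded_dataset> %d samples, %d groups, vc_scale = %g\n",
              length(x$samples), length(x$groups), x$vc_scale))
  invisible(x)
}

#' Save an encoded dataset (array archive + JSON sidecar)
#'
#' Writes the stacked arrays to an RDS archive and a JSON sidecar recording
#' labels, the day-axis mapping, and the target scale.
#'
#' @param dataset An `encoded_dataset`.
#' @param path Path of the `.rds` archive; the sidecar gets `.json` added.
#' @return `path`, invisibly.
#' @export
save_encoded_dataset <- function(dataset, path) {
  arr <- stack_dataset(dataset)
  saveRDS(arr, path)
  sidecar <- list(
    n_samples = length(dataset$samples),
    vc_scale = dataset$vc_scale,
    seq_len = PULSAR_SEQ_LEN,
    group_id = vapply(dataset$samples, function(s) s$group_id, character(1)),
    sample_id = vapply(dataset$samples, function(s) s$sample_id, character(1)),
    day_axis = list(step1_relative_day = -3L, first_pulse_relative_day = 0L)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Stack an encoded dataset into dense arrays
#'
#' @param dataset An `encoded_dataset`.
#' @return List of arrays: `rad`, `drug` (28 x 5 x n), `targets`, `mask`
#'   (28 x n).
#' @keywords internal
stack_dataset <- function(dataset) {
  n <- length(dataset$samples)
  rad <- array(0, c(PULSAR_SEQ_LEN, 5L, n))
  drug <- array(0, c(PULSAR_SEQ_LEN, 5L, n))
  targets <- matrix(0, PULSAR_SEQ_LEN, n)
  mask <- matrix(FALSE, PULSAR_SEQ_LEN, n)
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    rad[, , i] <- s$radiation_seq
    drug[, , i] <- s$drug_seq
    targets[, i] <- s$target$values
    mask[, i] <- s$target$mask
  }
  list(rad = rad, drug = drug, targets = targets, mask = mask)
}
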
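#' @useDynLib pulsarformer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Day-axis conventions
# --------------------
# The modeling axis has 28 consecutive calendar days (steps). Step 1 is the
# first measurement day, which falls three days before the first radiation
# pulse. Two day conventions coexist:
#   * treatment days: integer, day 1 = day of the first pulse (event tables,
#     group labels such as "20Gyd1+20Gyd10");
#   * relative days: integer, day 0 = day of the first pulse (measurement
#     schedules, range -3 .. 24).
# treatment day d  -> step d + 3;  relative day r -> step r + 4.

#' Number of steps (days) on the modeling axis
#' @export
PULSAR_SEQ_LEN <- 28L

#' Convert a treatment day (day 1 = first pulse) to a step index
#'
#' @param day Integer treatment day.
#' @return 1-based step index on the 28-step axis.
#' @export
treatment_day_to_step <- function(day) {
  step <- as.integer(day) + 3L
  if (any(step < 1L | step > PULSAR_SEQ_LEN)) {
    stop("treatment day out of the 28-day course: ", toString(day[step < 1L | step > PULSAR_SEQ_LEN]))
  }
  step
}

#' Convert a measurement day relative to the first pulse to a step index
#'
#' @param day Integer day relative to the first pulse (day 0 = first pulse).
#' @return 1-based step index.
#' @export
relative_day_to_step <- function(day) {
  step <- as.integer(day) + 4L
  if (any(step < 1L | step > PULSAR_SEQ_LEN)) {
    stop("measurement day out of the 28-day course: ", toString(day[step < 1L | step > PULSAR_SEQ_LEN]))
  }
  step
}

#' A single radiation pulse
#'
#' @param day Integer treatment day (day 1 = first pulse).
#' @param dose Dose in Gy, positive.
#' @return A `radiation_event` list.
#' @export
radiation_event <- function(day, dose) {
  day <- as.integer(day)
  stopifnot(length(day) == 1L, length(dose) == 1L)
  if (!is.finite(dose) || dose <= 0) stop("radiation dose must be positive, got ", dose)
  treatment_day_to_step(day) # bounds check
  structure(list(day = day, dose = as.numeric(dose)), class = "radiation_event")
}

#' A single drug administration
#'
#' @param day Integer treatment day.
#' @param agent `"anti-PD-L1"` or `"isotype"`. The isotype control antibody
#'   carries no checkpoint blockade and encodes as the no-drug condition.
#' @return A `drug_event` list.
#' @export
drug_event <- function(day, agent = c("anti-PD-L1", "isotype")) {
  day <- as.integer(day)
  agent <- match.arg(agent)
  treatment_day_to_step(day)
  structure(list(day = day, agent = agent), class = "drug_event")
}

#' A treatment-group schedule
#'
#' Bundles the radiation pulses, antibody administrations, and tumor-volume
#' measurement days of one experimental arm.
#'
#' @param group_id Character label, e.g. `"g08_20Gyd1+20Gyd10_aPDL1"`.
#' @param radiation List of [radiation_event()]s.
#' @param drug List of [drug_event()]s.
#' @param measurement_days Strictly increasing integer days relative to the
#'   first pulse (day 0 = first pulse); defaults to the six-day schedule
#'   starting three days before the first pulse.
#' @return A `treatment_schedule` object.
#' @export
treatment_schedule <- function(group_id, radiation = list(), drug = list(),
                               measurement_days = default_measurement_days()) {
  stopifnot(is.character(group_id), length(group_id) == 1L)
  measurement_days <- as.integer(measurement_days)
  if (length(measurement_days) < 2L || any(diff(measurement_days) <= 0L)) {
    stop("measurement_days must be strictly increasing with at least two entries")
  }
  relative_day_to_step(measurement_days) # bounds check
  rad_days <- vapply(radiation, function(e) e$day, integer(1))
  if (anyDuplicated(rad_days)) stop("two radiation pulses on the same day")
  for (e in radiation) if (!inherits(e, "radiation_event")) stop("radiation must be radiation_event objects")
  for (e in drug) if (!inherits(e, "drug_event")) stop("drug must be drug_event objects")
  structure(
    list(group_id = group_id,
         radiation = radiation[order(rad_days)],
         drug = drug,
         measurement_days = measurement_days),
    class = "treatment_schedule"
  )
}

#' Default tumor-volume measurement days
#'
#' Six sparse measurement days relative to the first pulse: three days before
#' the first pulse, the day of the first pulse, four days after it, and three
#' later follow-ups. Six measurements yield five volume-change targets.
#'
#' @return Integer vector of length 6.
#' @export
default_measurement_days <- function() c(-3L, 0L, 4L, 9L, 14L, 20L)

#' @export
print.treatment_schedule <- function(x, ...) {
  rad <- if (length(x$radiation) == 0L) "none" else
    paste(vapply(x$radiation, function(e) sprintf("%gGy d%d", e$dose, e$day), character(1)), collapse = " + ")
  drg <- if (length(x$drug) == 0L) "none" else
    paste(vapply(x$drug, function(e) sprintf("%s d%d", e$agent, e$day), character(1)), collapse = ", ")
  cat(sprintf("<treatment_schedule> %s\n  radiation: %s\n  drug: %s\n  measurement days (rel. to first pulse): %s\n",
              x$group_id, rad, drg, toString(x$measurement_days)))
  invisible(x)
}

#' Whether a schedule includes checkpoint blockade
#' @param schedule A `treatment_schedule`.
#' @return Logical.
#' @export
has_pdl1 <- function(schedule) {
  any(vapply(schedule$drug, function(e) e$agent == "anti-PD-L1", logical(1)))
}

#' The default 24-group treatment roster
#'
#' Twelve radiation arms crossed with isotype control / anti-PD-L1 antibody.
#' Odd group numbers receive the isotype control, even numbers the antibody.
#' Arms 1-6 are the named experimental arms (control, 20 Gy d1, 40 Gy d1,
#' 20 Gy d1+d10, 10 Gy d1+d2, 10 Gy d1+d10); arms 7-12 are further
#' dose/interval permutations over {10, 15, 20, 40} Gy and {1, 2, 4, 10}-day
#' spacings completing the 24-group roster. Antibody doses are given on
#' treatment days 1 and 10.
#'
#' @param measurement_days Measurement schedule shared by all groups.
#' @return A list of 24 [treatment_schedule()] objects, named by group id.
#' @export
build_default_groups <- function(measurement_days = default_measurement_days()) {
  arms <- list(
    list(tag = "noRT",            rad = list()),
    list(tag = "20Gyd1",          rad = list(c(1, 20))),
    list(tag = "40Gyd1",          rad = list(c(1, 40))),
    list(tag = "20Gyd1+20Gyd10",  rad = list(c(1, 20), c(10, 20))),
    list(tag = "10Gyd1+10Gyd2",   rad = list(c(1, 10), c(2, 10))),
    list(tag = "10Gyd1+10Gyd10",  rad = list(c(1, 10), c(10, 10))),
    list(tag = "15Gyd1",          rad = list(c(1, 15))),
    list(tag = "10Gyd1",          rad = list(c(1, 10))),
    list(tag = "15Gyd1+15Gyd10",  rad = list(c(1, 15), c(10, 15))),
    list(tag = "20Gyd1+20Gyd2",   rad = list(c(1, 20), c(2, 20))),
    list(tag = "20Gyd1+20Gyd4",   rad = list(c(1, 20), c(4, 20))),
    list(tag = "10Gyd1+10Gyd4",   rad = list(c(1, 10), c(4, 10)))
  )
  drug_days <- c(1L, 10L)
  groups <- vector("list", 24L)
  g <- 0L
  for (arm in arms) {
    rad <- lapply(arm$rad, function(p) radiation_event(p[1], p[2]))
    for (agent in c("isotype", "anti-PD-L1")) {
      g <- g + 1L
      suffix <- if (agent == "anti-PD-L1") "aPDL1" else "iso"
      id <- sprintf("g%02d_%s_%s", g, arm$tag, suffix)
      groups[[g]] <- treatment_schedule(
        group_id = id,
        radiation = rad,
        drug = lapply(drug_days, function(d) drug_event(d, agent)),
        measurement_days = measurement_days
      )
    }
  }
  names(groups) <- vapply(groups, function(s) s$group_id, character(1))
  groups
}

#' Look up a roster schedule by group number or id
#'
#' @param groups A list of schedules as from [build_default_groups()].
#' @param id Integer group number (position) or character group id.
#' @return A `treatment_schedule`.
#' @export
get_group <- function(groups, id) {
  if (is.numeric(id)) {
    if (id < 1 || id > length(groups)) stop("no group number ", id)
    return(groups[[as.integer(id)]])
  }
  hit <- which(names(groups) == id)
  if (length(hit) == 0L) {
    # allow matching by the bare arm tag, e.g. "g04" prefix
    hit <- grep(paste0("^", id), names(groups))
  }
  if (length(hit) != 1L) stop("unknown group id: ", id)
  groups[[hit]]
}

#' Write schedules to a delimited event table
#'
#' One row per event with columns `group_id`, `event_type` (`RT`/`DRUG`),
#' `day`, `dose_Gy`, `agent`. Groups without events contribute a single
#' `NONE` row so the roster round-trips.
#'
#' @param groups List of schedules.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedules <- function(groups, path) {
  rows <- list()
  for (s in groups) {
    for (e in s$radiation) {
      rows[[length(rows) + 1L]] <- data.frame(group_id = s$group_id, event_type = "RT",
                                              day = e$day, dose_Gy = e$dose, agent = NA_character_)
    }
    for (e in s$drug) {
      rows[[length(rows) + 1L]] <- data.frame(group_id = s$group_id, event_type = "DRUG",
                                              day = e$day, dose_Gy = NA_real_, agent = e$agent)
    }
    if (length(s$radiation) + length(s$drug) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(group_id = s$group_id, event_type = "NONE",
                                              day = NA_integer_, dose_Gy = NA_real_, agent = NA_character_)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read schedules from a delimited event table
#'
#' @param path CSV path in the [write_schedules()] layout.
#' @param measurement_days Measurement schedule to attach to every group.
#' @return Named list of `treatment_schedule` objects.
#' @export
read_schedules <- function(path, measurement_days = default_measurement_days()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group_id", "event_type", "day")
  if (!all(need %in% names(df))) stop("schedule file must have columns: ", toString(need))
  out <- lapply(split(df, factor(df$group_id, levels = unique(df$group_id))), function(d) {
    rt <- d[d$event_type == "RT", , drop = FALSE]
    dr <- d[d$event_type == "DRUG", , drop = FALSE]
    treatment_schedule(
      group_id = d$group_id[1],
      radiation = lapply(seq_len(nrow(rt)), function(i) radiation_event(rt$day[i], rt$dose_Gy[i])),
      drug = lapply(seq_len(nrow(dr)), function(i) drug_event(dr$day[i], dr$agent[i])),
      measurement_days = measurement_days
    )
  })
  names(out) <- vapply(out, function(s) s$group_id, character(1))
  out
}
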
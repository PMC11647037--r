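test_that("caliper volume and survival-endpoint rules", {
  expect_equal(volume_from_calipers(10, 10, 10), 500)
  expect_equal(volume_from_calipers(1, 1, 2), 1)
  expect_equal(volume_from_calipers(20, 15, 10), 1500)
  expect_error(volume_from_calipers(0, 1, 1), "positive")
  expect_error(volume_from_calipers(5, -2, 1), "positive")

  expect_true(endpoint_reached(21, 5, 5, 262.5))    # dimension rule
  expect_false(endpoint_reached(10, 10, 10, 500))   # all criteria unmet
  expect_true(endpoint_reached(15, 15, 14, 1575))   # volume rule
  expect_error(endpoint_reached(0, 1, 1, 1), "positive")
})

test_that("linear-quadratic survival: closed form, bounds, monotonicity", {
  expect_equal(lq_survival(0, 0.3, 0.03), 1)
  expect_equal(lq_survival(2, 0.3, 0.03), exp(-0.72))
  expect_equal(round(lq_survival(2, 0.3, 0.03), 4), 0.4868)
  expect_equal(lq_survival(40, 0.3, 0.03), exp(-60))
  expect_error(lq_survival(-1, 0.3, 0.03), "nonnegative")
  doses <- seq(0, 40, by = 0.5)
  s <- lq_survival(doses, 0.25, 0.025)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
})

test_that("free growth matches the closed-form exponential oracle", {
  # 10 days of growth at lam = 0.1 from V0 = 100 -> 100 * e
  sched <- fx_free_schedule(days = c(-3L, 7L))
  pk <- tumor_kinetics_params(V0 = 100, lam = 0.1)
  tr <- simulate_mean_trajectory(sched, pk)
  expect_equal(tr$volumes[2], 100 * exp(1), tolerance = 1e-9)

  # every measurement day, generic schedule, tight relative tolerance
  sched6 <- fx_free_schedule()
  pk2 <- tumor_kinetics_params(V0 = 80, lam = 0.12)
  tr6 <- simulate_mean_trajectory(sched6, pk2)
  t_el <- tr6$days - tr6$days[1]
  expect_equal(tr6$volumes, 80 * exp(0.12 * t_el), tolerance = 1e-9)
})

test_that("null drug effect reproduces the control trajectory exactly", {
  pk <- tumor_kinetics_params(drug_kill = 0)
  ctrl <- simulate_mean_trajectory(fx_groups[["g01_noRT_iso"]], pk)
  drug <- simulate_mean_trajectory(fx_groups[["g02_noRT_aPDL1"]], pk)
  expect_identical(ctrl$volumes, drug$volumes)
  # no radiation arm: drug alone has no synergy partner, matches control
  pk2 <- tumor_kinetics_params()
  drug2 <- simulate_mean_trajectory(fx_groups[["g02_noRT_aPDL1"]], pk2)
  ctrl2 <- simulate_mean_trajectory(fx_groups[["g01_noRT_iso"]], pk2)
  expect_identical(ctrl2$volumes, drug2$volumes)
})

test_that("a single pulse with frozen regrowth applies exactly the LQ factor", {
  sched <- treatment_schedule("one_pulse",
                              radiation = list(radiation_event(1, 20)),
                              measurement_days = c(-3L, 0L, 4L, 9L))
  pk <- tumor_kinetics_params(V0 = 60, lam = 0.15, repop_lag = Inf, drug_kill = 0)
  tr <- simulate_mean_trajectory(sched, pk)
  pre_pulse <- 60 * exp(0.15 * 3)  # growth up to the pulse day
  expect_equal(tr$volumes[2], pre_pulse, tolerance = 1e-12)
  surv <- lq_survival(20, pk$alpha, pk$beta)
  # no regrowth after the pulse: all later measurements equal pre * surv
  expect_equal(tr$volumes[3], pre_pulse * surv, tolerance = 1e-12)
  expect_equal(tr$volumes[4], pre_pulse * surv, tolerance = 1e-12)
})

test_that("increasing drug_kill never increases any reported volume", {
  sched <- fx_groups[["g08_20Gyd1+20Gyd10_aPDL1"]]
  kills <- c(0, 0.05, 0.15, 0.4)
  trajs <- lapply(kills, function(k)
    simulate_mean_trajectory(sched, tumor_kinetics_params(drug_kill = k)))
  for (i in seq_len(length(kills) - 1L)) {
    a <- trajs[[i]]; b <- trajs[[i + 1L]]
    shared <- intersect(a$days, b$days)
    expect_true(all(b$volumes[match(shared, b$days)] <=
                    a$volumes[match(shared, a$days)] + 1e-12))
  }
})

test_that("synergy kernel peaks at the lag and vanishes outside its window", {
  tau <- 0:15
  g <- synergy_kernel(tau, synergy_lag = 5, synergy_width = 3)
  expect_equal(g[6], 1)                       # tau = 5: peak value 1
  expect_equal(which.max(g), 6L)
  expect_true(all(g[tau > 9] == 0))           # truncated at 3 * width
  expect_equal(g[1], 0)                       # tau = 0
  expect_equal(synergy_kernel(-1, 5, 3), 0)   # before the pulse
  expect_true(all(g >= 0 & g <= 1))
})

test_that("endpoint censoring truncates trajectories and is monotone in growth rate", {
  ctrl <- simulate_mean_trajectory(fx_groups[["g01_noRT_iso"]], fx_kinetics)
  expect_false(is.null(ctrl$censored_from))
  expect_true(all(ctrl$days < ctrl$censored_from))
  expect_true(all(ctrl$volumes <= 1500))

  cens_day <- function(lam) {
    tr <- simulate_mean_trajectory(fx_groups[["g01_noRT_iso"]],
                                   tumor_kinetics_params(lam = lam))
    if (is.null(tr$censored_from)) Inf else tr$censored_from
  }
  lams <- c(0.10, 0.14, 0.18, 0.25, 0.35)
  days <- vapply(lams, cens_day, numeric(1))
  expect_true(all(diff(days) <= 0))
})

test_that("uniform augmentation: bounds, convergence, and determinism", {
  mt <- simulate_mean_trajectory(fx_groups[["g03_20Gyd1_iso"]], fx_kinetics)

  co0 <- augment_group(mt, 5, 0, seed = 1)
  for (s in co0$samples) expect_identical(s$volumes, mt$volumes)

  n_big <- 10000L
  co <- augment_group(mt, n_big, 0.10, seed = 2)
  vols <- do.call(rbind, lapply(co$samples, `[[`, "volumes"))
  for (j in seq_along(mt$volumes)) {
    expect_true(all(vols[, j] >= mt$volumes[j] * 0.9))
    expect_true(all(vols[, j] <= mt$volumes[j] * 1.1))
    expect_lt(abs(mean(vols[, j]) / mt$volumes[j] - 1), 0.01)
  }

  co_a <- augment_group(mt, 50, 0.15, seed = 7)
  co_b <- augment_group(mt, 50, 0.15, seed = 7)
  expect_identical(co_a, co_b)
  co_c <- augment_group(mt, 50, 0.15, seed = 8)
  expect_false(identical(co_a, co_c))

  expect_error(augment_group(mt, 0, 0.1, 1), "at least 1")
  expect_error(augment_group(mt, 5, 1.2, 1), "noise_level")
  empty <- mt; empty$days <- integer(0); empty$volumes <- numeric(0)
  expect_error(augment_group(empty, 5, 0.1, 1), "empty")
})

test_that("default roster: 24 groups with the named arms in place", {
  expect_length(fx_groups, 24L)
  g1 <- fx_groups[[1]]
  expect_length(g1$radiation, 0L)
  expect_false(has_pdl1(g1))
  g2 <- fx_groups[[2]]
  expect_length(g2$radiation, 0L)
  expect_true(has_pdl1(g2))
  g8 <- fx_groups[[8]]
  expect_equal(vapply(g8$radiation, `[[`, numeric(1), "dose"), c(20, 20))
  expect_equal(vapply(g8$radiation, `[[`, integer(1), "day"), c(1L, 10L))
  expect_true(has_pdl1(g8))
  g12 <- fx_groups[[12]]
  expect_equal(vapply(g12$radiation, `[[`, numeric(1), "dose"), c(10, 10))
  expect_equal(vapply(g12$radiation, `[[`, integer(1), "day"), c(1L, 10L))
  # isotype/antibody alternation across the roster
  expect_equal(vapply(fx_groups, has_pdl1, logical(1)),
               rep(c(FALSE, TRUE), 12L), ignore_attr = TRUE)
  expect_false(anyDuplicated(names(fx_groups)) > 0)
})

test_that("schedule event tables round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedules(fx_groups, path)
  back <- read_schedules(path)
  expect_equal(names(back), names(fx_groups))
  for (g in names(fx_groups)) {
    expect_equal(vapply(back[[g]]$radiation, `[[`, numeric(1), "dose"),
                 vapply(fx_groups[[g]]$radiation, `[[`, numeric(1), "dose"))
    expect_equal(vapply(back[[g]]$drug, `[[`, character(1), "agent"),
                 vapply(fx_groups[[g]]$drug, `[[`, character(1), "agent"))
  }
})

test_that("schedule and event validation rejects malformed input", {
  expect_error(radiation_event(1, 0), "positive")
  expect_error(radiation_event(26, 10), "out of the 28-day course")
  expect_error(drug_event(1, "aspirin"))
  expect_error(treatment_schedule("x", radiation = list(radiation_event(1, 10),
                                                        radiation_event(1, 20))),
               "same day")
  expect_error(treatment_schedule("x", measurement_days = c(0, 0, 4)),
               "strictly increasing")
  expect_error(treatment_schedule("x", measurement_days = c(-3, 25)),
               "out of the 28-day course")
})
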
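test_that("positional codes are zero-phase at day 0, bounded, and injective", {
  expect_equal(positional_code(0), c(0, 1, 0, 1))
  codes <- t(vapply(0:27, positional_code, numeric(4)))
  expect_true(all(codes >= -1 & codes <= 1))
  # brute-force pairwise distinctness over all 28 positions
  for (i in 1:27) for (j in (i + 1):28) {
    expect_false(isTRUE(all.equal(codes[i, ], codes[j, ])))
  }
  expect_error(positional_code(28), "0..27")
  expect_error(positional_code(-1), "0..27")
})

test_that("radiation encoding places normalized doses at pulse steps", {
  ctrl <- encode_radiation(fx_groups[["g01_noRT_iso"]])
  expect_equal(dim(ctrl), c(28L, 5L))
  expect_true(all(ctrl[, 1] == 0))

  g40 <- encode_radiation(fx_groups[["g05_40Gyd1_iso"]])
  expect_equal(unname(g40[4, 1]), 1.0)  # 40/40 at the step of treatment day 1
  expect_equal(sum(g40[, 1] != 0), 1L)

  g8 <- encode_radiation(fx_groups[["g08_20Gyd1+20Gyd10_aPDL1"]])
  nz <- which(g8[, 1] != 0)
  expect_equal(g8[nz, 1], c(0.5, 0.5), ignore_attr = TRUE)
  expect_equal(diff(nz), 9L)  # d1 and d10 are nine steps apart
})

test_that("drug encoding marks anti-PD-L1 days and zeros isotype", {
  iso <- encode_drug(fx_groups[["g03_20Gyd1_iso"]])
  expect_true(all(iso[, 1] == 0))

  ab <- encode_drug(fx_groups[["g04_20Gyd1_aPDL1"]])
  expect_equal(which(ab[, 1] != 0), c(4L, 13L))  # days 1 and 10
  expect_true(all(ab[ab[, 1] != 0, 1] == 1))

  g2_rad <- encode_radiation(fx_groups[["g02_noRT_aPDL1"]])
  g2_drug <- encode_drug(fx_groups[["g02_noRT_aPDL1"]])
  expect_true(all(g2_rad[, 1] == 0))
  expect_true(any(g2_drug[, 1] != 0))
})

test_that("positional channels are identical across sequences at every step", {
  for (g in c(1, 8, 17)) {
    r <- encode_radiation(fx_groups[[g]])
    d <- encode_drug(fx_groups[[g]])
    expect_identical(r[, 2:5], d[, 2:5])
  }
})

test_that("the paired encoding separates all 24 default groups", {
  keys <- vapply(fx_groups, function(s) {
    paste(c(encode_radiation(s)[, 1], encode_drug(s)[, 1]), collapse = ",")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("volume changes: placement, count, sign, and edge cases", {
  tr <- trajectory(c(-3L, 0L, 4L), c(100, 150, 130))
  tgt <- compute_volume_changes(tr)
  expect_equal(tgt$values[tgt$mask], c(50, -20))
  expect_equal(which(tgt$mask), c(4L, 8L))  # steps of the later days
  expect_true(all(tgt$values[!tgt$mask] == 0))

  tr6 <- trajectory(default_measurement_days(), c(100, 170, 240, 300, 420, 600))
  expect_equal(sum(compute_volume_changes(tr6)$mask), 5L)

  flat <- trajectory(c(0L, 4L, 9L), c(200, 200, 200))
  tgt_flat <- compute_volume_changes(flat)
  expect_true(all(tgt_flat$values == 0))
  expect_equal(sum(tgt_flat$mask), 2L)

  expect_error(compute_volume_changes(trajectory(0L, 100)), "two measurement")
})

test_that("summed masked changes telescope to last-minus-first volume", {
  tr <- trajectory(c(-3L, 0L, 4L), c(100, 150, 130))
  expect_equal(recover_total_change(compute_volume_changes(tr)), 30)
  zero <- target_sequence(numeric(28), logical(28))
  expect_equal(recover_total_change(zero), 0)
  set.seed(99)
  for (i in 1:100) {
    tr <- fx_random_trajectory(sample(2:10, 1))
    got <- recover_total_change(compute_volume_changes(tr))
    want <- tr$volumes[length(tr$volumes)] - tr$volumes[1]
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("target sequences reject values at unmasked steps", {
  v <- numeric(28); v[3] <- 1
  expect_error(target_sequence(v, logical(28)), "unmasked")
})

test_that("dataset assembly: counts, scaling, and censoring drops", {
  ds <- fx_dataset(group_idx = c(1, 4), n = 5L, noise = 0, seed = 3)
  expect_length(ds$samples, 10L)
  s <- ds$samples[[1]]
  expect_equal(dim(s$radiation_seq), c(28L, 5L))
  expect_equal(dim(s$drug_seq), c(28L, 5L))

  # vc_scale converts mm^3 changes to model units
  ds_mm <- fx_dataset(group_idx = 4, n = 1L, noise = 0, seed = 3, vc_scale = 1)
  ds_cm <- fx_dataset(group_idx = 4, n = 1L, noise = 0, seed = 3, vc_scale = 1e-3)
  expect_equal(ds_cm$samples[[1]]$target$values,
               ds_mm$samples[[1]]$target$values * 1e-3)

  # a heavily censored replicate (single surviving point) is dropped
  one_pt <- trajectory(-3L, 100, censored_from = 0L, group_id = "g01_noRT_iso")
  co <- cohort("g01_noRT_iso", list(one_pt), 0)
  expect_warning(ds2 <- encode_dataset(list(co), fx_groups), "dropped")
  expect_length(ds2$samples, 0L)
})
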
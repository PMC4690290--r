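# Re-referencing arithmetic, epoch bookkeeping, the strict amplitude
# criterion, and the band-power estimator's spectral properties.

test_that("re-referencing subtracts the reference and keeps the right channels", {
  sig <- matrix(c(10, 2, 4, 6), nrow = 4, ncol = 3)
  rec <- toy_recording(sig, c("F3", "TP9", "TP10", "Cz"))
  mast <- rereference(rec, "mastoid")
  expect_identical(mast$channel_names, c("F3", "Cz"))
  expect_equal(unname(mast$signal["F3", 1]), 10 - 3)  # mean(TP9, TP10) = 3
  cz <- rereference(rec, "cz")
  expect_true(all(cz$signal["Cz", ] == 0))
  expect_equal(unname(cz$signal["F3", 1]), 10 - 6)
  expect_identical(cz$channel_names, rec$channel_names)

  zero_ref <- toy_recording(rbind(sig[1, , drop = FALSE], 0, 0),
                            c("F3", "TP9", "TP10"))
  expect_equal(rereference(zero_ref, "mastoid")$signal["F3", ],
               zero_ref$signal["F3", ])
  expect_error(rereference(toy_recording(sig[1:2, ], c("F3", "F4")), "mastoid"),
               "TP9")
  expect_error(rereference(toy_recording(sig[1:2, ], c("F3", "F4")), "cz"), "Cz")
})

test_that("epoch segmentation follows the sliding-window count formula", {
  cases <- list(
    list(duration = 180, epoch = 2, overlap = 0.5, expected = 179),
    list(duration = 2, epoch = 2, overlap = 0.5, expected = 1),
    list(duration = 10, epoch = 2, overlap = 0, expected = 5)
  )
  for (cs in cases) {
    rec <- toy_recording(matrix(0, 2, cs$duration * 500), c("F3", "F4"))
    ep <- segment_epochs(rec, cs$epoch, cs$overlap)
    expect_equal(dim(ep$epochs)[1], cs$expected)
    expect_equal(dim(ep$epochs)[3], cs$epoch * 500)
  }
  short <- toy_recording(matrix(0, 2, 100), c("F3", "F4"))
  expect_error(segment_epochs(short), "shorter")
})

test_that("artifact rejection uses a strict criterion and is idempotent", {
  arr <- array(0, dim = c(3, 2, 10))
  arr[1, 1, 5] <- 80    # above: rejected
  arr[2, 2, 3] <- 75    # exactly at threshold: retained
  arr[3, 1, 1] <- -76   # below -75: rejected
  ep <- as_epochs(arr)
  kept <- suppressMessages(reject_artifacts(ep))
  expect_equal(kept$n_retained, 1)
  expect_equal(kept$epochs[1, 2, 3], 75)
  again <- suppressMessages(reject_artifacts(kept))
  expect_equal(again$n_retained, 1)
  expect_equal(again$epochs, kept$epochs)
  all_bad <- as_epochs(array(100, dim = c(2, 1, 4)))
  expect_warning(kept0 <- reject_artifacts(all_bad), "rejected")
  expect_equal(kept0$n_retained, 0)
})

test_that("band power vanishes for silence and localizes a pure sinusoid", {
  silent <- suppressMessages(reject_artifacts(segment_epochs(
    toy_recording(matrix(0, 2, 2000), c("F3", "F4")))))
  bp0 <- band_power(silent)
  expect_true(all(bp0$power == 0))
  expect_true(all(bp0$ln_power == -Inf))

  rec <- sine_recording(freq = 10, amplitude = 1, duration = 4,
                        channels = c("O1", "O2"))
  bp <- band_power(segment_epochs(rec))
  o1 <- bp[bp$channel == "O1", ]
  total_1_30 <- sum(o1$power[o1$band %in% c("delta", "theta", "alpha1", "alpha2", "beta")])
  expect_gte(o1$power[o1$band == "alpha1"] / total_1_30, 0.9)
  # one-sided scaling: a unit sinusoid carries mean-square power 1/2
  expect_equal(o1$power[o1$band == "alpha1"], 0.5, tolerance = 0.05)
  expect_error(band_power(segment_epochs(rec), tibble::tibble(
    band = "hf", low = 200, high = 400)), "fs/2")
})

test_that("white noise is spectrally flat per Hz and invariant to epoch order", {
  set.seed(42)
  arr <- array(rnorm(100 * 1 * 1000), dim = c(100, 1, 1000))
  ep <- as_epochs(arr)
  bands <- eeg_bands(c("delta", "theta", "alpha", "beta"))
  bp <- band_power(ep, bands)
  per_hz <- bp$power / (bp$high - bp$low)
  expect_lt(max(per_hz) / min(per_hz), 1.2 / 0.8)

  shuffled <- as_epochs(arr[sample(100), , , drop = FALSE])
  expect_equal(band_power(shuffled, bands)$power, bp$power)
})

test_that("total spectral power matches window-corrected time-domain variance", {
  fs <- 500
  t <- seq(0, by = 1 / fs, length.out = 1000)
  x <- 2 * sin(2 * pi * 7 * t) + sin(2 * pi * 21 * t + 1)
  ep <- as_epochs(array(x, dim = c(1, 1, 1000)), fs = fs)
  wide <- tibble::tibble(band = "all", low = 0.25, high = 249.5)
  total <- band_power(ep, wide)$power
  expect_equal(total, mean((x - mean(x))^2), tolerance = 0.05)
})

test_that("feature tables assemble with the expected shape, order and ln option", {
  cfg <- synth_config(electrodes = c("O1", "O2", "Fz", "Cz"),
                      bands = eeg_bands(c("alpha", "beta")),
                      informative_features = 1:2,
                      duration = 6, seed = 5)
  recs <- tibble::tibble(
    sample_id = c("MDD_01", "MDD_02", "HV_01"),
    label = c("MDD", "MDD", "HV"),
    condition = "EC",
    recording = list(generate_recording(cfg, "MDD", seed = 1),
                     generate_recording(cfg, "MDD", seed = 2),
                     generate_recording(cfg, "HV", seed = 3))
  )
  tab <- build_feature_table(recs, bands = eeg_bands(c("alpha", "beta")),
                             reference = "mastoid")
  expect_equal(dim(tab), c(3, 2 + 4 * 2))
  expect_identical(feature_names(tab)[1:2],
                   c("O1_alpha_EC_mastoid", "O1_beta_EC_mastoid"))
  ln_tab <- build_feature_table(recs, bands = eeg_bands(c("alpha", "beta")),
                                reference = "mastoid", power = "ln")
  expect_equal(as.matrix(ln_tab[feature_names(ln_tab)]),
               log(as.matrix(tab[feature_names(tab)])))
})
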
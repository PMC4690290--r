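# The generator must reproduce the emulated study's structure (sample sizes,
# feature layout, positivity) and the statistical properties the pipeline
# assumes (controlled effect size on informative features only).

test_that("generation is deterministic under a seed and varies across seeds", {
  a <- generate_feature_table(synth_config(seed = 7))
  b <- generate_feature_table(synth_config(seed = 7))
  c <- generate_feature_table(synth_config(seed = 8))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(ft <- as.matrix(a[feature_names(a)]),
                                as.matrix(c[feature_names(c)]))))
})

test_that("the all-bands design yields 112 strictly positive features with 53/43 labels", {
  tab <- generate_feature_table(synth_config(seed = 1))
  expect_length(feature_names(tab), 112)
  expect_equal(unname(table(tab$label)[c("MDD", "HV")]), c(53, 43),
               ignore_attr = TRUE)
  expect_true(all(as.matrix(tab[feature_names(tab)]) > 0))
  expect_identical(attr(tab, "value_kind"), "absolute_power")
  # electrode-major naming convention
  expect_identical(feature_names(tab)[1:4],
                   paste0("Fp1_", c("delta", "theta", "alpha1", "beta"), "_EC_mastoid"))
})

test_that("invalid configurations are rejected with messages", {
  expect_error(synth_config(effect_size = -1), "effect_size")
  expect_error(synth_config(n_mdd = 1), "at least 2")
  expect_error(synth_config(informative_features = 1:500), "index")
  expect_error(synth_config(noise_corr = 1), "noise_corr")
})

test_that("the configured effect size is realized on the log scale", {
  tab <- small_table(n_mdd = 250, n_hv = 250, p = 6, informative = 1:3,
                     d = 1.5, seed = 11)
  z <- log(as.matrix(tab[feature_names(tab)]))
  is_mdd <- tab$label == "MDD"
  d_hat <- vapply(1:3, function(j) {
    sp <- sqrt((var(z[is_mdd, j]) + var(z[!is_mdd, j])) / 2)
    (mean(z[is_mdd, j]) - mean(z[!is_mdd, j])) / sp
  }, 0)
  expect_true(all(abs(d_hat - 1.5) < 0.3))
})

test_that("non-informative features carry no detectable class difference", {
  hits <- vapply(1:100, function(s) {
    tab <- small_table(n_mdd = 20, n_hv = 20, p = 6, informative = 1:2,
                       d = 2, seed = 1000 + s)
    z <- log(tab[[feature_names(tab)[5]]])
    stats::t.test(z[tab$label == "MDD"], z[tab$label == "HV"])$p.value > 0.01
  }, TRUE)
  expect_gte(sum(hits), 95)
})

test_that("zero effect size gives chance-level classification", {
  accs <- vapply(1:20, function(s) {
    train <- small_table(n_mdd = 25, n_hv = 25, p = 8, informative = integer(0),
                         d = 0, seed = 200 + s)
    test <- small_table(n_mdd = 25, n_hv = 25, p = 8, informative = integer(0),
                        d = 0, seed = 400 + s)
    fit <- fit_lda(train)
    100 * mean(predict(fit, test) == test$label)
  }, 0)
  expect_gt(mean(accs), 38)
  expect_lt(mean(accs), 62)
})

test_that("strong informative features allow near-perfect LDA classification,
           in agreement with an independent resubstitution oracle", {
  ours <- numeric(20)
  oracle <- numeric(20)
  for (s in 1:20) {
    tab <- small_table(n_mdd = 53, n_hv = 43, p = 10, informative = 1:10,
                       d = 3, seed = 500 + s)
    fit <- fit_lda(tab)
    ours[s] <- 100 * mean(predict(fit, tab) == tab$label)
    ref <- MASS::lda(as.matrix(tab[feature_names(tab)]), grouping = tab$label)
    oracle[s] <- 100 * mean(predict(ref)$class == tab$label)
  }
  expect_gte(mean(ours), 90)
  expect_gte(mean(oracle), 90)
  expect_lt(max(abs(ours - oracle)), 6)
})

test_that("eyes-closed alpha power exceeds eyes-open at occipital channels", {
  wins <- vapply(1:10, function(s) {
    cfg <- synth_config(electrodes = c("O1", "O2", "Oz", "Fz"),
                        bands = eeg_bands(c("alpha", "beta")),
                        informative_features = integer(0),
                        duration = 20, alpha_attenuation = 0.5, seed = s)
    alpha_occ <- function(cond) {
      rec <- generate_recording(cfg, "HV", cond, seed = 9000 + s)
      bp <- band_power(reject_artifacts(segment_epochs(rereference(rec, "mastoid"))))
      mean(bp$power[bp$band == "alpha" & bp$channel %in% c("O1", "O2", "Oz")])
    }
    suppressMessages(alpha_occ("EC") > alpha_occ("EO"))
  }, TRUE)
  expect_true(all(wins))
})

test_that("clean recordings respect the amplitude bound; injected artifacts do not", {
  cfg <- synth_config(electrodes = c("O1", "Fz"), informative_features = integer(0),
                      duration = 10, seed = 3)
  clean <- generate_recording(cfg)
  expect_lte(max(abs(clean$signal)), 75)
  arty <- generate_recording(synth_config(electrodes = c("O1", "Fz"),
                                          informative_features = integer(0),
                                          duration = 10, artifact_rate = 3, seed = 3))
  expect_gt(max(abs(arty$signal)), 75)
  ep <- segment_epochs(arty)
  kept <- suppressMessages(reject_artifacts(ep))
  expect_lt(kept$n_retained, ep$n_input)
})

test_that("silence in, silence out: no oscillations and no noise give a zero signal", {
  cfg <- synth_config(electrodes = c("O1", "Fz"),
                      bands = eeg_bands()[0, ],
                      informative_features = integer(0),
                      noise_sd = 0, duration = 4, seed = 1)
  rec <- generate_recording(cfg)
  expect_true(all(rec$signal == 0))
  expect_error(generate_recording(synth_config(duration = 1)), "epoch")
})

test_that("worked fixtures carry the printed operator strings and toy data", {
  fx <- worked_fixtures()
  expect_identical(fx$crossover_parents, c("111010011", "010111001"))
  expect_identical(fx$crossover_offspring, c("111011001", "010110011"))
  expect_identical(fx$mutation_input, "111010011")
  expect_identical(fx$mutation_output, "110010011")
  expect_equal(dim(fx$toy_table), c(6, 6))
  expect_length(feature_names(fx$toy_table), 4)
  expect_equal(fx$metric_pairs$lr_pos, c(8.09, 4.35))
})
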
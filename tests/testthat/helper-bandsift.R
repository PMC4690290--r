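# Shared fixtures and independent oracles used across the suite.

# Small synthetic table: p features, first `informative` carry effect d.
small_table <- function(n_mdd = 30, n_hv = 30, p = 10, informative = 1:3,
                        d = 2, seed = 1, rho = 0.2) {
  cfg <- synth_config(
    n_mdd = n_mdd, n_hv = n_hv,
    electrodes = paste0("E", seq_len(p)),
    bands = eeg_bands("alpha1"),
    conditions = "EC",
    informative_features = informative,
    effect_size = d, noise_corr = rho, seed = seed
  )
  generate_feature_table(cfg)
}

# Hand-made 3-channel (+refs) recording with known values.
toy_recording <- function(signal, channels, fs = 500, condition = "EC") {
  rownames(signal) <- channels
  structure(list(signal = signal, channel_names = channels,
                 fs = fs, condition = condition),
            class = "eeg_recording")
}

# recording holding a pure sinusoid on every channel
sine_recording <- function(freq, amplitude = 1, duration = 4, fs = 500,
                           channels = c("O1", "TP9", "TP10", "Cz")) {
  t <- seq(0, by = 1 / fs, length.out = duration * fs)
  sig <- matrix(rep(amplitude * sin(2 * pi * freq * t), length(channels)),
                nrow = length(channels), byrow = TRUE)
  toy_recording(sig, channels, fs = fs)
}

as_epochs <- function(arr, fs = 500) {
  structure(list(epochs = arr, channel_names = paste0("ch", seq_len(dim(arr)[2])),
                 fs = fs, epoch_length = dim(arr)[3] / fs, overlap = 0,
                 n_input = dim(arr)[1], n_retained = dim(arr)[1]),
            class = "epoch_set")
}

# --- independent oracles -----------------------------------------------------

# exhaustive depth-<=2 axis-aligned tree search: enumerate all root/child
# splits over candidate midpoints, score training accuracy, return the best
# tree's predictions (ties: first found in deterministic order).
oracle_depth2_predictions <- function(x, y) {
  y <- factor(as.character(y), levels = c("MDD", "HV"))
  majority <- function(yy) {
    if (length(yy) == 0) return(levels(y)[1])
    counts <- table(factor(yy, levels = levels(y)))
    levels(y)[which.max(counts)]
  }
  thresholds <- function(v) {
    u <- sort(unique(v))
    if (length(u) < 2) return(numeric(0))
    (u[-1] + u[-length(u)]) / 2
  }
  best_acc <- -1
  best_pred <- rep(majority(y), length(y))
  stumps <- function(idx) {
    # all (feature, threshold) pairs plus "no split"
    out <- list(list(feature = NA, threshold = NA))
    for (j in seq_len(ncol(x))) {
      for (th in thresholds(x[idx, j])) {
        out[[length(out) + 1]] <- list(feature = j, threshold = th)
      }
    }
    out
  }
  all_idx <- seq_len(nrow(x))
  for (root in stumps(all_idx)) {
    if (is.na(root$feature)) {
      pred <- rep(majority(y), length(y))
      acc <- mean(pred == y)
      if (acc > best_acc) { best_acc <- acc; best_pred <- pred }
      next
    }
    left <- which(x[, root$feature] <= root$threshold)
    right <- setdiff(all_idx, left)
    if (length(left) == 0 || length(right) == 0) next
    for (ls in stumps(left)) {
      pred_l <- rep(NA_character_, length(y))
      if (is.na(ls$feature)) {
        pred_l[left] <- majority(y[left])
      } else {
        ll <- left[x[left, ls$feature] <= ls$threshold]
        lr <- setdiff(left, ll)
        pred_l[ll] <- majority(y[ll])
        pred_l[lr] <- majority(y[lr])
      }
      for (rs in stumps(right)) {
        pred <- pred_l
        if (is.na(rs$feature)) {
          pred[right] <- majority(y[right])
        } else {
          rl <- right[x[right, rs$feature] <= rs$threshold]
          rr <- setdiff(right, rl)
          pred[rl] <- majority(y[rl])
          pred[rr] <- majority(y[rr])
        }
        acc <- mean(pred == y)
        if (acc > best_acc) { best_acc <- acc; best_pred <- pred }
      }
    }
  }
  factor(best_pred, levels = levels(y))
}

# 12-sample, 2-feature toy set: perfectly separable, but only by a
# two-level tree (no single axis-aligned split is pure). Values are
# deliberately discrete so the candidate-threshold set is small and the
# exhaustive search space is unambiguous.
depth2_toy <- function() {
  tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    label = factor(c(rep("MDD", 4), rep("HV", 4), rep("MDD", 4)),
                   levels = c("MDD", "HV")),
    f1 = c(rep(0.2, 4), rep(0.8, 4), rep(0.8, 4)),
    f2 = c(rep(0.3, 4), rep(0.3, 4), rep(0.9, 4))
  )
}
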
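# Spectral feature extraction: re-referencing, epoch segmentation,
# amplitude-based artifact rejection, Hann-windowed FFT band power.

#' Re-reference a multichannel recording
#'
#' `"mastoid"` subtracts the mean of TP9 and TP10 from every channel and then
#' drops TP9/TP10 (the linked-mastoid reference channels are not analysis
#' channels). `"cz"` subtracts the vertex channel Cz from every channel; Cz is
#' kept and becomes identically zero.
#'
#' @param rec An `eeg_recording`.
#' @param scheme `"mastoid"` or `"cz"`.
#' @return A re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, scheme = c("mastoid", "cz")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(rec, "eeg_recording"))
  ch <- rec$channel_names
  if (scheme == "mastoid") {
    if (!all(c("TP9", "TP10") %in% ch)) {
      abort("Mastoid re-referencing requires channels TP9 and TP10.")
    }
    ref <- colMeans(rec$signal[c("TP9", "TP10"), , drop = FALSE])
    keep <- setdiff(ch, c("TP9", "TP10"))
    sig <- sweep(rec$signal[keep, , drop = FALSE], 2, ref, `-`)
  } else {
    if (!"Cz" %in% ch) abort("Cz re-referencing requires a Cz channel.")
    ref <- rec$signal["Cz", ]
    keep <- ch
    sig <- sweep(rec$signal, 2, ref, `-`)
  }
  structure(list(signal = sig, channel_names = keep,
                 fs = rec$fs, condition = rec$condition),
            class = "eeg_recording")
}

#' Segment a recording into overlapping epochs
#'
#' Sliding windows of `epoch_length` seconds with step
#' `epoch_length * (1 - overlap)`; a partial trailing window is discarded.
#' A 180-s recording cut into 2-s epochs with 50% overlap yields 179 epochs.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length Epoch length in seconds (default 2).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @return An `epoch_set`: list with `epochs` (n_epochs x channels x samples
#'   array), `channel_names`, `fs`, `epoch_length`, `overlap`.
#' @export
segment_epochs <- function(rec, epoch_length = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  spe <- round(epoch_length * rec$fs)
  n_t <- ncol(rec$signal)
  if (n_t < spe) abort("Recording is shorter than one epoch.")
  step <- round(spe * (1 - overlap))
  starts <- seq(1, n_t - spe + 1, by = step)
  epochs <- array(0, dim = c(length(starts), nrow(rec$signal), spe))
  for (i in seq_along(starts)) {
    epochs[i, , ] <- rec$signal[, starts[i]:(starts[i] + spe - 1)]
  }
  structure(list(epochs = epochs, channel_names = rec$channel_names,
                 fs = rec$fs, epoch_length = epoch_length, overlap = overlap,
                 n_input = length(starts), n_retained = length(starts)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d retained) x %d channels x %d samples @ %g Hz\n",
              x$n_input, x$n_retained, dim(x$epochs)[2], dim(x$epochs)[3], x$fs))
  invisible(x)
}

#' Reject epochs with high-amplitude activity
#'
#' Drops every epoch in which any channel sample strictly exceeds the
#' amplitude criterion (`|v| > threshold_uv`); a sample at exactly the
#' threshold is retained. The operation is idempotent.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Rejection threshold in microvolts (default 75).
#' @return An `epoch_set` containing only retained epochs; `n_retained`
#'   records the count (an empty result is allowed and reported).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 75) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (threshold_uv <= 0) abort("`threshold_uv` must be positive.")
  peak <- apply(abs(epochs$epochs), 1, max)
  keep <- peak <= threshold_uv
  out <- epochs
  out$epochs <- epochs$epochs[keep, , , drop = FALSE]
  out$n_retained <- sum(keep)
  if (out$n_retained == 0) {
    warn("All epochs rejected by the amplitude criterion.")
  } else {
    inform(sprintf("Retained %d of %d epochs (|v| <= %g uV).",
                   out$n_retained, length(keep), threshold_uv))
  }
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))

# Tukey (tapered cosine) window with total taper fraction r.
tukey_window <- function(n, r = 0.1) {
  k <- seq(0, n - 1) / (n - 1)
  w <- rep(1, n)
  lo <- k < r / 2
  hi <- k >= 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * k[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * k[hi] / r - 2 / r + 1)))
  w
}

# One-sided windowed periodogram of a single epoch channel.
# Scaled so that the sum over all returned bins equals the window-corrected
# mean square of the signal (Parseval): sum(x^2 w^2) / sum(w^2).
epoch_spectrum <- function(x, fs, window) {
  n <- length(x)
  xw <- (x - mean(x)) * window
  X <- fft(xw)
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2 / (n * sum(window^2))
  mult <- rep(2, half + 1)
  mult[1] <- 1
  if (n %% 2 == 0) mult[half + 1] <- 1
  tibble(freq = (0:half) * fs / n, power = p * mult)
}

#' Band power of an epoch set
#'
#' Per epoch and channel the mean-removed signal is tapered, Fourier
#' transformed, and its one-sided power spectrum summed over the bins with
#' `low <= f < high` for each band; band powers are then averaged across
#' epochs (a Welch-type estimate). Both absolute power (uV^2) and its natural
#' log are returned.
#'
#' The default taper is a 5% cosine (Tukey) window, which keeps an on-bin
#' oscillation's power almost entirely inside its own half-open band; a full
#' Hann window (`"hann"`) is available but spreads one sixth of an on-bin
#' tone's power into the adjacent bin across the band edge.
#'
#' @param epochs An `epoch_set` with at least one retained epoch.
#' @param bands Band definitions from [eeg_bands()].
#' @param window `"tukey05"` (default), a 5%-taper cosine window, or
#'   `"hann"`.
#' @return Tibble with columns `channel`, `band`, `low`, `high`, `power`,
#'   `ln_power`.
#' @export
band_power <- function(epochs, bands = eeg_bands(), window = c("tukey05", "hann")) {
  stopifnot(inherits(epochs, "epoch_set"))
  window <- match.arg(window)
  d <- dim(epochs$epochs)
  if (d[1] < 1) abort("No retained epochs to compute band power from.")
  if (any(bands$low < 0) || any(bands$high > epochs$fs / 2)) {
    abort("Band edges must lie within [0, fs/2).")
  }
  n <- d[3]
  w <- if (window == "hann") hann_window(n) else tukey_window(n, 0.1)
  freqs <- epoch_spectrum(epochs$epochs[1, 1, ], epochs$fs, w)$freq
  bin_sets <- lapply(seq_len(nrow(bands)), function(b) {
    which(freqs >= bands$low[b] & freqs < bands$high[b])
  })
  acc <- matrix(0, d[2], nrow(bands))
  for (e in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      sp <- epoch_spectrum(epochs$epochs[e, ch, ], epochs$fs, w)$power
      acc[ch, ] <- acc[ch, ] + vapply(bin_sets, function(ix) sum(sp[ix]), 0)
    }
  }
  acc <- acc / d[1]
  out <- tidyr::expand_grid(channel = epochs$channel_names, band = bands$band)
  out$low <- bands$low[match(out$band, bands$band)]
  out$high <- bands$high[match(out$band, bands$band)]
  out$power <- as.vector(t(acc))
  out$ln_power <- ifelse(out$power > 0, log(out$power), -Inf)
  out
}

#' Build a feature table from per-subject recordings
#'
#' Runs the full extraction chain (re-reference, 2-s epochs with 50% overlap,
#' +/-75 uV artifact rejection, Hann-window band power) for every subject and
#' condition and assembles one row per subject. Columns are ordered
#' electrode-major, then band, then condition, named
#' `<electrode>_<band>_<condition>_<reference>`. Subjects with zero retained
#' epochs in any recording are excluded with a warning.
#'
#' @param recordings Tibble with columns `sample_id`, `label`, `condition`
#'   and a list-column `recording` of `eeg_recording` objects.
#' @param bands Band definitions from [eeg_bands()].
#' @param reference `"mastoid"` or `"cz"`.
#' @param power `"absolute"` (default; the better-performing variant) or
#'   `"ln"` for natural-log power.
#' @param threshold_uv Artifact-rejection criterion in microvolts.
#' @return A feature table tibble (`value_kind` `"absolute_power"` or
#'   `"ln_power"`).
#' @export
build_feature_table <- function(recordings, bands = eeg_bands(c("delta", "theta", "alpha1", "beta")),
                                reference = c("mastoid", "cz"),
                                power = c("absolute", "ln"),
                                threshold_uv = 75) {
  reference <- match.arg(reference)
  power <- match.arg(power)
  stopifnot(all(c("sample_id", "label", "condition", "recording") %in% names(recordings)))

  rows <- purrr::pmap(recordings, function(sample_id, label, condition, recording, ...) {
    rr <- rereference(recording, reference)
    ep <- segment_epochs(rr)
    ep <- suppressMessages(suppressWarnings(reject_artifacts(ep, threshold_uv)))
    if (ep$n_retained == 0) {
      return(tibble(sample_id = sample_id, label = label,
                    condition = condition, dropped = TRUE))
    }
    bp <- band_power(ep, bands)
    val <- if (power == "absolute") bp$power else bp$ln_power
    tibble(sample_id = sample_id, label = label, condition = condition,
           dropped = FALSE,
           feature = paste(bp$channel, bp$band, condition, reference, sep = "_"),
           value = val)
  })
  long <- dplyr::bind_rows(rows)
  dropped <- unique(long$sample_id[long$dropped])
  if (length(dropped) > 0) {
    warn(paste0("Excluding subject(s) with zero retained epochs: ",
                paste(dropped, collapse = ", ")))
    long <- long[!long$sample_id %in% dropped, ]
  }
  long <- long[!long$dropped, ]

  # electrode-major, band, then condition ordering
  electrodes <- {
    rr <- rereference(recordings$recording[[1]], reference)
    rr$channel_names
  }
  conds <- unique(recordings$condition)
  ord <- as.vector(t(outer(electrodes, bands$band, paste, sep = "_")))
  ord <- as.vector(t(outer(ord, conds, paste, sep = "_")))
  ord <- paste(ord, reference, sep = "_")

  wide <- tidyr::pivot_wider(long[, c("sample_id", "label", "feature", "value")],
                             names_from = "feature", values_from = "value")
  wide <- wide[, c("sample_id", "label", intersect(ord, names(wide)))]
  wide$label <- as_label_factor(wide$label)
  set_value_kind(wide, if (power == "absolute") "absolute_power" else "ln_power")
}
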
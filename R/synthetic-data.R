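#' Standard EEG frequency bands
#'
#' The six classical resting-EEG bands used throughout the package:
#' delta (1-4 Hz), theta (4-8 Hz), alpha1 (8-10.5 Hz), alpha2 (10.5-13 Hz),
#' alpha (8-13 Hz) and beta (13-30 Hz). Band edges are half-open
#' `[low, high)` so a shared edge (e.g. 10.5 Hz) belongs to exactly one band.
#'
#' @param which Optional character vector of band names to keep, in the
#'   requested order.
#' @return A tibble with columns `band`, `low`, `high` (Hz).
#' @examples
#' eeg_bands()
#' eeg_bands(c("delta", "theta", "alpha1", "beta"))
#' @export
eeg_bands <- function(which = NULL) {
  bands <- tibble(
    band = c("delta", "theta", "alpha1", "alpha2", "alpha", "beta"),
    low  = c(1, 4, 8, 10.5, 8, 13),
    high = c(4, 8, 10.5, 13, 13, 30)
  )
  if (is.null(which)) return(bands)
  missing <- setdiff(which, bands$band)
  if (length(missing) > 0) {
    abort(paste0("Unknown band(s): ", paste(missing, collapse = ", ")))
  }
  bands[match(which, bands$band), ]
}

#' The 28-electrode recording montage
#'
#' Scalp sites of the 10-10 cap used for feature extraction. The mastoid
#' reference channels TP9/TP10 are not part of the analysis montage; they are
#' present in raw recordings only.
#'
#' @return Character vector of 28 electrode names.
#' @export
montage_28 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz", "Oz",
    "Fc1", "Fc2", "Cp1", "Cp2", "Fc5", "Fc6", "Cp5", "Cp6")
}

#' Configuration for the synthetic EEG study generator
#'
#' Describes the statistical structure of the emulated study: 53 MDD patients
#' and 43 healthy volunteers, 28 scalp electrodes, and band-power features for
#' a chosen set of frequency bands and recording conditions. Band power is
#' modeled log-normally (power is positive and right-skewed); the class
#' difference is a standardized mean shift (Cohen's d) applied on the log
#' scale to the `informative_features` only, and inter-feature correlation
#' follows a single-factor model with loading `sqrt(noise_corr)`.
#'
#' The default band set (delta, theta, alpha1, beta) with one condition and
#' 28 electrodes yields the 112-feature "all bands" design; per-band designs
#' restrict `bands` to a single row.
#'
#' @param n_mdd,n_hv Samples per class (default 53 / 43).
#' @param electrodes Electrode names (default [montage_28()]).
#' @param bands Tibble of band definitions as from [eeg_bands()].
#' @param conditions Recording condition(s) to generate columns for,
#'   subset of `c("EO", "EC")`.
#' @param reference Reference scheme label used in feature names
#'   (`"mastoid"` or `"cz"`).
#' @param informative_features Integer indices (into the generated feature
#'   columns) that carry the class effect.
#' @param effect_size Standardized mean difference (Cohen's d, log scale)
#'   between classes on informative features; must be >= 0.
#' @param noise_corr Inter-feature correlation in `[0, 1)`.
#' @param fs Sampling rate in Hz for generated raw recordings.
#' @param duration Recording duration in seconds.
#' @param noise_sd White-noise standard deviation in microvolts for raw
#'   recordings.
#' @param alpha_attenuation Multiplier applied to alpha-band amplitude in the
#'   eyes-open condition (alpha desynchronizes when the eyes open).
#' @param artifact_rate Number of injected high-amplitude artifact pulses per
#'   generated recording (0 = artifact-free by construction).
#' @param seed Integer seed; equal seeds give bitwise-identical output.
#' @return A `synth_config` list.
#' @examples
#' cfg <- synth_config(seed = 1)
#' tab <- generate_feature_table(cfg)
#' dim(tab)
#' @export
synth_config <- function(n_mdd = 53, n_hv = 43,
                         electrodes = montage_28(),
                         bands = eeg_bands(c("delta", "theta", "alpha1", "beta")),
                         conditions = "EC",
                         reference = c("mastoid", "cz"),
                         informative_features = 1:12,
                         effect_size = 2.0,
                         noise_corr = 0.2,
                         fs = 500, duration = 180,
                         noise_sd = 2,
                         alpha_attenuation = 0.5,
                         artifact_rate = 0,
                         seed = 1L) {
  reference <- match.arg(reference)
  if (n_mdd < 2 || n_hv < 2) abort("Each class needs at least 2 samples.")
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (noise_corr < 0 || noise_corr >= 1) abort("`noise_corr` must be in [0, 1).")
  if (!all(conditions %in% c("EO", "EC"))) abort("`conditions` must be in {EO, EC}.")
  if (any(bands$low <= 0) || any(bands$high <= bands$low)) {
    abort("Bands need 0 < low < high.")
  }
  p <- length(electrodes) * nrow(bands) * length(conditions)
  if (length(informative_features) > 0 &&
      (min(informative_features) < 1 || max(informative_features) > p)) {
    abort(paste0("`informative_features` must index into 1..", p, "."))
  }
  structure(list(
    n_mdd = n_mdd, n_hv = n_hv, electrodes = electrodes, bands = bands,
    conditions = conditions, reference = reference,
    informative_features = as.integer(informative_features),
    effect_size = effect_size, noise_corr = noise_corr,
    fs = fs, duration = duration, noise_sd = noise_sd,
    alpha_attenuation = alpha_attenuation, artifact_rate = artifact_rate,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Feature names in electrode-major order: electrode, then band, then condition.
synth_feature_names <- function(config) {
  grid <- expand.grid(condition = config$conditions,
                      band = config$bands$band,
                      electrode = config$electrodes,
                      stringsAsFactors = FALSE)
  paste(grid$electrode, grid$band, grid$condition, config$reference, sep = "_")
}

# Typical log-power baseline per band: low frequencies carry more power.
band_log_baseline <- function(band) {
  base <- c(delta = 3.0, theta = 2.3, alpha1 = 2.5, alpha2 = 2.2,
            alpha = 2.7, beta = 1.2)
  unname(base[band])
}

#' Generate a synthetic band-power feature table
#'
#' Draws one row per subject from a class-conditional log-normal model.
#' On the log scale every feature is `baseline + sqrt(rho) * g + sqrt(1-rho) * e`
#' with a per-subject common factor `g` (inter-feature correlation `rho`) and
#' unit total variance; informative features additionally receive +d/2 (MDD)
#' and -d/2 (HV). Absolute power is the exponential of this, hence strictly
#' positive.
#'
#' @param config A [synth_config()].
#' @return A feature table: tibble with `sample_id`, `label` and one column
#'   per electrode x band x condition feature, `value_kind` attribute
#'   `"absolute_power"`.
#' @examples
#' tab <- generate_feature_table(synth_config(seed = 42))
#' length(feature_names(tab))  # 28 electrodes x 4 bands = 112
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  feats <- synth_feature_names(config)
  p <- length(feats)
  n <- config$n_mdd + config$n_hv
  labels <- as_label_factor(rep(c("MDD", "HV"), c(config$n_mdd, config$n_hv)))

  band_of <- rep(rep(config$bands$band, each = length(config$conditions)),
                 times = length(config$electrodes))
  mu <- band_log_baseline(band_of)

  shift <- numeric(p)
  shift[config$informative_features] <- config$effect_size / 2

  rho <- config$noise_corr
  withr::with_seed(config$seed, {
    g <- rnorm(n)
    e <- matrix(rnorm(n * p), n, p)
    z <- sqrt(rho) * g + sqrt(1 - rho) * e
    z <- sweep(z, 2, mu, `+`)
    sgn <- ifelse(labels == "MDD", 1, -1)
    z <- z + outer(sgn, shift)
    values <- exp(z)
  })
  colnames(values) <- feats

  out <- bind_feature_table(
    sample_id = sprintf("%s_%02d", labels,
                        c(seq_len(config$n_mdd), seq_len(config$n_hv))),
    labels = labels, values = values
  )
  set_value_kind(out, "absolute_power")
}

bind_feature_table <- function(sample_id, labels, values) {
  out <- as_tibble(as.data.frame(values, optional = TRUE))
  out <- dplyr::bind_cols(tibble(sample_id = sample_id,
                                 label = as_label_factor(labels)), out)
  out
}

#' Generate a synthetic multichannel resting-EEG recording
#'
#' Builds a raw-like signal for one subject as a sum of band-limited
#' sinusoids (randomized phase and per-channel amplitude jitter) plus white
#' noise. Alpha amplitude is attenuated in the eyes-open condition and mildly
#' elevated in MDD (scaled by the configured effect size), so downstream band
#' power reproduces the qualitative contrasts the analysis expects. The clean
#' signal is bounded within +/-70 microvolts by construction; optional
#' artifacts are 200-ms square pulses of +/-150 microvolts, unambiguously
#' violating a +/-75 microvolt rejection criterion.
#'
#' @param config A [synth_config()].
#' @param class_label `"MDD"` or `"HV"`.
#' @param condition `"EO"` or `"EC"`.
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return An `eeg_recording`: list with `signal` (channels x timepoints
#'   matrix, microvolts), `channel_names`, `fs`, `condition`.
#' @export
generate_recording <- function(config, class_label = "MDD",
                               condition = "EC", seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  class_label <- match.arg(class_label, .classes)
  condition <- match.arg(condition, c("EO", "EC"))
  if (config$duration < 2) abort("Recording must be at least one 2-s epoch long.")

  channels <- unique(c(config$electrodes, "TP9", "TP10", "Cz"))
  n_ch <- length(channels)
  n_t <- round(config$duration * config$fs)
  t <- seq(0, by = 1 / config$fs, length.out = n_t)

  # Per-band carrier amplitude in microvolts; alpha dominates at rest.
  amp <- c(delta = 8, theta = 6, alpha1 = 10, alpha2 = 9, alpha = 10, beta = 3)
  is_alpha <- function(b) b %in% c("alpha", "alpha1", "alpha2")

  seed <- seed %||% config$seed
  withr::with_seed(seed, {
    signal <- matrix(0, n_ch, n_t)
    for (bi in seq_len(nrow(config$bands))) {
      b <- config$bands$band[bi]
      f <- (config$bands$low[bi] + config$bands$high[bi]) / 2
      a <- if (b %in% names(amp)) amp[[b]] else 5
      if (is_alpha(b)) {
        if (condition == "EO") a <- a * config$alpha_attenuation
        if (class_label == "MDD") a <- a * (1 + 0.1 * config$effect_size)
      }
      phase <- runif(n_ch, 0, 2 * pi)
      jitter <- exp(rnorm(n_ch, 0, 0.1))
      carrier <- outer(rep(1, n_ch), 2 * pi * f * t)
      signal <- signal + (a * jitter) * sin(carrier + phase)
    }
    if (config$noise_sd > 0) {
      signal <- signal + matrix(rnorm(n_ch * n_t, 0, config$noise_sd), n_ch, n_t)
    }
    # artifact-free guarantee for the clean signal
    signal <- pmin(pmax(signal, -70), 70)
    if (config$artifact_rate > 0) {
      pulse_len <- round(0.2 * config$fs)
      for (k in seq_len(config$artifact_rate)) {
        ch <- sample.int(n_ch, 1)
        onset <- sample.int(n_t - pulse_len, 1)
        sgn <- sample(c(-1, 1), 1)
        signal[ch, onset:(onset + pulse_len - 1)] <- sgn * 150
      }
    }
  })
  rownames(signal) <- channels
  structure(list(signal = signal, channel_names = channels,
                 fs = config$fs, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, x$condition))
  invisible(x)
}

#' Worked fixtures for the genetic-algorithm operators and metrics
#'
#' Small named constants used in documentation and tests: the one-point
#' crossover example (parents `111010011` / `010111001`, cut after locus 5,
#' offspring `111011001` / `010110011`), the bit-flip mutation example
#' (`111010011` with locus 3 flipped to `110010011`), a fixed 6-sample x
#' 4-feature toy table, and sensitivity/specificity pairs with their
#' likelihood ratios.
#'
#' The toy table rows are (label: f1, f2, f3, f4):
#' MDD: (0.9, 0.8, 0.1, 0.5), (0.8, 0.9, 0.2, 0.4), (0.7, 0.7, 0.3, 0.6);
#' HV: (0.2, 0.1, 0.9, 0.5), (0.1, 0.3, 0.8, 0.4), (0.3, 0.2, 0.7, 0.6).
#'
#' @return Named list of fixtures.
#' @export
worked_fixtures <- function() {
  toy <- tibble(
    sample_id = c("MDD_01", "MDD_02", "MDD_03", "HV_01", "HV_02", "HV_03"),
    label = as_label_factor(c("MDD", "MDD", "MDD", "HV", "HV", "HV")),
    f1 = c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3),
    f2 = c(0.8, 0.9, 0.7, 0.1, 0.3, 0.2),
    f3 = c(0.1, 0.2, 0.3, 0.9, 0.8, 0.7),
    f4 = c(0.5, 0.4, 0.6, 0.5, 0.4, 0.6)
  )
  list(
    crossover_parents = c("111010011", "010111001"),
    crossover_point = 5L,
    crossover_offspring = c("111011001", "010110011"),
    mutation_input = "111010011",
    mutation_locus = 3L,
    mutation_output = "110010011",
    toy_table = toy,
    metric_pairs = tibble(
      sensitivity = c(89, 100), specificity = c(89, 77),
      lr_pos = c(8.09, 4.35), lr_neg = c(0.12, 0)
    )
  )
}

# string <-> bit-vector helpers shared with the GA module
bits_from_string <- function(s) as.integer(strsplit(s, "")[[1]])
bits_to_string <- function(b) paste(b, collapse = "")
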
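#' ERP component specification
#'
#' A Gaussian-bump parameterization of one evoked component: a kernel of
#' fixed peak latency, FWHM width and base amplitude, projected to the scalp
#' through a smooth topography. Polarity is tied to the component name
#' (P* positive, N* negative).
#'
#' @param name one of "P1", "N1", "P2", "N2", "P3".
#' @param peak_latency_ms kernel peak latency relative to stimulus onset.
#' @param width_ms full width at half maximum of the Gaussian bump.
#' @param base_amplitude_uV peak amplitude (positive number) for nontarget
#'   events, in microvolts.
#' @param topography named per-channel weight vector in `[-1, 1]` with unit
#'   maximum (see [scalp_topography()]).
#' @return a `component_spec` list.
#' @export
component_spec <- function(name, peak_latency_ms, width_ms,
                           base_amplitude_uV, topography) {
  name <- match.arg(name, c("P1", "N1", "P2", "N2", "P3"))
  stopifnot_positive(width_ms, "width_ms")
  stopifnot_positive(base_amplitude_uV, "base_amplitude_uV")
  if (max(abs(topography)) > 1 + 1e-9) {
    abort("topography weights must lie in [-1, 1]")
  }
  structure(
    list(name = name,
         polarity = if (startsWith(name, "P")) 1 else -1,
         peak_latency_ms = peak_latency_ms, width_ms = width_ms,
         base_amplitude_uV = base_amplitude_uV, topography = topography),
    class = "component_spec"
  )
}

#' Default five-component ERP family
#'
#' P1, N1, P2, N2 and P3 with peak latencies at the centers of the standard
#' analysis windows (115, 190, 250, 320, 395 ms), widths equal to the
#' window widths (70, 80, 80, 80, 90 ms FWHM), parieto-occipital
#' topographies (peaks PO7/PO8) for P1/N1/N2 and midline-central
#' topographies for P2 (Fz/Cz) and P3 (Cz/Pz). Base amplitudes of
#' 2, 3, 2.5, 2 and 4 microvolts are free generator parameters chosen as
#' realistic scalp values.
#'
#' @param channels montage labels the topographies are evaluated on.
#' @return named list of five [component_spec()] objects.
#' @export
default_components <- function(channels = montage_labels()) {
  post <- scalp_topography(c("PO7", "PO8"), channels)
  midf <- scalp_topography(c("Fz", "Cz"), channels)
  midp <- scalp_topography(c("Cz", "Pz"), channels)
  list(
    P1 = component_spec("P1", 115, 70, 2.0, post),
    N1 = component_spec("N1", 190, 80, 3.0, post),
    P2 = component_spec("P2", 250, 80, 2.5, midf),
    N2 = component_spec("N2", 320, 80, 2.0, post),
    P3 = component_spec("P3", 395, 90, 4.0, midp)
  )
}

#' Attention-modulation presets
#'
#' Per-component multiplicative gains applied to target events (nontarget
#' gain is fixed at 1). The presets encode the qualitative modulation
#' pattern of the four experimental subconditions: under overt attention
#' all five components are enhanced for targets; under covert attention
#' only N2 and P3 are modulated with the Matrix, while the Hex-o-Spell
#' additionally modulates N1 and P2 and reverses the direction of the N2
#' modulation (gain below 1).
#'
#' @param attention "overt" or "covert".
#' @param speller "matrix" or "hex".
#' @return a `modulation_profile` list with fields `attention`, `speller`,
#'   `gains` (named numeric over components).
#' @export
#' @examples
#' modulation_profile("covert", "hex")$gains
modulation_profile <- function(attention = c("overt", "covert"),
                               speller = c("matrix", "hex")) {
  attention <- match.arg(attention)
  speller <- match.arg(speller)
  gains <- if (attention == "overt") {
    c(P1 = 1.6, N1 = 2.0, P2 = 1.8, N2 = 1.6, P3 = 2.0)
  } else if (speller == "matrix") {
    c(P1 = 1.0, N1 = 1.0, P2 = 1.0, N2 = 1.4, P3 = 1.7)
  } else {
    c(P1 = 1.0, N1 = 1.3, P2 = 1.5, N2 = 0.7, P3 = 1.7)
  }
  structure(list(attention = attention, speller = speller, gains = gains),
            class = "modulation_profile")
}

#' Custom modulation profile
#'
#' @param gains named numeric vector of per-component target gains (>= 0);
#'   missing components default to 1.
#' @param attention,speller metadata labels.
#' @return a `modulation_profile`.
#' @export
custom_modulation <- function(gains, attention = "custom",
                              speller = "custom") {
  if (any(gains < 0)) abort("gains must be >= 0")
  base <- c(P1 = 1, N1 = 1, P2 = 1, N2 = 1, P3 = 1)
  base[names(gains)] <- gains
  structure(list(attention = attention, speller = speller, gains = base),
            class = "modulation_profile")
}

#' Background-noise model
#'
#' Colored (1/f^alpha) noise, spatially smoothed across neighbouring
#' channels and scaled to a per-channel target rms.
#'
#' @param rms_uV per-channel root-mean-square amplitude in microvolts.
#' @param spectral_exponent alpha of the 1/f^alpha spectrum (>= 0; 0 gives
#'   white noise).
#' @param channel_mixing Gaussian spatial-smoothing width in schematic
#'   montage grid units (0 disables mixing).
#' @param seed optional integer seed.
#' @return a `noise_model` list.
#' @export
noise_model <- function(rms_uV = 6, spectral_exponent = 1,
                        channel_mixing = 1, seed = NULL) {
  if (rms_uV < 0) abort("`rms_uV` must be >= 0")
  if (spectral_exponent < 0) abort("`spectral_exponent` must be >= 0")
  structure(list(rms_uV = rms_uV, spectral_exponent = spectral_exponent,
                 channel_mixing = channel_mixing, seed = seed),
            class = "noise_model")
}

#' Single-channel component kernel
#'
#' The time-domain kernel of one component at a given sampling rate:
#' `polarity * amplitude * exp(-(t - latency)^2 / (2 sigma^2))` with
#' `sigma = width / 2.355` (FWHM convention), truncated at +/- 3 sigma.
#'
#' @param spec a [component_spec()].
#' @param fs sampling rate in Hz.
#' @return list with `offsets` (integer sample offsets relative to stimulus
#'   onset) and `values` (kernel in microvolts).
#' @export
component_waveform <- function(spec, fs) {
  stopifnot_positive(fs, "fs")
  sigma_ms <- spec$width_ms / 2.355
  lo <- floor((spec$peak_latency_ms - 3 * sigma_ms) * fs / 1000)
  hi <- ceiling((spec$peak_latency_ms + 3 * sigma_ms) * fs / 1000)
  offsets <- lo:hi
  t_ms <- offsets * 1000 / fs
  values <- spec$polarity * spec$base_amplitude_uV *
    exp(-(t_ms - spec$peak_latency_ms)^2 / (2 * sigma_ms^2))
  list(offsets = offsets, values = values)
}

#' Generate colored, spatially mixed background noise
#'
#' Per channel, white Gaussian noise is spectrally shaped to 1/f^alpha by
#' scaling its discrete Fourier coefficients (DC removed), then channels
#' are mixed with Gaussian spatial weights over the schematic montage
#' layout, and finally each channel is rescaled to the exact target rms.
#'
#' @param n_channels,n_samples output dimensions.
#' @param model a [noise_model()].
#' @param channels montage labels (for the spatial mixing distances).
#' @param seed optional seed overriding `model$seed`.
#' @return `n_channels x n_samples` matrix in microvolts.
#' @export
generate_noise <- function(n_channels, n_samples, model = noise_model(),
                           channels = montage_labels()[seq_len(n_channels)],
                           seed = NULL) {
  stopifnot_positive(n_channels, "n_channels")
  stopifnot_positive(n_samples, "n_samples")
  if (model$rms_uV == 0) {
    return(matrix(0, n_channels, n_samples,
                  dimnames = list(channels, NULL)))
  }
  seed <- seed %||% model$seed
  x <- with_seed_or_stream(seed, {
    w <- matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
    if (model$spectral_exponent > 0) {
      k <- seq_len(n_samples) - 1L
      k <- pmin(k, n_samples - k)           # |frequency| index
      shape <- ifelse(k == 0, 0, k^(-model$spectral_exponent / 2))
      w <- t(apply(w, 1, function(row) {
        Re(fft(fft(row) * shape, inverse = TRUE)) / n_samples
      }))
    }
    w
  })
  if (model$channel_mixing > 0 && n_channels > 1) {
    d <- montage_distance(channels)
    m <- exp(-d^2 / (2 * model$channel_mixing^2))
    x <- m %*% x
  }
  rms <- sqrt(rowMeans(x^2))
  x <- x * (model$rms_uV / rms)
  dimnames(x) <- list(channels, NULL)
  x
}

#' Synthesize a continuous recording for one trial
#'
#' Linearly superposes, at every intensification onset of the schedule, the
#' kernels of all components projected through their topographies; target
#' events are additionally scaled by the modulation profile's per-component
#' gains. Colored background noise is added last. Because the SOA (166 ms)
#' is much shorter than the component kernels, responses of subsequent
#' intensifications overlap by construction.
#'
#' @param schedule a [generate_trial_schedule()] result.
#' @param components list of [component_spec()]s (default
#'   [default_components()]).
#' @param modulation a [modulation_profile()].
#' @param noise a [noise_model()].
#' @param fs sampling rate in Hz (default 1000).
#' @param seed optional integer seed for the noise stream.
#' @param pad_pre_ms,pad_post_ms silent padding before the first and after
#'   the last onset.
#' @return an `eeg_recording` list: `data` (channels x samples matrix in
#'   microvolts), `fs`, `channels`, `events` (tibble with `sample` plus the
#'   schedule columns), `pad_pre_ms`.
#' @export
synthesize_recording <- function(schedule,
                                 components = default_components(),
                                 modulation = modulation_profile("overt",
                                                                 "matrix"),
                                 noise = noise_model(), fs = 1000,
                                 seed = NULL, pad_pre_ms = 500,
                                 pad_post_ms = 1000) {
  if (nrow(schedule) == 0) abort("schedule has no events")
  channels <- names(components[[1]]$topography)
  n_ch <- length(channels)
  onset_samples <- round(schedule$onset_ms * fs / 1000) +
    round(pad_pre_ms * fs / 1000) + 1L
  n_samp <- max(onset_samples) + round(pad_post_ms * fs / 1000)
  data <- matrix(0, n_ch, n_samp, dimnames = list(channels, NULL))
  for (comp in components) {
    kern <- component_waveform(comp, fs)
    gain <- modulation$gains[[comp$name]]
    topo <- comp$topography[channels]
    amp <- ifelse(schedule$is_target, gain, 1)
    for (e in seq_len(nrow(schedule))) {
      idx <- onset_samples[e] + kern$offsets
      keep <- idx >= 1L & idx <= n_samp
      if (!any(keep)) next
      data[, idx[keep]] <- data[, idx[keep]] +
        outer(topo, kern$values[keep]) * amp[e]
    }
  }
  if (noise$rms_uV > 0) {
    data <- data + generate_noise(n_ch, n_samp, noise, channels, seed = seed)
  }
  events <- dplyr::mutate(as_tibble(as.data.frame(schedule)),
                          sample = onset_samples, .before = 1)
  structure(
    list(data = data, fs = fs, channels = channels, events = events,
         pad_pre_ms = pad_pre_ms),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}
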
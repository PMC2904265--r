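#' Downsample a recording by an integer factor
#'
#' Anti-alias FIR low-pass filtering (zero-phase, via forward-backward
#' filtering) followed by decimation. Event sample indices are rescaled to
#' the new rate. The target rate must divide the original rate.
#'
#' @param recording an `eeg_recording`.
#' @param target_fs new sampling rate in Hz (integer divisor of
#'   `recording$fs`).
#' @param filter_order FIR order of the anti-alias filter.
#' @return the resampled `eeg_recording`.
#' @export
resample_recording <- function(recording, target_fs, filter_order = 64) {
  q <- recording$fs / target_fs
  if (abs(q - round(q)) > 1e-9 || q < 1) {
    abort(sprintf("target_fs (%g) must divide fs (%g) by an integer factor",
                  target_fs, recording$fs))
  }
  q <- as.integer(round(q))
  if (q == 1L) return(recording)
  b <- signal::fir1(filter_order, 0.8 / q)
  filt <- t(apply(recording$data, 1, function(x) signal::filtfilt(b, x)))
  keep <- seq(1L, ncol(recording$data), by = q)
  recording$data <- filt[, keep, drop = FALSE]
  recording$fs <- target_fs
  recording$events$sample <- (recording$events$sample - 1L) %/% q + 1L
  recording
}

#' Epoching window
#'
#' Stimulus-locked analysis window from -170 ms (about one SOA before
#' onset) to +670 ms (about four SOAs after), with the 170 ms pre-stimulus
#' interval as baseline.
#'
#' @param start_ms,end_ms window bounds relative to stimulus onset.
#' @param baseline length-2 vector, the baseline interval (within
#'   `[start_ms, 0]`).
#' @return an `epoch_window` list.
#' @export
epoch_window <- function(start_ms = -170, end_ms = 670,
                         baseline = c(-170, 0)) {
  if (!(start_ms < 0 && end_ms > 0)) abort("window must straddle 0")
  if (baseline[1] < start_ms || baseline[2] > 0) {
    abort("baseline must lie within [start_ms, 0]")
  }
  structure(list(start_ms = start_ms, end_ms = end_ms, baseline = baseline),
            class = "epoch_window")
}

#' Extract stimulus-locked, baseline-corrected epochs
#'
#' Cuts one epoch per event of the recording, labels it target/nontarget
#' from the event's ground-truth flag, and subtracts the per-channel mean
#' of the baseline interval. Events too close to the recording edges are
#' flagged as excluded (`reason = "boundary"`) and carry no data.
#'
#' @param recording an `eeg_recording`.
#' @param window an [epoch_window()].
#' @return an `epoch_set`: `data` (epochs x channels x time array, in
#'   microvolts), `times_ms`, `channels`, `fs`, and `info` — a tibble with
#'   one row per epoch (`epoch`, `event_index`, `label`, `level`, `phase`,
#'   `sequence`, `element_id`, `kept`, `reason`).
#' @export
extract_epochs <- function(recording, window = epoch_window()) {
  ev <- recording$events
  if (is.null(ev) || nrow(ev) == 0) abort("recording has no events")
  fs <- recording$fs
  r0 <- round(window$start_ms * fs / 1000)
  r1 <- round(window$end_ms * fs / 1000)
  times_ms <- (r0:r1) * 1000 / fs
  n_t <- length(times_ms)
  n_samp <- ncol(recording$data)
  n_ch <- nrow(recording$data)
  in_range <- ev$sample + r0 >= 1L & ev$sample + r1 <= n_samp
  data <- array(NA_real_, c(nrow(ev), n_ch, n_t),
                dimnames = list(NULL, recording$channels, NULL))
  bl <- times_ms >= window$baseline[1] & times_ms <= window$baseline[2]
  for (e in which(in_range)) {
    seg <- recording$data[, ev$sample[e] + (r0:r1), drop = FALSE]
    seg <- seg - rowMeans(seg[, bl, drop = FALSE])
    data[e, , ] <- seg
  }
  info <- tibble(
    epoch = seq_len(nrow(ev)),
    event_index = ev$index,
    label = ifelse(ev$is_target, "target", "nontarget"),
    level = ev$level,
    phase = ev$phase,
    sequence = ev$sequence,
    element_id = ev$element_id,
    kept = in_range,
    reason = ifelse(in_range, NA_character_, "boundary")
  )
  structure(
    list(data = data, times_ms = times_ms, channels = recording$channels,
         fs = fs, window = window, info = info),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs (%d kept) x %d ch x %d samples @ %g Hz\n",
    nrow(x$info), sum(x$info$kept), length(x$channels),
    length(x$times_ms), x$fs))
  invisible(x)
}

#' Combine several epoch sets
#'
#' @param sets list of `epoch_set`s sharing channels, times and rate.
#' @return one `epoch_set`; `info` gains a `set` column identifying the
#'   source.
#' @export
bind_epochs <- function(sets) {
  stopifnot(length(sets) >= 1)
  t0 <- sets[[1]]$times_ms
  for (s in sets) {
    if (!isTRUE(all.equal(s$times_ms, t0)) ||
        !identical(s$channels, sets[[1]]$channels)) {
      abort("epoch sets differ in channels or time axis")
    }
  }
  data <- do.call(abind_epochs_first, lapply(sets, `[[`, "data"))
  info <- dplyr::bind_rows(lapply(seq_along(sets), function(i) {
    dplyr::mutate(sets[[i]]$info, set = i)
  }))
  info$epoch <- seq_len(nrow(info))
  structure(list(data = data, times_ms = t0,
                 channels = sets[[1]]$channels, fs = sets[[1]]$fs,
                 window = sets[[1]]$window, info = info),
            class = "epoch_set")
}

# rbind 3D arrays along the first margin
abind_epochs_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 0)),
                           d[2], d[3]),
               dimnames = list(NULL, dimnames(arrs[[1]])[[2]], NULL))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Subset an epoch set
#'
#' @param epochs an `epoch_set`.
#' @param which logical or integer index over epochs.
#' @return the subsetted `epoch_set`.
#' @export
subset_epochs <- function(epochs, which) {
  epochs$data <- epochs$data[which, , , drop = FALSE]
  epochs$info <- epochs$info[which, ]
  epochs$info$epoch <- seq_len(nrow(epochs$info))
  epochs
}

#' Target-epoch contamination filter
#'
#' A target event is kept only if the nearest preceding and nearest
#' following target intensifications (if any) are at least 3 stream
#' positions away (about 500 ms at a 166 ms SOA), so that no other target
#' response overlaps the epoch. Stream edges count as satisfied. The filter
#' is a pure function of the event stream.
#'
#' @param schedule a `trial_schedule` (or any tibble with `index` and
#'   `is_target`).
#' @param min_gap minimum stream-position difference (default 3).
#' @return integer vector of kept target event `index` values.
#' @export
filter_target_epochs <- function(schedule, min_gap = 3L) {
  pos <- schedule$index[schedule$is_target]
  if (length(pos) == 0) return(integer(0))
  gap_prev <- c(Inf, diff(pos))
  gap_next <- c(diff(pos), Inf)
  pos[gap_prev >= min_gap & gap_next >= min_gap]
}

#' Nontarget-epoch contamination filter
#'
#' A nontarget event at stream position i is kept only if no target
#' occupies positions i-3 ... i-1 (three preceding) or i+1 ... i+2 (two
#' following). Stream edges truncate the checked ranges.
#'
#' @param schedule a `trial_schedule`.
#' @param n_before,n_after checked ranges before/after (defaults 3 and 2).
#' @return integer vector of kept nontarget event `index` values.
#' @export
filter_nontarget_epochs <- function(schedule, n_before = 3L, n_after = 2L) {
  ord <- order(schedule$index)
  idx <- schedule$index[ord]
  tgt <- schedule$is_target[ord]
  n <- length(idx)
  is_t <- as.integer(tgt)
  # cumulative targets; targets in (i-n_before .. i-1] and [i+1 .. i+n_after]
  cs <- cumsum(is_t)
  csp <- c(0L, cs)  # csp[i] = targets among first i-1 events
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (tgt[i]) next
    lo <- max(1L, i - n_before)
    hi <- min(n, i + n_after)
    before <- cs[i - 1L + 1L] - csp[lo]      # targets in [lo, i-1]
    after <- cs[hi] - cs[i]                  # targets in [i+1, hi]
    keep[i] <- (before + after) == 0L
  }
  idx[keep]
}

#' Apply the contamination filters to an epoch set
#'
#' Marks epochs excluded by [filter_target_epochs()] /
#' [filter_nontarget_epochs()] as not kept, with reasons
#' `"target_proximity"` and `"nontarget_contamination"`. Boundary
#' exclusions from epoching are preserved. The filters operate on the event
#' stream only, never on signal content.
#'
#' @param epochs an `epoch_set`.
#' @param schedule the trial's schedule (must cover the epochs'
#'   `event_index`).
#' @return the `epoch_set` with updated `kept`/`reason`.
#' @export
apply_epoch_filters <- function(epochs, schedule) {
  kt <- filter_target_epochs(schedule)
  kn <- filter_nontarget_epochs(schedule)
  info <- epochs$info
  drop_t <- info$label == "target" & !(info$event_index %in% kt)
  drop_n <- info$label == "nontarget" & !(info$event_index %in% kn)
  info$reason[info$kept & drop_t] <- "target_proximity"
  info$reason[info$kept & drop_n] <- "nontarget_contamination"
  info$kept <- info$kept & !drop_t & !drop_n
  epochs$info <- info
  epochs
}
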
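#' Write / read a recording bundle
#'
#' A recording is serialized to a plain-text directory bundle:
#' `header.json` (rate, channel labels, padding), `samples.tsv` (time by
#' channel, microvolts, full precision) and `events.tsv` (the event
#' sidecar). The round trip preserves events exactly and samples to within
#' text-formatting precision (far below 0.1 microvolt).
#'
#' @param recording an `eeg_recording`.
#' @param dir directory to create/populate.
#' @return `read_recording()` returns the `eeg_recording`.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- list(fs = recording$fs, channels = recording$channels,
                 pad_pre_ms = recording$pad_pre_ms,
                 n_samples = ncol(recording$data))
  jsonlite::write_json(header, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  samples <- as.data.frame(t(recording$data))
  names(samples) <- recording$channels
  utils::write.table(samples, file.path(dir, "samples.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(as.data.frame(recording$events),
                     file.path(dir, "events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  hpath <- file.path(dir, "header.json")
  epath <- file.path(dir, "events.tsv")
  spath <- file.path(dir, "samples.tsv")
  for (p in c(hpath, epath, spath)) {
    if (!file.exists(p)) abort(sprintf("missing bundle file: %s", p))
  }
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  samples <- utils::read.delim(spath, check.names = FALSE)
  if (!identical(names(samples), header$channels)) {
    abort("channel labels in samples.tsv do not match header.json")
  }
  events <- as_tibble(utils::read.delim(epath, stringsAsFactors = FALSE))
  if (nrow(events) == 0) abort("events sidecar is empty")
  if (any(events$sample < 1 | events$sample > nrow(samples))) {
    abort("event sample indices outside the recording")
  }
  structure(
    list(data = t(as.matrix(samples)), fs = header$fs,
         channels = header$channels, events = events,
         pad_pre_ms = header$pad_pre_ms),
    class = "eeg_recording")
}

#' Write / read an epoch-set bundle
#'
#' Plain-text serialization of an `epoch_set`: `meta.json` (time axis,
#' channels, rate, window), `info.tsv` (per-epoch labels and kept flags —
#' the kept/excluded report) and `data.tsv` (one row per epoch x channel,
#' one column per time sample; excluded epochs are omitted).
#'
#' @param epochs an `epoch_set`.
#' @param dir directory to create/populate.
#' @return `read_epochs()` returns the `epoch_set` (excluded epochs come
#'   back with `NA` data, as written).
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(times_ms = epochs$times_ms, channels = epochs$channels,
               fs = epochs$fs,
               window = unclass(epochs$window))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA)
  utils::write.table(as.data.frame(epochs$info), file.path(dir, "info.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  rows <- which(!apply(is.na(epochs$data[, 1, , drop = FALSE]), 1, any))
  n_ch <- length(epochs$channels)
  flat <- do.call(rbind, lapply(rows, function(e) epochs$data[e, , ]))
  df <- data.frame(epoch = rep(rows, each = n_ch),
                   channel = rep(epochs$channels, length(rows)), flat,
                   check.names = FALSE)
  names(df) <- c("epoch", "channel",
                 paste0("t", seq_along(epochs$times_ms)))
  utils::write.table(df, file.path(dir, "data.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  info <- as_tibble(utils::read.delim(file.path(dir, "info.tsv"),
                                      stringsAsFactors = FALSE))
  flat <- utils::read.delim(file.path(dir, "data.tsv"),
                            check.names = FALSE)
  n_t <- length(meta$times_ms)
  data <- array(NA_real_, c(nrow(info), length(meta$channels), n_t),
                dimnames = list(NULL, meta$channels, NULL))
  for (e in unique(flat$epoch)) {
    block <- flat[flat$epoch == e, ]
    m <- as.matrix(block[match(meta$channels, block$channel),
                         paste0("t", seq_len(n_t))])
    data[e, , ] <- m
  }
  window <- epoch_window(meta$window$start_ms, meta$window$end_ms,
                         meta$window$baseline)
  structure(list(data = data, times_ms = meta$times_ms,
                 channels = meta$channels, fs = meta$fs, window = window,
                 info = info),
            class = "epoch_set")
}

#' Write / read a fitted shrinkage-LDA model as JSON
#'
#' Serializes weights, bias, shrinkage intensity and the feature
#' specification (channel subset and temporal windows).
#'
#' @param model a `shrinkage_lda`.
#' @param spec optional [feature_spec()] stored alongside.
#' @param path JSON file path.
#' @return `read_model()` returns a list `model` (a `shrinkage_lda`) and
#'   `spec` (a `feature_spec` or `NULL`).
#' @export
write_model <- function(model, path, spec = NULL) {
  obj <- list(weights = model$weights, bias = model$bias,
              gamma = model$gamma, gamma_mode = model$gamma_mode,
              nu = model$nu, n = model$n, d = model$d,
              mu0 = as.numeric(model$means$mu0),
              mu1 = as.numeric(model$means$mu1))
  if (!is.null(spec)) {
    obj$spec <- list(channels = spec$channels,
                     windows = as.data.frame(spec$windows))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(
    list(weights = obj$weights, bias = obj$bias, gamma = obj$gamma,
         gamma_mode = obj$gamma_mode, nu = obj$nu,
         means = list(mu0 = obj$mu0, mu1 = obj$mu1), n = obj$n, d = obj$d),
    class = "shrinkage_lda")
  spec <- NULL
  if (!is.null(obj$spec)) {
    spec <- feature_spec(obj$spec$channels, as_tibble(obj$spec$windows))
  }
  list(model = model, spec = spec)
}
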
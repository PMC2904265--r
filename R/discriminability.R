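#' Spatial and temporal discriminability maps
#'
#' Locates where (on the scalp) and when (within the epoch) target versus
#' nontarget information is available: (a) per electrode, the
#' cross-validated binary classification error using that electrode's time
#' samples as features; (b) per 40 ms sliding window, the cross-validated
#' error using all electrodes' window means as features. Classes are
#' balanced by randomly subsampling the majority class so that chance
#' error is 0.5; classification uses shrinkage LDA with automatic gamma.
#'
#' @param epochs an `epoch_set` (epochs with data are used; the ERP
#'   contamination filters are not applied).
#' @param channels channel subset to analyze (default all).
#' @param window_ms sliding-window width (default 40).
#' @param step_ms sliding-window step (default 10).
#' @param folds number of stratified cross-validation folds (default 5).
#' @param seed seed for fold assignment and class balancing.
#' @return a `discriminability_maps` list: `electrode_error` (tibble
#'   `channel`, `error`), `window_error` (tibble `center_ms`, `error`).
#' @export
discriminability_maps <- function(epochs, channels = epochs$channels,
                                  window_ms = 40, step_ms = 10, folds = 5,
                                  seed = 1) {
  has_data <- !apply(is.na(epochs$data[, 1, , drop = FALSE]), 1, any)
  y <- as.integer(epochs$info$label == "target")
  rows <- which(has_data)
  y <- y[rows]
  if (length(unique(y)) < 2) abort("both classes must be present")
  bal <- with_seed_or_stream(seed, balance_classes(y))
  rows <- rows[bal]
  y <- y[bal]
  fold_id <- with_seed_or_stream(seed + 1L, stratified_folds(y, folds))

  ch_ix <- match(channels, epochs$channels)
  electrode_error <- purrr::map_dfr(seq_along(channels), function(ci) {
    x <- epochs$data[rows, ch_ix[ci], , drop = TRUE]
    tibble(channel = channels[ci], error = cv_error(x, y, fold_id))
  })

  t <- epochs$times_ms
  centers <- seq(min(t) + window_ms / 2, max(t) - window_ms / 2,
                 by = step_ms)
  window_error <- purrr::map_dfr(centers, function(ct) {
    ix <- which(t >= ct - window_ms / 2 & t <= ct + window_ms / 2)
    x <- rowMeans(epochs$data[rows, ch_ix, ix, drop = FALSE], dims = 2)
    tibble(center_ms = ct, error = cv_error(x, y, fold_id))
  })

  structure(list(electrode_error = electrode_error,
                 window_error = window_error),
            class = "discriminability_maps")
}

# indices of a balanced subsample (majority class downsampled)
balance_classes <- function(y) {
  i0 <- which(y == 0); i1 <- which(y == 1)
  m <- min(length(i0), length(i1))
  sort(c(sample(i0, m), sample(i1, m)))
}

# stratified fold labels
stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    ix <- sample(which(y == cl))
    id[ix] <- rep_len(seq_len(folds), length(ix))
  }
  id
}

# cross-validated misclassification error of shrinkage LDA (threshold 0)
cv_error <- function(x, y, fold_id) {
  errs <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    model <- train_shrinkage_lda(x[tr, , drop = FALSE], y[tr])
    pred <- as.integer(lda_score(model, x[!tr, , drop = FALSE]) > 0)
    mean(pred != y[!tr])
  }, numeric(1))
  mean(errs)
}

#' @export
print.discriminability_maps <- function(x, ...) {
  best_ch <- x$electrode_error$channel[which.min(x$electrode_error$error)]
  best_t <- x$window_error$center_ms[which.min(x$window_error$error)]
  cat(sprintf(
    "<discriminability_maps> best electrode %s (err %.3f), best window %g ms (err %.3f)\n",
    best_ch, min(x$electrode_error$error), best_t,
    min(x$window_error$error)))
  invisible(x)
}

#' @method autoplot discriminability_maps
#' @export
autoplot.discriminability_maps <- function(object, ...) {
  co <- montage_coordinates()
  df <- dplyr::left_join(object$electrode_error, co, by = "channel")
  p1 <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                         color = .data$error,
                                         label = .data$channel)) +
    ggplot2::geom_point(size = 6) +
    ggplot2::geom_text(size = 2, color = "black") +
    ggplot2::scale_color_viridis_c(direction = -1) +
    ggplot2::labs(title = "per-electrode CV error", x = NULL, y = NULL)
  p2 <- ggplot2::ggplot(object$window_error,
                        ggplot2::aes(.data$center_ms, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "sliding 40 ms window CV error",
                  x = "window center (ms)", y = "error")
  list(electrode = p1, window = p2)
}
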
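#' Point-biserial correlation map
#'
#' Pearson correlation between the signal value and the binary
#' target/nontarget label, computed per channel and time point over kept
#' epochs. Points with zero signal variance get r = 0.
#'
#' @param epochs an `epoch_set` (kept epochs are used).
#' @param labels optional 0/1 or logical label vector overriding the
#'   epochs' target flags (aligned to kept epochs).
#' @return a `score_map`: `r` (channels x time matrix in `[-1, 1]`),
#'   `times_ms`, `channels`.
#' @export
point_biserial <- function(epochs, labels = NULL) {
  kept <- which(epochs$info$kept)
  y <- labels %||% (epochs$info$label[kept] == "target")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    abort("both classes must be present to compute point-biserial r")
  }
  x <- epochs$data[kept, , , drop = FALSE]
  n <- length(y)
  dm <- dim(x)
  xm <- matrix(x, n, dm[2] * dm[3])           # epochs x (ch*time)
  xc <- sweep(xm, 2, colMeans(xm))
  yc <- y - mean(y)
  num <- as.numeric(crossprod(xc, yc))
  den <- sqrt(colSums(xc^2)) * sqrt(sum(yc^2))
  r <- ifelse(den > 0, num / den, 0)
  r <- matrix(r, dm[2], dm[3], dimnames = list(epochs$channels, NULL))
  structure(list(r = r, times_ms = epochs$times_ms,
                 channels = epochs$channels),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("<score_map> %d ch x %d times, |r| max %.3f\n",
              nrow(x$r), ncol(x$r), max(abs(x$r))))
  invisible(x)
}

#' @method autoplot score_map
#' @export
autoplot.score_map <- function(object, ...) {
  df <- tidyr::expand_grid(channel = factor(object$channels,
                                            levels = rev(object$channels)),
                           time_ms = object$times_ms)
  df$r <- as.vector(object$r)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$channel,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  fill = "point-biserial r")
}

#' Heuristic temporal-window selection
#'
#' Collapses a point-biserial map to a per-timepoint score (maximum of |r|
#' over channels), finds strict local maxima, and greedily accepts the
#' highest-scoring ones subject to a pairwise minimum separation, then
#' centers a fixed-width window on each accepted peak (clipped to the
#' epoch range) and sorts by time. Warns when fewer than `k` separated
#' maxima exist.
#'
#' @param map a [point_biserial()] result.
#' @param k number of windows (default 7).
#' @param width_ms window width (default 40).
#' @param min_separation_ms minimum peak separation (default 50).
#' @param min_time_ms earliest admissible peak (default 0: post-stimulus
#'   only).
#' @return tibble: `center_ms`, `start_ms`, `end_ms`, `score`.
#' @export
select_temporal_windows <- function(map, k = 7, width_ms = 40,
                                    min_separation_ms = 50,
                                    min_time_ms = 0) {
  score <- apply(abs(map$r), 2, max)
  t <- map$times_ms
  cand <- local_maxima(score)
  cand <- cand[t[cand] >= min_time_ms]
  cand <- cand[order(score[cand], decreasing = TRUE)]
  picked <- integer(0)
  for (i in cand) {
    if (length(picked) == k) break
    if (all(abs(t[i] - t[picked]) >= min_separation_ms)) {
      picked <- c(picked, i)
    }
  }
  if (length(picked) < k) {
    warn(sprintf("only %d of %d separated correlation peaks found",
                 length(picked), k))
  }
  out <- tibble(center_ms = t[picked], score = score[picked])
  out$start_ms <- pmax(out$center_ms - width_ms / 2, min(t))
  out$end_ms <- pmin(out$center_ms + width_ms / 2, max(t))
  dplyr::arrange(out[, c("center_ms", "start_ms", "end_ms", "score")],
                 .data$center_ms)
}

#' Spatio-temporal feature specification
#'
#' @param channels ordered channel subset (default the 55-channel
#'   classification montage).
#' @param windows tibble with `start_ms` / `end_ms` (e.g. from
#'   [select_temporal_windows()]).
#' @return a `feature_spec` with `channels`, `windows`, `dimensionality`
#'   (`length(channels) * nrow(windows)`).
#' @export
feature_spec <- function(channels = classification_channels(), windows) {
  structure(list(channels = channels, windows = windows,
                 dimensionality = length(channels) * nrow(windows)),
            class = "feature_spec")
}

#' Build spatio-temporal features
#'
#' Per epoch, the mean amplitude within each (channel, temporal window)
#' cell, flattened channel-major. All epochs are used regardless of the
#' ERP contamination filters — the classification path never discards
#' epochs (only boundary-less epochs enter, i.e. `info$kept` from
#' epoching; filter flags applied later are ignored by passing
#' `use = "all"`).
#'
#' @param epochs an `epoch_set`.
#' @param spec a [feature_spec()].
#' @param use `"all"` (every epoch with data, default) or `"kept"`.
#' @return list: `x` (epochs x dimensionality matrix), `y` (0/1 labels,
#'   1 = target), `info` (matching epoch info rows), `spec`.
#' @export
build_features <- function(epochs, spec, use = c("all", "kept")) {
  use <- match.arg(use)
  has_data <- !apply(is.na(epochs$data[, 1, , drop = FALSE]), 1, any)
  rows <- if (use == "all") which(has_data) else which(epochs$info$kept)
  chs <- spec$channels
  if (!all(chs %in% epochs$channels)) {
    abort("feature channels missing from the epoch set")
  }
  ch_ix <- match(chs, epochs$channels)
  win_ix <- lapply(seq_len(nrow(spec$windows)), function(i) {
    ix <- which(epochs$times_ms >= spec$windows$start_ms[i] &
                  epochs$times_ms <= spec$windows$end_ms[i])
    if (length(ix) == 0) abort("a feature window contains no samples")
    ix
  })
  n <- length(rows)
  x <- matrix(0, n, spec$dimensionality)
  col <- 0L
  for (ci in ch_ix) {
    for (w in win_ix) {
      col <- col + 1L
      x[, col] <- rowMeans(epochs$data[rows, ci, w, drop = FALSE],
                           dims = 1)
    }
  }
  list(x = x, y = as.integer(epochs$info$label[rows] == "target"),
       info = epochs$info[rows, ], spec = spec)
}

#' Train a shrinkage-regularized LDA classifier
#'
#' Binary linear discriminant with covariance shrinkage toward a scaled
#' identity: the pooled empirical covariance S (computed from class-
#' centered samples) is replaced by
#' `S(gamma) = (1 - gamma) S + gamma * nu * I`, `nu = mean(diag(S))`.
#' `gamma` is either fixed or estimated analytically with the
#' Ledoit-Wolf / Schafer-Strimmer formula
#' `gamma* = sum_ij Var(S_ij) / sum_ij (S_ij - T_ij)^2` (T = nu I),
#' clipped to `[0, 1]`. Weights are `S(gamma)^-1 (mu1 - mu0)`; the bias
#' places the decision threshold midway between the projected class means.
#' At `gamma = 0` with a singular S the inverse falls back to the
#' Moore-Penrose pseudoinverse.
#'
#' @param x feature matrix (samples x features).
#' @param y binary labels (0/1 or logical; 1 = target).
#' @param gamma `"auto"` (default) or a fixed value in `[0, 1]`.
#' @return a `shrinkage_lda` model: `weights`, `bias`, `gamma`,
#'   `gamma_mode`, `nu`, `means` (list `mu0`, `mu1`), `n`, `d`.
#' @export
train_shrinkage_lda <- function(x, y, gamma = "auto") {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (min(table(y)) < 2) abort("need at least 2 samples per class")
  if (is.numeric(gamma) && (gamma < 0 || gamma > 1)) {
    abort("fixed gamma must lie in [0, 1]")
  }
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  mu0 <- colMeans(x[y == 0, , drop = FALSE])
  mu1 <- colMeans(x[y == 1, , drop = FALSE])
  z <- x
  z[y == 0, ] <- sweep(x[y == 0, , drop = FALSE], 2, mu0)
  z[y == 1, ] <- sweep(x[y == 1, , drop = FALSE], 2, mu1)
  s <- crossprod(z) / (n - 1)
  nu <- mean(diag(s))
  if (identical(gamma, "auto")) {
    # Var-hat of the entries of S from the centered samples
    wbar <- crossprod(z) / n
    w2 <- crossprod(z^2)
    var_s <- n / (n - 1)^3 * (w2 - n * wbar^2)
    tgt <- diag(nu, d)
    denom <- sum((s - tgt)^2)
    g <- if (denom > 0) sum(var_s) / denom else 1
    gamma_val <- min(max(g, 0), 1)
    gamma_mode <- "auto"
  } else {
    gamma_val <- gamma
    gamma_mode <- "fixed"
  }
  sg <- (1 - gamma_val) * s
  diag(sg) <- diag(sg) + gamma_val * nu
  dmu <- mu1 - mu0
  w <- tryCatch(solve(sg, dmu), error = function(e) {
    as.numeric(MASS::ginv(sg) %*% dmu)
  })
  b <- -sum(w * (mu0 + mu1)) / 2
  structure(list(weights = as.numeric(w), bias = b, gamma = gamma_val,
                 gamma_mode = gamma_mode, nu = nu,
                 means = list(mu0 = mu0, mu1 = mu1), n = n, d = d),
            class = "shrinkage_lda")
}

#' @export
print.shrinkage_lda <- function(x, ...) {
  cat(sprintf("<shrinkage_lda> d = %d, n = %d, gamma = %.4f (%s)\n",
              x$d, x$n, x$gamma, x$gamma_mode))
  invisible(x)
}

#' Classifier output for feature vectors
#'
#' Linear score `w' x + b`; higher values are more target-like, and the
#' midpoint of the class means scores exactly 0.
#'
#' @param model a [train_shrinkage_lda()] model.
#' @param x feature matrix (samples x features) or single vector.
#' @return numeric score per row.
#' @export
lda_score <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != model$d) {
    abort(sprintf("feature length %d does not match model dimension %d",
                  ncol(x), model$d))
  }
  as.numeric(x %*% model$weights + model$bias)
}

#' @export
predict.shrinkage_lda <- function(object, newdata, ...) {
  lda_score(object, newdata)
}

#' @method tidy shrinkage_lda
#' @export
tidy.shrinkage_lda <- function(x, ...) {
  tibble(feature = seq_len(x$d), weight = x$weights)
}

#' @method glance shrinkage_lda
#' @export
glance.shrinkage_lda <- function(x, ...) {
  tibble(n = x$n, d = x$d, gamma = x$gamma, gamma_mode = x$gamma_mode,
         nu = x$nu)
}

#' Decode a trial from per-event classifier outputs
#'
#' Restricts the stream to the first `n_sequences` core sequences,
#' averages classifier outputs per selection group (Matrix: per row and
#' per column separately; Hex-o-Spell: per disc per level), picks the
#' argmax per decision stage (ties resolve to the lowest group index), and
#' maps the selection through [decode_selection()]. A Hex-o-Spell trial is
#' decoded correctly only if both stages are correct; choosing the empty
#' backdoor disc yields no symbol.
#'
#' @param scores numeric vector of classifier outputs aligned to `info`
#'   rows.
#' @param info tibble with `level`, `phase`, `sequence`, `element_id`
#'   (e.g. `epoch_set$info` rows or a schedule).
#' @param layout the trial's [build_layout()].
#' @param n_sequences number of core sequences to use.
#' @return list: `symbol` (`NA` on backdoor), `backdoor`, `selection`
#'   (chosen element ids per stage).
#' @export
decode_trial <- function(scores, info, layout, n_sequences) {
  stopifnot(length(scores) == nrow(info))
  core <- info$phase == "core" & info$sequence <= n_sequences &
    !is.na(info$sequence)
  if (!any(core)) abort("no core events within the requested sequences")
  sel <- character(0)
  if (layout$kind == "matrix") {
    dat <- tibble(element_id = info$element_id[core], score = scores[core])
    means <- dplyr::summarise(dplyr::group_by(dat, .data$element_id),
                              m = mean(.data$score))
    for (pfx in c("R", "C")) {
      grp <- means[startsWith(means$element_id, pfx), ]
      grp <- grp[order(grp$element_id), ]
      sel <- c(sel, grp$element_id[which.max(grp$m)])
    }
  } else {
    for (lv in 1:2) {
      ix <- core & info$level == lv
      dat <- tibble(element_id = info$element_id[ix], score = scores[ix])
      means <- dplyr::summarise(dplyr::group_by(dat, .data$element_id),
                                m = mean(.data$score))
      means <- means[order(means$element_id), ]
      sel <- c(sel, means$element_id[which.max(means$m)])
    }
  }
  res <- decode_selection(layout, sel)
  res$selection <- sel
  res
}

#' Accuracy as a function of the number of sequences
#'
#' Aggregates per-trial decoding outcomes into the fraction of correctly
#' decoded symbols for each number of intensification sequences.
#'
#' @param decoded tibble with columns `trial`, `n_sequences`, `correct`
#'   (logical), plus optional condition columns.
#' @param by optional extra grouping columns (e.g. condition keys).
#' @return an `accuracy_curve` tibble: grouping columns, `n_sequences`,
#'   `accuracy`, `n_trials`.
#' @export
accuracy_curve <- function(decoded, by = character(0)) {
  out <- dplyr::summarise(
    dplyr::group_by(decoded, dplyr::across(dplyr::all_of(c(by, "n_sequences")))),
    accuracy = mean(.data$correct), n_trials = dplyr::n(),
    .groups = "drop")
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  keys <- setdiff(names(object), c("n_sequences", "accuracy", "n_trials"))
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$n_sequences,
                                            .data$accuracy))
  if (length(keys)) {
    object$condition <- do.call(paste, c(object[keys], sep = " / "))
    p <- ggplot2::ggplot(object, ggplot2::aes(.data$n_sequences,
                                              .data$accuracy,
                                              color = .data$condition))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "number of sequences", y = "decoding accuracy")
}
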
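test_that("point-biserial correlation matches the direct Pearson formula", {
  t <- c(0, 10)
  vals <- c(1, 2, 3, 4, 5, 6)
  labs <- c(0, 0, 0, 1, 1, 1)
  data <- array(0, c(6, 1, 2))
  data[, 1, 1] <- vals
  data[, 1, 2] <- labs          # value equals label at the second point
  ep <- make_epoch_set(data, t, "Cz",
                       labels = ifelse(labs == 1, "target", "nontarget"))
  map <- point_biserial(ep)
  expect_equal(unname(map$r[1, 1]), stats::cor(vals, labs))  # textbook oracle
  expect_equal(unname(map$r[1, 2]), 1)
  # constant signal has zero variance: r defined as 0
  data0 <- array(7, c(6, 1, 1))
  ep0 <- make_epoch_set(data0, 0, "Cz",
                        labels = ifelse(labs == 1, "target", "nontarget"))
  expect_equal(unname(point_biserial(ep0)$r[1, 1]), 0)
  ep1 <- make_epoch_set(data, t, "Cz", labels = rep("target", 6))
  expect_error(point_biserial(ep1), "both classes")
})

test_that("window selection centers on well-separated correlation peaks", {
  t <- seq(-170, 670, by = 10)
  r <- rbind(0.02 * exp(-(t - 200)^2 / (2 * 20^2)) +
               0.03 * exp(-(t - 400)^2 / (2 * 20^2)))
  map <- structure(list(r = r, times_ms = t, channels = "Cz"),
                   class = "score_map")
  w <- select_temporal_windows(map, k = 2, width_ms = 40,
                               min_separation_ms = 50)
  expect_equal(nrow(w), 2)
  expect_lte(abs(w$center_ms[1] - 200), 20)
  expect_lte(abs(w$center_ms[2] - 400), 20)
  expect_equal(w$end_ms - w$start_ms, c(40, 40))
  # flat map: no peaks, warning, zero windows
  flat <- structure(list(r = r * 0, times_ms = t, channels = "Cz"),
                    class = "score_map")
  expect_warning(w0 <- select_temporal_windows(flat, k = 3), "0 of 3")
  expect_equal(nrow(w0), 0)
})

test_that("feature building averages per channel and window", {
  t <- seq(-170, 670, by = 10)
  n_t <- length(t)
  data <- array(rnorm(4 * 2 * n_t), c(4, 2, n_t))
  ep <- make_epoch_set(data, t, c("Cz", "Pz"),
                       labels = c("target", "nontarget", "target",
                                  "nontarget"))
  whole <- tibble::tibble(start_ms = min(t), end_ms = max(t))
  spec <- feature_spec(c("Cz", "Pz"), whole)
  f <- build_features(ep, spec)
  expect_equal(dim(f$x), c(4, 2))
  expect_equal(f$x[, 1], rowMeans(data[, 1, ]))
  expect_equal(f$y, c(1, 0, 1, 0))
  # constant epoch gives constant features; dimensionality = ch x windows
  datac <- array(3.5, c(2, 2, n_t))
  epc <- make_epoch_set(datac, t, c("Cz", "Pz"),
                        labels = c("target", "nontarget"))
  two <- tibble::tibble(start_ms = c(0, 300), end_ms = c(100, 400))
  spec2 <- feature_spec(c("Cz", "Pz"), two)
  expect_equal(spec2$dimensionality, 4)
  f2 <- build_features(epc, spec2)
  expect_true(all(f2$x == 3.5))
  bad <- feature_spec(c("Cz", "XX"), two)
  expect_error(build_features(ep, bad), "missing")
})

test_that("gamma = 0 reproduces classical LDA from a direct-solve oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 60; d <- 6
    x <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, 1), n))
    y <- rep(c(0, 1), each = n)
    m <- train_shrinkage_lda(x, y, gamma = 0)
    # independent oracle: pooled covariance via cov() and qr.solve
    x0 <- x[y == 0, ]; x1 <- x[y == 1, ]
    sp <- ((n - 1) * stats::cov(x0) + (n - 1) * stats::cov(x1)) / (2 * n - 2)
    w_oracle <- qr.solve(sp, colMeans(x1) - colMeans(x0))
    # covariance denominators differ (n-1 pooled vs 2n-2); weights are
    # proportional, so compare directions and the induced scores
    expect_equal(m$weights / sqrt(sum(m$weights^2)),
                 w_oracle / sqrt(sum(w_oracle^2)), tolerance = 1e-8)
  }
})

test_that("gamma = 1 gives the spherical closed form", {
  set.seed(3)
  x <- rbind(matrix(rnorm(200), 50), matrix(rnorm(200, 2), 50))
  y <- rep(c(0, 1), each = 50)
  m <- train_shrinkage_lda(x, y, gamma = 1)
  mu0 <- colMeans(x[y == 0, ]); mu1 <- colMeans(x[y == 1, ])
  expect_equal(m$weights, (mu1 - mu0) / m$nu, tolerance = 1e-10)
  # bias convention: the midpoint of the class means scores zero
  expect_equal(lda_score(m, (mu0 + mu1) / 2), 0, tolerance = 1e-10)
  expect_gt(lda_score(m, mu1), 0)
  expect_error(train_shrinkage_lda(x, y, gamma = 1.5), "\\[0, 1\\]")
  expect_error(train_shrinkage_lda(x, rep(0, 100)), "both classes")
})

test_that("batch scoring equals per-row scoring and checks dimensions", {
  set.seed(4)
  x <- rbind(matrix(rnorm(80), 20), matrix(rnorm(80, 1), 20))
  y <- rep(c(0, 1), each = 20)
  m <- train_shrinkage_lda(x, y)
  batch <- lda_score(m, x)
  rowwise <- vapply(seq_len(nrow(x)), function(i) lda_score(m, x[i, ]),
                    numeric(1))
  expect_equal(batch, rowwise)
  expect_equal(predict(m, x), batch)
  expect_error(lda_score(m, matrix(0, 2, 3)), "does not match")
})

test_that("automatic shrinkage helps in high dimension", {
  # d = 385, n = 100 per class: auto gamma must land inside (0, 1) and
  # beat the (pseudoinverse) classical LDA on held-out accuracy on average
  d <- 385
  acc <- matrix(NA_real_, 5, 2)
  for (rep in 1:5) {
    set.seed(rep)
    mu <- rnorm(d, sd = 0.3)
    xtr <- rbind(matrix(rnorm(100 * d), 100),
                 sweep(matrix(rnorm(100 * d), 100), 2, mu, `+`))
    xte <- rbind(matrix(rnorm(100 * d), 100),
                 sweep(matrix(rnorm(100 * d), 100), 2, mu, `+`))
    y <- rep(c(0, 1), each = 100)
    m_auto <- train_shrinkage_lda(xtr, y)
    m_cls <- train_shrinkage_lda(xtr, y, gamma = 0)
    expect_gt(m_auto$gamma, 0)
    expect_lt(m_auto$gamma, 1)
    acc[rep, 1] <- mean((lda_score(m_auto, xte) > 0) == (y == 1))
    acc[rep, 2] <- mean((lda_score(m_cls, xte) > 0) == (y == 1))
  }
  expect_gte(mean(acc[, 1]), mean(acc[, 2]))
})

test_that("model tidiers expose weights and fit metadata", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40), 10), matrix(rnorm(40, 1), 10))
  m <- train_shrinkage_lda(x, rep(c(0, 1), each = 10))
  td <- tidy(m)
  expect_equal(nrow(td), 4)
  expect_named(td, c("feature", "weight"))
  gl <- glance(m)
  expect_equal(gl$d, 4)
  expect_equal(gl$gamma_mode, "auto")
})

test_that("perfect per-event outputs decode the true symbol at every n", {
  for (kind in c("matrix", "hex")) {
    lay <- build_layout(kind)
    sched <- generate_trial_schedule(lay, "H", seed = 8)
    scores <- as.numeric(sched$is_target)
    for (n in c(1, 5, 10)) {
      d <- decode_trial(scores, sched, lay, n)
      expect_identical(d$symbol, "H")
      expect_false(d$backdoor)
    }
  }
})

test_that("a backdoor argmax yields no symbol and counts as incorrect", {
  lay <- build_layout("hex")
  sched <- generate_trial_schedule(lay, "H", seed = 8)
  # level 1 correct, level 2 forced to the empty disc
  scores <- as.numeric(sched$is_target & sched$level == 1)
  scores[sched$level == 2 & sched$element_id == "D6"] <- 5
  d <- decode_trial(scores, sched, lay, 10)
  expect_true(d$backdoor)
  expect_true(is.na(d$symbol))
  expect_equal(d$selection[2], "D6")
})

test_that("ties resolve deterministically to the lowest element id", {
  lay <- build_layout("matrix")
  sched <- generate_trial_schedule(lay, "H", seed = 8)
  d <- decode_trial(rep(0, nrow(sched)), sched, lay, 10)
  expect_identical(d$selection, c("R1", "C1"))
  expect_error(decode_trial(rep(0, nrow(sched)), sched, lay, 0),
               "no core events")
})

test_that("accuracy curves aggregate per-trial outcomes", {
  decoded <- tidyr::expand_grid(trial = 1:4, n_sequences = 1:3)
  decoded$correct <- TRUE
  ac <- accuracy_curve(decoded)
  expect_equal(ac$accuracy, rep(1, 3))
  decoded$correct <- decoded$trial <= 2
  ac2 <- accuracy_curve(decoded)
  expect_equal(ac2$accuracy, rep(0.5, 3))
  expect_equal(ac2$n_trials, rep(4, 3))
})
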
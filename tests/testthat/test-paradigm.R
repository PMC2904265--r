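test_that("pixel extents map to the printed visual angles", {
  geo <- display_geometry()
  expect_equal(px_to_degrees(148, geo), 4.15, tolerance = 0.1 / 4.15)
  expect_equal(px_to_degrees(40, geo), 1.12, tolerance = 0.05 / 1.12)
  expect_equal(px_to_degrees(500, geo), 13.96, tolerance = 0.1 / 13.96)
  # small-angle limit: angle ~ extent / distance (radians)
  tiny <- 1e-4
  expected <- tiny * geo$pitch_cm / geo$viewing_distance_cm * 180 / pi
  expect_equal(px_to_degrees(tiny, geo), expected, tolerance = 1e-8)
  expect_error(px_to_degrees(-1, geo), "positive")
})

test_that("intensification size increases match both spellers", {
  expect_equal(intensification_increase(40, 65), 62.5)
  expect_equal(round(intensification_increase(148, 200), 1), 35.1)
  expect_equal(intensification_increase(77, 77), 0)
  expect_error(intensification_increase(0, 10), "positive")
})

test_that("matrix layout covers 30 symbols with 6 rows and 5 columns", {
  lay <- build_layout("matrix")
  groups <- lay$groups$level1
  rows <- groups[startsWith(names(groups), "R")]
  cols <- groups[startsWith(names(groups), "C")]
  expect_length(rows, 6)
  expect_length(cols, 5)
  expect_setequal(unlist(rows), lay$symbols)
  # every symbol in exactly one row and one column
  for (s in lay$symbols) {
    expect_equal(sum(vapply(rows, function(g) s %in% g, logical(1))), 1)
    expect_equal(sum(vapply(cols, function(g) s %in% g, logical(1))), 1)
  }
  expect_equal(unique(lay$elements$base_size_px), 40)
  expect_equal(unique(lay$elements$intensified_size_px), 65)
})

test_that("hex layout has six groups and an empty backdoor disc", {
  lay <- build_layout("hex")
  expect_length(lay$groups$level1, 6)
  expect_true(all(lengths(lay$groups$level1) == 5))
  expect_setequal(unlist(lay$groups$level1), lay$symbols)
  expect_length(lay$groups$level2, 6)
  expect_length(lay$groups$level2$D6, 0)  # the backdoor
  expect_equal(unique(lay$elements$base_size_px), 148)
})

test_that("geometry scaling changes pixels but not group structure", {
  g2 <- display_geometry(width_px = 2560, height_px = 2048)
  lay1 <- build_layout("matrix")
  lay2 <- build_layout("matrix", geometry = g2)
  expect_identical(lay1$groups, lay2$groups)
  expect_equal(lay2$elements$base_size_px, lay1$elements$base_size_px * 2)
  expect_error(build_layout("circle"), "arg")
})

test_that("core blocks are per-sequence permutations obeying the min-gap", {
  b <- generate_core_block(11, 10, min_gap = 2, seed = 42)
  expect_length(b, 110)
  expect_true(all(table(b) == 10))
  for (s in 1:10) {  # each sequence a permutation
    expect_setequal(b[(s - 1) * 11 + 1:11], 1:11)
  }
  # linear-scan oracle: all equal-element pairs separated by >= 2 others
  occ <- split(seq_along(b), b)
  expect_true(all(vapply(occ, function(p) all(diff(p) >= 3), logical(1))))
})

test_that("one sequence of the core block is a plain permutation", {
  b <- generate_core_block(6, 1, seed = 5)
  expect_setequal(b, 1:6)
})

test_that("3-element blocks force identical consecutive sequences", {
  # exhaustive oracle: of all 36 ordered pairs of 3-permutations, exactly
  # the 6 identical pairs satisfy the min-gap-2 constraint
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  valid <- 0
  for (p in perms) for (q in perms) {
    blk <- c(p, q)
    occ <- split(seq_along(blk), blk)
    if (all(vapply(occ, function(z) all(diff(z) >= 3), logical(1)))) {
      valid <- valid + 1
      expect_identical(p, q)
    }
  }
  expect_equal(valid, 6)
  for (seed in 1:5) {
    b <- generate_core_block(3, 2, seed = seed)
    expect_identical(b[1:3], b[4:6])
  }
})

test_that("infeasible core blocks are rejected", {
  expect_error(generate_core_block(2, 3, min_gap = 2), "infeasible")
})

test_that("matrix trials have 132 events and 20 core target events", {
  lay <- build_layout("matrix")
  sched <- generate_trial_schedule(lay, "B", seed = 3)
  expect_equal(nrow(sched), 132)
  expect_equal(sum(sched$phase == "core"), 110)
  expect_equal(count_target_intensifications(sched, "core"), 20)
  expect_true(all(diff(sched$onset_ms) == 166))
  # each row/column exactly once per core sequence
  core <- sched[sched$phase == "core", ]
  for (s in unique(core$sequence)) {
    expect_setequal(core$element_id[core$sequence == s],
                    names(lay$groups$level1))
  }
})

test_that("hex trials have 72 events per level, 144 total, 10 targets each", {
  lay <- build_layout("hex")
  sched <- generate_trial_schedule(lay, "B", seed = 3)
  expect_equal(nrow(sched), 144)
  expect_equal(sum(sched$level == 1), 72)
  expect_equal(sum(sched$level == 2), 72)
  expect_equal(sum(sched$is_target & sched$phase == "core" &
                     sched$level == 1), 10)
  expect_equal(sum(sched$is_target & sched$phase == "core" &
                     sched$level == 2), 10)
  expect_equal(count_target_intensifications(sched, "core"), 20)
})

test_that("target counts over all phases vary across trials", {
  lay <- build_layout("matrix")
  counts <- vapply(1:30, function(s) {
    count_target_intensifications(generate_trial_schedule(lay, "B",
                                                          seed = s))
  }, numeric(1))
  expect_gt(length(unique(counts)), 1)
  expect_true(all(counts >= 20))  # prequel/sequel only add target events
})

test_that("schedules are reproducible by seed and differ across seeds", {
  lay <- build_layout("hex")
  a <- generate_trial_schedule(lay, "K", seed = 11)
  b <- generate_trial_schedule(lay, "K", seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  distinct <- vapply(1:100, function(s) {
    !identical(
      generate_trial_schedule(lay, "K", seed = s)$element_id,
      a$element_id)
  }, logical(1))
  expect_gt(mean(distinct), 0.98)
  expect_error(generate_trial_schedule(lay, "?", seed = 1), "vocabulary")
})

test_that("decode_selection inverts the true row/column for all symbols", {
  lay <- build_layout("matrix")
  for (s in lay$symbols) {
    sel <- target_els <- c(
      grep("^R", names(lay$groups$level1), value = TRUE)[
        vapply(lay$groups$level1[1:6], function(g) s %in% g, logical(1))],
      grep("^C", names(lay$groups$level1), value = TRUE)[
        vapply(lay$groups$level1[7:11], function(g) s %in% g, logical(1))])
    expect_identical(decode_selection(lay, sel)$symbol, s)
  }
})

test_that("hex decoding returns group symbols and flags the backdoor", {
  lay <- build_layout("hex")
  expect_identical(decode_selection(lay, c("G1", "D2"))$symbol, "B")
  for (s in lay$symbols) {
    grp <- names(lay$groups$level1)[
      vapply(lay$groups$level1, function(g) s %in% g, logical(1))]
    pos <- match(s, lay$groups$level1[[grp]])
    expect_identical(decode_selection(lay, c(grp, paste0("D", pos)))$symbol,
                     s)
  }
  bd <- decode_selection(lay, c("G3", "D6"))
  expect_true(bd$backdoor)
  expect_true(is.na(bd$symbol))
  expect_error(decode_selection(lay, c("G9", "D1")), "valid")
})

test_that("chance levels are 1/30 (matrix) and 1/36 (hex)", {
  expect_equal(chance_level(build_layout("matrix")), 1 / 30)
  expect_equal(chance_level(build_layout("hex")), 1 / 36)
})

test_that("schedule round-trips through the TSV event table", {
  sched <- generate_trial_schedule(build_layout("matrix"), "Q", seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_schedule(sched, path)
  back <- read_schedule(path)
  expect_equal(back$element_id, sched$element_id)
  expect_equal(back$is_target, sched$is_target)
  expect_equal(back$onset_ms, sched$onset_ms)
})
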
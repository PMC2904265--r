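#' Display geometry of the presentation screen
#'
#' Physical description of the stimulation monitor, used to convert pixel
#' extents to degrees of visual angle. Defaults describe a 19-inch TFT at
#' 1280 x 1024 with 60 Hz refresh viewed from 60 cm.
#'
#' @param width_px,height_px screen resolution in pixels.
#' @param diagonal_inch physical diagonal in inches.
#' @param viewing_distance_cm eye-to-screen distance in centimeters.
#' @param refresh_hz refresh rate in Hz.
#' @return a `display_geometry` list with the fields above plus the derived
#'   square-pixel pitch `pitch_cm` (cm per pixel).
#' @export
#' @examples
#' display_geometry()$pitch_cm
display_geometry <- function(width_px = 1280, height_px = 1024,
                             diagonal_inch = 19, viewing_distance_cm = 60,
                             refresh_hz = 60) {
  for (nm in c("width_px", "height_px", "diagonal_inch",
               "viewing_distance_cm", "refresh_hz")) {
    stopifnot_positive(get(nm), nm)
  }
  pitch_cm <- diagonal_inch * 2.54 / sqrt(width_px^2 + height_px^2)
  structure(
    list(width_px = width_px, height_px = height_px,
         diagonal_inch = diagonal_inch,
         viewing_distance_cm = viewing_distance_cm,
         refresh_hz = refresh_hz, pitch_cm = pitch_cm),
    class = "display_geometry"
  )
}

#' Convert a pixel extent to visual angle
#'
#' Full subtended angle `2 * atan(extent / (2 * distance))` in degrees,
#' assuming square pixels (pitch from the screen diagonal and resolution),
#' a flat screen, and central viewing.
#'
#' @param extent_px extent in pixels (vectorized).
#' @param geometry a [display_geometry()].
#' @return visual angle(s) in degrees.
#' @export
#' @examples
#' px_to_degrees(148)  # a Hex-o-Spell disc, about 4.15 degrees
px_to_degrees <- function(extent_px, geometry = display_geometry()) {
  stopifnot_positive(extent_px, "extent_px")
  extent_cm <- extent_px * geometry$pitch_cm
  2 * atan(extent_cm / (2 * geometry$viewing_distance_cm)) * 180 / pi
}

#' Relative size increase of an intensified element
#'
#' @param base_px,intensified_px element extent before / during
#'   intensification, in pixels.
#' @return percent increase `100 * (intensified - base) / base`.
#' @export
#' @examples
#' intensification_increase(40, 65)   # 62.5
#' intensification_increase(148, 200) # 35.1
intensification_increase <- function(base_px, intensified_px) {
  stopifnot_positive(base_px, "base_px")
  100 * (intensified_px - base_px) / base_px
}

#' The 30-symbol speller vocabulary
#'
#' The 26 letters plus four punctuation/control symbols, giving the 30
#' selectable symbols shared by both spellers.
#'
#' @return character vector of length 30.
#' @export
speller_vocabulary <- function() {
  c(LETTERS, "_", ".", ",", "!")
}

#' Build a speller layout
#'
#' Constructs the Matrix speller (30 symbols in 6 rows x 5 columns on a
#' 500 x 500 px grid; symbols 40 px tall, 65 px when intensified) or the
#' two-level Hex-o-Spell (6 discs of 148 px, 200 px when intensified, on an
#' invisible hexagon of 440 px diameter; level 1 selects one of six 5-symbol
#' groups, level 2 one of 6 discs of which one is an empty "backdoor").
#'
#' @param kind `"matrix"` or `"hex"`.
#' @param geometry a [display_geometry()]; scales pixel fields only, never
#'   the group structure.
#' @param grid_px,symbol_px,symbol_intens_px Matrix geometry overrides.
#' @param hex_diameter_px,disc_px,disc_intens_px Hex-o-Spell overrides.
#' @return a `speller_layout` list: `kind`, `symbols`, `n_levels`,
#'   `groups` (per level, named list mapping element id to member symbols;
#'   for the hex symbol level the discs are positional, with `"D6"` empty),
#'   `elements` (tibble of element id, level, center and sizes in px), and
#'   the geometry.
#' @export
#' @examples
#' lay <- build_layout("matrix")
#' names(lay$groups$level1)
build_layout <- function(kind = c("matrix", "hex"),
                         geometry = display_geometry(),
                         grid_px = 500, symbol_px = 40, symbol_intens_px = 65,
                         hex_diameter_px = 440, disc_px = 148,
                         disc_intens_px = 200) {
  kind <- match.arg(kind)
  scale <- geometry$width_px / 1280  # pixel fields scale with resolution
  vocab <- speller_vocabulary()
  if (kind == "matrix") {
    n_rows <- 6L; n_cols <- 5L
    grid <- grid_px * scale
    cell_w <- grid / n_cols; cell_h <- grid / n_rows
    cells <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
    rows <- lapply(seq_len(n_rows), function(r) vocab[(r - 1) * n_cols + seq_len(n_cols)])
    names(rows) <- paste0("R", seq_len(n_rows))
    cols <- lapply(seq_len(n_cols), function(c) vocab[(seq_len(n_rows) - 1) * n_cols + c])
    names(cols) <- paste0("C", seq_len(n_cols))
    elements <- tibble(
      element_id = c(names(rows), names(cols)),
      level = 1L,
      center_x_px = c(rep(grid / 2, n_rows), (seq_len(n_cols) - 0.5) * cell_w),
      center_y_px = c((seq_len(n_rows) - 0.5) * cell_h, rep(grid / 2, n_cols)),
      base_size_px = symbol_px * scale,
      intensified_size_px = symbol_intens_px * scale
    )
    groups <- list(level1 = c(rows, cols))
  } else {
    n_groups <- 6L
    stopifnot(length(vocab) == 5L * n_groups)
    gsym <- split(vocab, rep(seq_len(n_groups), each = 5L))
    groups1 <- stats::setNames(gsym, paste0("G", seq_len(n_groups)))
    ang <- (seq_len(n_groups) - 1) * pi / 3
    rad <- hex_diameter_px * scale / 2
    elements <- tibble(
      element_id = c(paste0("G", 1:6), paste0("D", 1:6)),
      level = rep(1:2, each = 6L),
      center_x_px = rep(rad * sin(ang), 2),
      center_y_px = rep(-rad * cos(ang), 2),
      base_size_px = disc_px * scale,
      intensified_size_px = disc_intens_px * scale
    )
    # level 2 is positional: disc i carries the i-th symbol of the chosen
    # group; disc 6 is the empty backdoor
    groups <- list(
      level1 = groups1,
      level2 = stats::setNames(
        c(as.list(paste0("slot", 1:5)), list(character(0))),
        paste0("D", 1:6))
    )
  }
  structure(
    list(kind = kind, symbols = vocab,
         n_levels = if (kind == "matrix") 1L else 2L,
         groups = groups, elements = elements, geometry = geometry),
    class = "speller_layout"
  )
}

#' @export
print.speller_layout <- function(x, ...) {
  cat(sprintf("<speller_layout> %s: %d symbols, %d level(s)\n",
              x$kind, length(x$symbols), x$n_levels))
  invisible(x)
}

# element ids intensified at a given level
level_elements <- function(layout, level) {
  names(layout$groups[[paste0("level", level)]])
}

# element ids at `level` that contain / correspond to `target`
target_elements <- function(layout, target, level = 1L) {
  if (!target %in% layout$symbols) {
    abort(sprintf("target symbol '%s' is not in the vocabulary", target))
  }
  if (layout$kind == "matrix") {
    hit <- vapply(layout$groups$level1, function(s) target %in% s, logical(1))
    names(layout$groups$level1)[hit]
  } else if (level == 1L) {
    hit <- vapply(layout$groups$level1, function(s) target %in% s, logical(1))
    names(layout$groups$level1)[hit]
  } else {
    grp <- target_elements(layout, target, 1L)
    pos <- match(target, layout$groups$level1[[grp]])
    paste0("D", pos)
  }
}

#' Timing parameters of the intensification stream
#'
#' @param soa_ms stimulus onset asynchrony in ms (default 166, i.e. 10
#'   frames at 60 Hz).
#' @param intensification_ms duration of one intensification (default 100).
#' @param n_sequences number of core sequences per level (default 10).
#' @param countdown_s pre-trial countdown in seconds (not simulated, kept
#'   for provenance).
#' @return a `timing_params` list.
#' @export
timing_params <- function(soa_ms = 166, intensification_ms = 100,
                          n_sequences = 10, countdown_s = 4) {
  if (intensification_ms >= soa_ms) {
    abort("`intensification_ms` must be shorter than `soa_ms`")
  }
  if (n_sequences < 1) abort("`n_sequences` must be >= 1")
  structure(list(soa_ms = soa_ms, intensification_ms = intensification_ms,
                 n_sequences = as.integer(n_sequences),
                 countdown_s = countdown_s),
            class = "timing_params")
}

#' Generate a constrained pseudo-random core block
#'
#' Concatenates `n_sequences` random permutations of `n_elements` element
#' indices such that, across the whole block, two occurrences of the same
#' element are always separated by at least `min_gap` other
#' intensifications (the oddball stream constraint: at least two
#' intermittent intensifications before an element repeats). Each successive
#' permutation is rejection-resampled until it is compatible with the tail
#' of the block; generation fails after `max_retries` attempts.
#'
#' @param n_elements number of distinct elements (> `min_gap`).
#' @param n_sequences number of permutations to concatenate.
#' @param min_gap minimum number of intervening events between repeats
#'   (default 2).
#' @param seed optional integer seed (local RNG stream).
#' @param max_retries rejection-sampling cap per sequence.
#' @return integer vector of length `n_elements * n_sequences`.
#' @export
#' @examples
#' b <- generate_core_block(11, 10, seed = 1)
#' table(b)
generate_core_block <- function(n_elements, n_sequences, min_gap = 2L,
                                seed = NULL, max_retries = 10000L) {
  n_elements <- as.integer(n_elements)
  n_sequences <- as.integer(n_sequences)
  min_gap <- as.integer(min_gap)
  if (n_elements <= min_gap) {
    abort(sprintf("infeasible: n_elements (%d) must exceed min_gap (%d)",
                  n_elements, min_gap))
  }
  if (n_sequences < 1) abort("`n_sequences` must be >= 1")
  with_seed_or_stream(seed, {
    out <- integer(0)
    for (s in seq_len(n_sequences)) {
      tries <- 0L
      repeat {
        perm <- sample.int(n_elements)
        ok <- TRUE
        if (length(out) && min_gap > 0) {
          L <- length(out)
          for (i in seq_len(min_gap)) {
            lo <- L - min_gap + i
            if (lo <= L && perm[i] %in% out[max(1L, lo):L]) { ok <- FALSE; break }
          }
        }
        if (ok) break
        tries <- tries + 1L
        if (tries >= max_retries) {
          abort(sprintf(
            "core-block generation exhausted %d retries at sequence %d (seed %s)",
            max_retries, s, if (is.null(seed)) "<stream>" else seed))
        }
      }
      out <- c(out, perm)
    }
    out
  })
}

#' Generate one copy-spelling trial schedule
#'
#' Produces the ordered intensification stream for a single trial: per
#' level, a prequel of one sequence-length of unconstrained uniform draws
#' (repeats allowed), the constrained core block
#' (see [generate_core_block()]), and a sequel like the prequel. Events are
#' annotated with onset (`index * soa_ms` from trial start, levels
#' concatenated), phase, core sequence number, and target status. For the
#' Hex-o-Spell, level 1 marks the target's group and level 2 — constructed
#' under offline copy-spelling semantics, i.e. assuming the correct group
#' was chosen — marks the target's disc among the six discs including the
#' empty backdoor.
#'
#' @param layout a [build_layout()] result.
#' @param target_symbol the trial's target (must be in the vocabulary).
#' @param timing a [timing_params()].
#' @param seed optional integer seed; the same seed reproduces the schedule
#'   bit-identically.
#' @return a `trial_schedule` tibble with columns `index`, `onset_ms`,
#'   `level`, `phase` (prequel/core/sequel), `sequence` (core sequence
#'   number, `NA` outside the core), `element_id`, `is_target`; layout
#'   kind, target, timing and seed attached as attributes.
#' @export
#' @examples
#' sched <- generate_trial_schedule(build_layout("matrix"), "B", seed = 7)
#' nrow(sched)  # 132
generate_trial_schedule <- function(layout, target_symbol,
                                    timing = timing_params(), seed = NULL) {
  stopifnot(inherits(layout, "speller_layout"))
  if (!target_symbol %in% layout$symbols) {
    abort(sprintf("target symbol '%s' is not in the layout vocabulary",
                  target_symbol))
  }
  seeds <- fan_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1),
                     layout$n_levels)
  per_level <- lapply(seq_len(layout$n_levels), function(lv) {
    els <- level_elements(layout, lv)
    n_el <- length(els)
    tgt <- target_elements(layout, target_symbol, lv)
    with_seed_or_stream(seeds[lv], {
      prequel <- sample.int(n_el, n_el, replace = TRUE)
      core <- generate_core_block(n_el, timing$n_sequences, 2L)
      sequel <- sample.int(n_el, n_el, replace = TRUE)
      idx <- c(prequel, core, sequel)
      phase <- rep(c("prequel", "core", "sequel"),
                   c(n_el, length(core), n_el))
      seqno <- rep(NA_integer_, length(idx))
      seqno[phase == "core"] <- rep(seq_len(timing$n_sequences), each = n_el)
      tibble(level = lv, phase = phase, sequence = seqno,
             element_id = els[idx],
             is_target = els[idx] %in% tgt)
    })
  })
  ev <- dplyr::bind_rows(per_level)
  ev <- dplyr::mutate(ev, index = dplyr::row_number(),
                      onset_ms = (.data$index - 1) * timing$soa_ms,
                      .before = 1)
  structure(
    ev,
    class = c("trial_schedule", class(ev)),
    layout_kind = layout$kind,
    target_symbol = target_symbol,
    timing = timing,
    rng_seed = seed
  )
}

#' Ground-truth target intensification count
#'
#' Number of target-bearing intensifications in a schedule — the quantity
#' participants silently count. Restricted to the core phase it is exactly
#' `2 * n_sequences` for both spellers; with prequel and sequel included it
#' varies from trial to trial.
#'
#' @param schedule a [generate_trial_schedule()] result.
#' @param phases phases to include (default all).
#' @return integer count.
#' @export
count_target_intensifications <- function(schedule,
                                          phases = c("prequel", "core",
                                                     "sequel")) {
  sum(schedule$is_target & schedule$phase %in% phases)
}

#' Map selected groups to a symbol
#'
#' Selection semantics of the two spellers: the Matrix returns the unique
#' symbol at the intersection of the chosen row and column; the Hex-o-Spell
#' returns the symbol at the chosen disc position of the chosen group, or a
#' backdoor flag (no symbol) when the empty disc is chosen.
#'
#' @param layout a [build_layout()] result.
#' @param selection character vector of chosen element ids: for the Matrix
#'   one row id and one column id (either order); for the Hex-o-Spell the
#'   level-1 group id followed by the level-2 disc id.
#' @return list with `symbol` (character or `NA`) and `backdoor` (logical).
#' @export
#' @examples
#' decode_selection(build_layout("matrix"), c("R1", "C2"))$symbol  # "B"
decode_selection <- function(layout, selection) {
  stopifnot(inherits(layout, "speller_layout"), length(selection) == 2L)
  if (layout$kind == "matrix") {
    row_id <- selection[startsWith(selection, "R")]
    col_id <- selection[startsWith(selection, "C")]
    if (length(row_id) != 1L || length(col_id) != 1L ||
        !row_id %in% names(layout$groups$level1) ||
        !col_id %in% names(layout$groups$level1)) {
      abort("matrix selection must be one valid row id and one column id")
    }
    sym <- intersect(layout$groups$level1[[row_id]],
                     layout$groups$level1[[col_id]])
    list(symbol = sym, backdoor = FALSE)
  } else {
    grp <- selection[1]; disc <- selection[2]
    if (!grp %in% names(layout$groups$level1) ||
        !disc %in% names(layout$groups$level2)) {
      abort("hex selection must be a valid group id and disc id")
    }
    pos <- match(disc, names(layout$groups$level2))
    if (pos == 6L) return(list(symbol = NA_character_, backdoor = TRUE))
    list(symbol = layout$groups$level1[[grp]][pos], backdoor = FALSE)
  }
}

#' Chance level of symbol selection
#'
#' Probability that independent uniform selection at every decision stage
#' yields the correct symbol: 1/6 x 1/5 = 1/30 for the Matrix and
#' 1/6 x 1/6 = 1/36 for the Hex-o-Spell (the empty backdoor disc counts as
#' a possible, always-incorrect choice).
#'
#' @param layout a [build_layout()] result.
#' @return probability in (0, 1].
#' @export
#' @examples
#' chance_level(build_layout("hex"))  # 1/36
chance_level <- function(layout) {
  stopifnot(inherits(layout, "speller_layout"))
  if (layout$kind == "matrix") {
    n_rows <- sum(startsWith(names(layout$groups$level1), "R"))
    n_cols <- sum(startsWith(names(layout$groups$level1), "C"))
    1 / (n_rows * n_cols)
  } else {
    prod(vapply(layout$groups, function(g) 1 / length(g), numeric(1)))
  }
}

#' Write / read a schedule event table
#'
#' Schedules are exchanged as tab-separated event tables with columns
#' `index`, `onset_ms`, `level`, `phase`, `sequence`, `element_id`,
#' `is_target`.
#'
#' @param schedule a `trial_schedule`.
#' @param path file path for the TSV.
#' @return `read_schedule()` returns a tibble (without layout attributes).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
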
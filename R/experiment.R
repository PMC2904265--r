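#' Experiment configuration
#'
#' Bundles every parameter of a simulated copy-spelling experiment. The
#' defaults reproduce the study design: both spellers crossed with both
#' attention modes, 3 blocks of 3 words of 5 letters per condition, 10
#' core sequences at a 166 ms SOA, 64-channel recordings at 1000 Hz,
#' classification at 100 Hz with 55 channels x 7 temporal windows, ERP
#' analysis at 250 Hz, training on block 1 and testing on the remaining
#' blocks. Reduced sizes (fewer words, lower simulation rate) are set
#' explicitly where desk-scale runs are wanted.
#'
#' @param spellers,attentions condition factors to cross.
#' @param n_blocks,words_per_block,word_length copy-spelling structure;
#'   each letter of each word is one trial.
#' @param timing a [timing_params()].
#' @param components list of [component_spec()]s.
#' @param noise a [noise_model()].
#' @param fs_sim generator sampling rate (Hz).
#' @param fs_classify,fs_erp analysis rates for the classification and ERP
#'   paths (must divide `fs_sim`).
#' @param n_temporal_windows,window_width_ms,min_separation_ms temporal
#'   feature heuristic parameters.
#' @param channels spatial feature subset.
#' @param gamma `"auto"` or fixed shrinkage intensity.
#' @param modulation_override optional [modulation_profile()] /
#'   [custom_modulation()] used for every condition instead of the
#'   attention-specific presets (e.g. a zero-modulation null profile).
#' @param train_block index of the training block.
#' @param do_erp run the ERP measurement path.
#' @param seed master seed; fans out to per-trial schedule and noise
#'   streams.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(spellers = c("matrix", "hex"),
                              attentions = c("overt", "covert"),
                              n_blocks = 3, words_per_block = 3,
                              word_length = 5,
                              timing = timing_params(),
                              components = default_components(),
                              noise = noise_model(),
                              fs_sim = 1000, fs_classify = 100,
                              fs_erp = 250,
                              n_temporal_windows = 7,
                              window_width_ms = 40,
                              min_separation_ms = 50,
                              channels = classification_channels(),
                              gamma = "auto", train_block = 1,
                              modulation_override = NULL,
                              do_erp = TRUE, seed = 1) {
  cfg <- list(spellers = spellers, attentions = attentions,
              n_blocks = as.integer(n_blocks),
              words_per_block = as.integer(words_per_block),
              word_length = as.integer(word_length),
              timing = timing, components = components, noise = noise,
              fs_sim = fs_sim, fs_classify = fs_classify, fs_erp = fs_erp,
              n_temporal_windows = n_temporal_windows,
              window_width_ms = window_width_ms,
              min_separation_ms = min_separation_ms,
              channels = channels, gamma = gamma,
              train_block = as.integer(train_block),
              modulation_override = modulation_override, do_erp = do_erp,
              seed = as.integer(seed))
  structure(cfg, class = "experiment_config")
}

#' Run a full simulated experiment
#'
#' For every condition (speller x attention): draws target-symbol
#' sequences, generates constrained schedules, synthesizes recordings with
#' the condition's modulation preset, extracts epochs, selects temporal
#' windows by point-biserial correlation on the training block, trains one
#' binary shrinkage-LDA classifier on the pooled training-block core
#' epochs, decodes every test trial for 1 ... `n_sequences` sequences, and
#' (optionally) runs the ERP path (250 Hz epochs, contamination filters,
#' per-condition averages, component measures and target-minus-nontarget
#' differences). Recordings are processed one trial at a time and
#' discarded, so memory stays bounded.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-condition progress.
#' @return an `experiment_result`: `accuracy` (an [accuracy_curve()] with
#'   `speller` and `attention` columns), `decoded` (per-trial outcomes),
#'   `models` (per condition: fitted model, selected windows, feature
#'   dimensionality), `erp_measures`, `erp_differences`, `config`,
#'   `provenance`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  conditions <- tidyr::expand_grid(speller = config$spellers,
                                   attention = config$attentions)
  cond_seeds <- fan_seeds(config$seed, nrow(conditions))
  decoded_all <- list(); models <- list(); measures_all <- list()
  for (ci in seq_len(nrow(conditions))) {
    sp <- conditions$speller[ci]; at <- conditions$attention[ci]
    if (verbose) message(sprintf("condition %s / %s", sp, at))
    res <- run_condition(sp, at, config, cond_seeds[ci])
    decoded_all[[ci]] <- dplyr::mutate(res$decoded, speller = sp,
                                       attention = at)
    models[[paste(sp, at, sep = ".")]] <- res$model_info
    if (config$do_erp) {
      measures_all[[ci]] <- dplyr::mutate(res$measures, speller = sp,
                                          attention = at)
    }
  }
  decoded <- dplyr::bind_rows(decoded_all)
  erp_measures <- if (config$do_erp) dplyr::bind_rows(measures_all) else NULL
  erp_differences <- if (config$do_erp) {
    dplyr::bind_rows(lapply(measures_all, function(m) {
      d <- difference_amplitude(m)
      d$speller <- m$speller[1]; d$attention <- m$attention[1]
      d
    }))
  } else NULL
  structure(
    list(accuracy = accuracy_curve(decoded, by = c("speller", "attention")),
         decoded = decoded, models = models,
         erp_measures = erp_measures, erp_differences = erp_differences,
         config = config,
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(config),
                           package_version =
                             as.character(utils::packageVersion("spellerbci")))),
    class = "experiment_result")
}

# one speller x attention condition
run_condition <- function(speller, attention, config, seed) {
  layout <- build_layout(speller)
  profile <- config$modulation_override %||%
    modulation_profile(attention, speller)
  n_trials <- config$n_blocks * config$words_per_block * config$word_length
  plan <- with_seed_or_stream(seed, tibble(
    trial = seq_len(n_trials),
    block = rep(seq_len(config$n_blocks),
                each = config$words_per_block * config$word_length),
    word = rep(rep(seq_len(config$words_per_block),
                   each = config$word_length), config$n_blocks),
    target = sample(layout$symbols, n_trials, replace = TRUE),
    sched_seed = sample.int(.Machine$integer.max - 1L, n_trials),
    noise_seed = sample.int(.Machine$integer.max - 1L, n_trials)
  ))

  erp_acc <- NULL
  simulate_trial <- function(row) {
    sched <- generate_trial_schedule(layout, row$target, config$timing,
                                     seed = row$sched_seed)
    rec <- synthesize_recording(sched, config$components, profile,
                                config$noise, fs = config$fs_sim,
                                seed = row$noise_seed)
    list(sched = sched, rec = rec)
  }
  erp_accumulate <- function(rec, sched) {
    rec_e <- resample_recording(rec, config$fs_erp)
    ep <- apply_epoch_filters(extract_epochs(rec_e), sched)
    kept <- ep$info$kept
    for (lab in c("target", "nontarget")) {
      ix <- which(kept & ep$info$label == lab)
      if (!length(ix)) next
      s <- colSums(ep$data[ix, , , drop = FALSE], dims = 1)
      if (is.null(erp_acc)) {
        erp_acc <<- list(times_ms = ep$times_ms, channels = ep$channels,
                         sums = list(), counts = c(target = 0,
                                                   nontarget = 0))
      }
      if (is.null(erp_acc$sums[[lab]])) {
        erp_acc$sums[[lab]] <<- s
      } else {
        erp_acc$sums[[lab]] <<- erp_acc$sums[[lab]] + s
      }
      erp_acc$counts[[lab]] <<- erp_acc$counts[[lab]] + length(ix)
    }
  }

  # --- training block ---
  train_rows <- which(plan$block == config$train_block)
  train_eps <- vector("list", length(train_rows))
  for (k in seq_along(train_rows)) {
    tr <- simulate_trial(plan[train_rows[k], ])
    rec_c <- resample_recording(tr$rec, config$fs_classify)
    ep <- extract_epochs(rec_c)
    train_eps[[k]] <- subset_epochs(ep, ep$info$phase == "core")
    if (config$do_erp) erp_accumulate(tr$rec, tr$sched)
  }
  train_ep <- bind_epochs(train_eps)
  rm(train_eps)
  pb <- point_biserial(train_ep)
  wins <- select_temporal_windows(pb, k = config$n_temporal_windows,
                                  width_ms = config$window_width_ms,
                                  min_separation_ms = config$min_separation_ms)
  spec <- feature_spec(config$channels, wins)
  feats <- build_features(train_ep, spec)
  model <- train_shrinkage_lda(feats$x, feats$y, gamma = config$gamma)
  rm(train_ep, feats)

  # --- test blocks ---
  test_rows <- which(plan$block != config$train_block)
  decoded <- list()
  for (k in seq_along(test_rows)) {
    row <- plan[test_rows[k], ]
    tr <- simulate_trial(row)
    rec_c <- resample_recording(tr$rec, config$fs_classify)
    ep <- extract_epochs(rec_c)
    ep <- subset_epochs(ep, ep$info$phase == "core")
    fx <- build_features(ep, spec)
    scores <- lda_score(model, fx$x)
    per_n <- purrr::map_dfr(seq_len(config$timing$n_sequences), function(n) {
      d <- decode_trial(scores, fx$info, layout, n)
      tibble(trial = row$trial, block = row$block, target = row$target,
             n_sequences = n, selected = d$symbol %||% NA_character_,
             backdoor = d$backdoor,
             correct = !d$backdoor && identical(d$symbol, row$target))
    })
    decoded[[k]] <- per_n
    if (config$do_erp) erp_accumulate(tr$rec, tr$sched)
  }

  measures <- NULL
  if (config$do_erp && !is.null(erp_acc)) {
    waveforms <- lapply(names(erp_acc$sums), function(lab) {
      erp_acc$sums[[lab]] / erp_acc$counts[[lab]]
    })
    names(waveforms) <- names(erp_acc$sums)
    avg <- structure(list(waveforms = waveforms,
                          counts = tibble(group = names(waveforms),
                                          n_epochs = as.integer(
                                            erp_acc$counts[names(waveforms)])),
                          times_ms = erp_acc$times_ms,
                          channels = erp_acc$channels),
                     class = "erp_average")
    measures <- measure_components(avg)
  }

  list(decoded = dplyr::bind_rows(decoded),
       model_info = list(model = model, windows = wins,
                         dimensionality = spec$dimensionality,
                         gamma = model$gamma),
       measures = measures)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>\n")
  top <- dplyr::filter(x$accuracy,
                       .data$n_sequences == max(.data$n_sequences))
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %s / %s: accuracy %.1f%% at %d sequences (%d trials)\n",
                top$speller[i], top$attention[i], 100 * top$accuracy[i],
                top$n_sequences[i], top$n_trials[i]))
  }
  invisible(x)
}

#' @method tidy experiment_result
#' @export
tidy.experiment_result <- function(x, ...) {
  as_tibble(x$accuracy)
}

#' @method glance experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  top <- dplyr::filter(x$accuracy,
                       .data$n_sequences == max(.data$n_sequences))
  tibble(
    n_conditions = nrow(top),
    max_sequences = max(x$accuracy$n_sequences),
    mean_final_accuracy = mean(top$accuracy),
    seed = x$provenance$seed
  )
}

#' @method autoplot experiment_result
#' @export
autoplot.experiment_result <- function(object, ...) {
  autoplot(object$accuracy) +
    ggplot2::facet_wrap(~speller)
}
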
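#' Component analysis windows
#'
#' Latency windows and polarities used for peak picking: P1 80-150, N1
#' 150-230, P2 210-290, N2 280-360, P3 350-440 ms.
#'
#' @return tibble with columns `component`, `start_ms`, `end_ms`,
#'   `polarity`.
#' @export
component_windows <- function() {
  tibble(
    component = c("P1", "N1", "P2", "N2", "P3"),
    start_ms = c(80, 150, 210, 280, 350),
    end_ms = c(150, 230, 290, 360, 440),
    polarity = c(1, -1, 1, -1, 1)
  )
}

#' Electrode subsets for component statistics
#'
#' Parieto-occipital electrodes (P5, P6, PO7, PO8) for P1, N1 and N2;
#' midline electrodes (Fz, Cz, Pz) for P2 and P3.
#'
#' @return named list: `posterior`, `midline`, and `by_component` mapping
#'   each component to its subset name.
#' @export
electrode_subsets <- function() {
  list(
    posterior = c("P5", "P6", "PO7", "PO8"),
    midline = c("Fz", "Cz", "Pz"),
    by_component = c(P1 = "posterior", N1 = "posterior", P2 = "midline",
                     N2 = "posterior", P3 = "midline")
  )
}

#' Average epochs into ERPs
#'
#' Arithmetic mean over kept epochs, grouped by `info` columns (default:
#' target vs nontarget). Groups without kept epochs are flagged and
#' omitted.
#'
#' @param epochs an `epoch_set`.
#' @param by character vector of `info` column names to group by.
#' @return an `erp_average`: `waveforms` (named list of channels x time
#'   matrices), `counts` (tibble of group sizes), `times_ms`, `channels`.
#' @export
average_erp <- function(epochs, by = "label") {
  info <- epochs$info
  kept <- which(info$kept)
  if (length(kept) == 0) abort("no kept epochs to average")
  key <- do.call(paste, c(info[kept, by, drop = FALSE], sep = "."))
  groups <- split(kept, key)
  waveforms <- lapply(groups, function(ix) {
    m <- apply(epochs$data[ix, , , drop = FALSE], c(2, 3), mean)
    dimnames(m) <- list(epochs$channels, NULL)
    m
  })
  counts <- tibble(group = names(groups),
                   n_epochs = unname(vapply(groups, length, integer(1))))
  structure(list(waveforms = waveforms, counts = counts,
                 times_ms = epochs$times_ms, channels = epochs$channels),
            class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat("<erp_average>", paste(sprintf("%s (n=%d)", x$counts$group,
                                     x$counts$n_epochs), collapse = ", "),
      "\n")
  invisible(x)
}

#' Measure one ERP component on a waveform
#'
#' Picks the largest peak of the component's polarity among strict 3-point
#' local extrema inside the component window (window endpoints are not
#' peaks). When no local extremum of the correct polarity exists, the mean
#' amplitude over the window is returned instead
#' (`method = "mean_fallback"`) and no latency is reported.
#'
#' @param waveform numeric vector over time (one channel of an averaged
#'   ERP, in microvolts).
#' @param times_ms matching time axis.
#' @param component component name ("P1" ... "P3").
#' @param windows a [component_windows()] table.
#' @return one-row tibble: `component`, `amplitude_uV` (signed),
#'   `latency_ms` (`NA` under fallback), `method`.
#' @export
extract_component <- function(waveform, times_ms, component,
                              windows = component_windows()) {
  w <- windows[windows$component == component, ]
  if (nrow(w) != 1) abort(sprintf("unknown component '%s'", component))
  if (w$start_ms < min(times_ms) || w$end_ms > max(times_ms)) {
    abort("component window lies outside the epoch time range")
  }
  sel <- which(times_ms >= w$start_ms & times_ms <= w$end_ms)
  seg <- waveform[sel]
  cand <- local_maxima(w$polarity * seg)
  if (length(cand) == 0) {
    return(tibble(component = component, amplitude_uV = mean(seg),
                  latency_ms = NA_real_, method = "mean_fallback"))
  }
  best <- cand[which.max(w$polarity * seg[cand])]
  tibble(component = component, amplitude_uV = seg[best],
         latency_ms = times_ms[sel[best]], method = "peak")
}

#' Component measures over conditions and electrodes
#'
#' Applies [extract_component()] to each per-condition average waveform at
#' each electrode of the component's designated subset, producing the tidy
#' long table used for downstream statistics.
#'
#' @param avg an [average_erp()] result (groups typically target /
#'   nontarget, possibly crossed with condition keys).
#' @param windows a [component_windows()] table.
#' @param subsets an [electrode_subsets()] list.
#' @return tibble: `group`, `component`, `electrode`, `amplitude_uV`,
#'   `latency_ms`, `method`.
#' @export
measure_components <- function(avg, windows = component_windows(),
                               subsets = electrode_subsets()) {
  purrr::map_dfr(names(avg$waveforms), function(g) {
    wf <- avg$waveforms[[g]]
    purrr::map_dfr(windows$component, function(comp) {
      electrodes <- subsets[[subsets$by_component[[comp]]]]
      electrodes <- intersect(electrodes, avg$channels)
      purrr::map_dfr(electrodes, function(el) {
        dplyr::mutate(
          extract_component(wf[el, ], avg$times_ms, comp, windows),
          group = g, electrode = el, .before = 1)
      })
    })
  })
}

#' Target-minus-nontarget difference amplitudes
#'
#' Signed difference of component amplitude between target and nontarget
#' measures sharing component and electrode — the magnitude of attentional
#' modulation.
#'
#' @param measures a [measure_components()] table whose `group` column is
#'   `"target"` / `"nontarget"` (possibly prefixed by condition keys
#'   separated with a dot, e.g. `"covert.hex.target"`).
#' @return tibble: condition keys (if any), `component`, `electrode`,
#'   `difference_uV`.
#' @export
difference_amplitude <- function(measures) {
  m <- dplyr::mutate(
    measures,
    status = ifelse(grepl("(^|\\.)target$", .data$group), "target",
                    ifelse(grepl("(^|\\.)nontarget$", .data$group),
                           "nontarget", NA_character_)),
    condition = sub("(^|\\.)(non)?target$", "", .data$group)
  )
  if (any(is.na(m$status))) {
    abort("`group` values must end in 'target' or 'nontarget'")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(m, "condition", "component", "electrode", "status",
                  "amplitude_uV"),
    names_from = "status", values_from = "amplitude_uV")
  if (any(is.na(wide$target)) || any(is.na(wide$nontarget))) {
    abort("unmatched target/nontarget measures")
  }
  dplyr::mutate(wide, difference_uV = .data$target - .data$nontarget)
}

#' Plot averaged ERPs at selected electrodes
#'
#' @param object an `erp_average`.
#' @param channels electrodes to show (default Cz, Pz, PO7, PO8).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot erp_average
#' @export
autoplot.erp_average <- function(object, channels = c("Cz", "Pz", "PO7",
                                                      "PO8"), ...) {
  channels <- intersect(channels, object$channels)
  df <- purrr::map_dfr(names(object$waveforms), function(g) {
    purrr::map_dfr(channels, function(ch) {
      tibble(group = g, channel = ch, time_ms = object$times_ms,
             amplitude_uV = object$waveforms[[g]][ch, ])
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude_uV,
                                   color = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (uV)", color = NULL)
}
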
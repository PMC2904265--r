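#' Standard 64-channel 10-10 montage
#'
#' Channel labels of the 64-electrode actiCAP-style montage (international
#' 10-10 system) used by the synthetic-EEG generator, together with an
#' approximate planar layout used for component topographies and spatial
#' noise mixing.
#'
#' The planar layout places each electrode on a coarse grid derived from its
#' label: the letter prefix gives the anterior-posterior row (Fp through O)
#' and the digit gives the lateral position (odd = left, even = right,
#' z = midline). It is a schematic layout, not measured 10-10 coordinates;
#' it only needs to order neighbours sensibly.
#'
#' @return `montage_labels()` returns a character vector of 64 labels;
#'   `montage_coordinates()` returns a tibble with columns `channel`, `x`
#'   (lateral, left negative) and `y` (anterior positive).
#' @export
#' @examples
#' length(montage_labels())
montage_labels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8")
}

# row rank per label prefix (anterior = small)
.montage_rows <- c(Fp = 1, AF = 2, F = 3, FT = 4, FC = 4, T = 5, C = 5,
                   TP = 6, CP = 6, P = 7, PO = 8, O = 9)

#' @rdname montage_labels
#' @export
montage_coordinates <- function() {
  labs <- montage_labels()
  prefix <- sub("[0-9z]+$", "", labs)
  suffix <- substr(labs, nchar(prefix) + 1L, nchar(labs))
  lat <- vapply(suffix, function(s) {
    if (s == "z") return(0)
    d <- as.integer(s)
    side <- if (d %% 2 == 1) -1 else 1
    side * ceiling(d / 2)
  }, numeric(1))
  tibble(
    channel = labs,
    x = unname(lat),
    y = -unname(.montage_rows[prefix])
  )
}

# pairwise distances between channels in the schematic layout
montage_distance <- function(channels = montage_labels()) {
  co <- montage_coordinates()
  co <- co[match(channels, co$channel), ]
  as.matrix(stats::dist(cbind(co$x, co$y)))
}

#' Smooth scalp topography around peak electrodes
#'
#' Builds a per-channel weight vector that is 1 at the given peak
#' electrode(s) and falls off as a Gaussian of the schematic inter-electrode
#' distance, emulating e.g. a parieto-occipital or midline-central component
#' distribution.
#'
#' @param peaks character vector of peak electrode labels.
#' @param channels montage labels to evaluate on.
#' @param falloff Gaussian standard deviation in grid units (default 1.5).
#' @return named numeric vector over `channels`, maximum 1.
#' @export
#' @examples
#' w <- scalp_topography(c("PO7", "PO8"))
#' names(which.max(w))
scalp_topography <- function(peaks, channels = montage_labels(),
                             falloff = 1.5) {
  if (!all(peaks %in% channels)) {
    abort("all `peaks` must be montage channel labels")
  }
  d <- montage_distance(channels)
  w <- apply(d[, match(peaks, channels), drop = FALSE], 1,
             function(di) max(exp(-di^2 / (2 * falloff^2))))
  names(w) <- channels
  w / max(w)
}

#' Default 55-channel classification subset
#'
#' The montage minus a 9-channel frontopolar / far-periphery ring
#' (Fp1, Fp2, AF7, AF8, FT9, FT10, TP9, TP10, PO9), giving the default 55
#' spatial features. The exact subset is a configuration choice.
#'
#' @return character vector of 55 channel labels.
#' @export
classification_channels <- function() {
  drop <- c("Fp1", "Fp2", "AF7", "AF8", "FT9", "FT10", "TP9", "TP10", "PO9")
  setdiff(montage_labels(), drop)
}
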
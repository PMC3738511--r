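#' Spot-level intensity and presence filtering
#'
#' Two filters are applied before the log transform, mirroring standard
#' two-color array practice: (i) any channel value below the array
#' background level is set to missing, and (ii) spots observed on too few
#' sample-channels are dropped entirely.
#'
#' Presence is counted per sample-channel by default (a 12-plex two-channel
#' slide carries 24 sample-channels, so the default `min_present = 20`
#' reads as "present on at least 20 of 24"); set `presence = "arrays"` to
#' instead count arrays on which both channels are non-missing.
#'
#' @param raw long-format intensity data frame (`spot`, `array`, `dye`,
#'   `intensity`) as returned by [read_intensities()] or
#'   [generate_experiment()].
#' @param design the companion [array_design].
#' @param min_intensity background level; channel values strictly below it
#'   become missing (default 300).
#' @param min_present minimum number of present units for a spot to be kept
#'   (default 20).
#' @param presence unit in which presence is counted: `"channels"`
#'   (default) or `"arrays"`.
#' @return list with elements `intensities` (filtered long data frame, spots
#'   failing the presence rule removed) and `report` (a `filter_report`).
#' @export
filter_spots <- function(raw, design, min_intensity = 300, min_present = 20,
                         presence = c("channels", "arrays")) {
  presence <- match.arg(presence)
  stopifnot(inherits(design, "array_design"))
  if (min_intensity < 0) stop("min_intensity must be non-negative")
  if (min_present < 0) stop("min_present must be non-negative")
  x <- raw
  low <- !is.na(x$intensity) & x$intensity < min_intensity
  x$intensity[low] <- NA_real_

  present <- !is.na(x$intensity)
  if (presence == "channels") {
    n_present <- tapply(present, x$spot, sum)
  } else {
    both <- tapply(present, list(x$spot, x$array), sum)
    n_present <- rowSums(both == 2L, na.rm = TRUE)
  }
  keep_spots <- names(n_present)[n_present >= min_present]
  spots_in <- unique(x$spot)
  removed <- setdiff(spots_in, keep_spots)
  out <- x[x$spot %in% keep_spots, , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(
    list(n_spots_in = length(spots_in),
         n_low_intensity_cells = sum(low),
         n_spots_removed_presence = length(removed),
         n_spots_out = length(spots_in) - length(removed),
         min_intensity = min_intensity,
         min_present = min_present,
         presence = presence,
         n_arrays = design$n_arrays),
    class = "filter_report")
  list(intensities = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_spots_in, "spots in;",
      x$n_low_intensity_cells, "cells <", x$min_intensity, "set missing;",
      x$n_spots_removed_presence, "spots removed by presence <",
      x$min_present, paste0("(", x$presence, ");"),
      x$n_spots_out, "spots out\n")
  invisible(x)
}

#' Log2-transform filtered intensities
#'
#' @param filtered long-format intensity data frame with all non-missing
#'   values strictly positive (guaranteed by [filter_spots()] with a
#'   positive background level).
#' @return the same data frame with `intensity` replaced by a `value` column
#'   of log2 intensities; missing cells stay missing.
#' @export
log2_transform <- function(filtered) {
  stopifnot("intensity" %in% names(filtered))
  bad <- !is.na(filtered$intensity) & filtered$intensity <= 0
  if (any(bad))
    stop("non-positive intensity reached the log transform; ",
         "run filter_spots() with a positive background level first")
  out <- filtered
  out$value <- log2(out$intensity)
  out$intensity <- NULL
  out
}
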
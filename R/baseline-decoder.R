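#' Grid layout for classical cell-wise decoding
#'
#' Describes where the decoder samples a registered code raster: the cell
#' grid of an imaging geometry plus an interior window fraction. The
#' interior window (default half the cell pitch, centred) avoids edge
#' roughness and jitter contamination at the cell borders.
#'
#' @param config an `imaging_config`; geometry is shared with the
#'   generator.
#' @param interior_fraction fraction of the cell pitch sampled, in
#'   (0, 1].
#' @return A `grid_layout`.
#' @export
grid_layout <- function(config = imaging_config(), interior_fraction = 0.5) {
  stopifnot(interior_fraction > 0, interior_fraction <= 1)
  geom <- grid_geometry(config)
  structure(list(n = config$n, canvas = config$canvas,
                 centers_r = geom$centers_r, centers_c = geom$centers_c,
                 pitch = geom$pitch,
                 interior_fraction = interior_fraction,
                 background_level = config$background_level,
                 fill_lo = config$fill_intensity_range[1]),
            class = "grid_layout")
}

#' Mean interior intensity of every grid cell
#'
#' @param raster grayscale matrix.
#' @param layout a `grid_layout` fitting the raster.
#' @return Numeric vector of n^2 means in row-major cell order.
#' @export
grid_cell_stats <- function(raster, layout) {
  if (nrow(raster) != layout$canvas[1] || ncol(raster) != layout$canvas[2])
    stop("raster is ", nrow(raster), " x ", ncol(raster),
         " but layout expects ", layout$canvas[1], " x ", layout$canvas[2])
  hw_r <- layout$pitch[1] * layout$interior_fraction / 2
  hw_c <- layout$pitch[2] * layout$interior_fraction / 2
  n <- layout$n
  stats <- numeric(n * n)
  k <- 0L
  for (r in seq_len(n)) {
    ri <- max(1L, round(layout$centers_r[r] - hw_r)):
          min(nrow(raster), round(layout$centers_r[r] + hw_r))
    for (cc in seq_len(n)) {
      ci <- max(1L, round(layout$centers_c[cc] - hw_c)):
            min(ncol(raster), round(layout$centers_c[cc] + hw_c))
      k <- k + 1L
      stats[k] <- mean(raster[ri, ci])
    }
  }
  stats
}

# Otsu separation point over a small sample of values: exhaustive search
# of the between-class variance over midpoints of the sorted values.
otsu_split <- function(x) {
  xs <- sort(x)
  if (diff(range(xs)) < .Machine$double.eps^0.5) return(NA_real_)
  best <- -Inf; thr <- NA_real_
  for (i in seq_len(length(xs) - 1L)) {
    if (xs[i] == xs[i + 1]) next
    t0 <- (xs[i] + xs[i + 1]) / 2
    lo <- xs[xs <= t0]; hi <- xs[xs > t0]
    bcv <- length(lo) * length(hi) * (mean(hi) - mean(lo))^2
    if (bcv > best) { best <- bcv; thr <- t0 }
  }
  thr
}

#' Threshold per-cell statistics into a binary channel key
#'
#' Bit i is 1 iff the cell's interior mean exceeds the threshold; ties
#' resolve to 0 (conservative for authentication: prefer a failed match
#' over a false accept). `method = "fixed"` uses the supplied threshold;
#' `"otsu"` finds the two-class separation point of the n^2 means and is
#' invariant under affine intensity rescaling. Degenerate all-equal
#' statistics under `"otsu"` decode to all zeros with a warning (no
#' signal present).
#'
#' @param stats numeric vector of n^2 interior means.
#' @param channel which fluorescence channel the raster came from.
#' @param method `"fixed"` or `"otsu"`.
#' @param threshold numeric threshold for `method = "fixed"`.
#' @return A `channel_key`.
#' @export
threshold_decode <- function(stats, channel = "ECFP",
                             method = c("fixed", "otsu"), threshold = NULL) {
  method <- match.arg(method)
  thr <- switch(method,
    fixed = {
      if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
      threshold
    },
    otsu = otsu_split(stats))
  if (is.na(thr)) {
    warning("degenerate all-equal cell statistics: no signal, decoding to zeros")
    return(channel_key(channel, integer(length(stats))))
  }
  channel_key(channel, as.integer(stats > thr))
}

#' Decode one channel raster with the classical reader
#'
#' Convenience wrapper: [grid_cell_stats()] then [threshold_decode()].
#' The default fixed threshold is the midpoint between the background
#' level and the low end of the filled-unit intensity range — the
#' generator-consistency oracle: on noiseless rendered codes it recovers
#' the truth key exactly.
#'
#' @param raster grayscale matrix.
#' @param layout a `grid_layout`.
#' @param channel channel label for the resulting key.
#' @inheritParams threshold_decode
#' @return A `channel_key`.
#' @export
baseline_decode <- function(raster, layout, channel = "ECFP",
                            method = c("fixed", "otsu"), threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(threshold))
    threshold <- layout$background_level + 0.5 * layout$fill_lo  # midpoint
  threshold_decode(grid_cell_stats(raster, layout), channel = channel,
                   method = method, threshold = threshold)
}

#' Decode all three channels of a code image set
#'
#' @param image_set a `code_image_set`.
#' @param layout a `grid_layout`.
#' @inheritParams threshold_decode
#' @return A `digitized_key`.
#' @export
baseline_decode_set <- function(image_set, layout,
                                method = c("fixed", "otsu"), threshold = NULL) {
  keys <- lapply(channel_order, function(ch)
    baseline_decode(image_set$channels[[ch]], layout, channel = ch,
                    method = method, threshold = threshold))
  concat_key(keys[[1]], keys[[2]], keys[[3]])
}
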
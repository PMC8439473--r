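# Spatial feature maps, torn-region QC, frequency distributions.

# fixed display scales matching the published images; values outside the
# range are saturated in renderings but preserved in the data
DISPLAY_RANGES <- list(diag_ratio = c(0.8, 1.2),
                       xpeak_intensity = c(0, 0.1),
                       peak_freq = c(1600, 1660),
                       anharm = c(5, 20))

FEATURE_NAMES <- names(DISPLAY_RANGES)

#' Estimate the per-cube QC floor
#'
#' Five times the robust noise estimate (median absolute deviation of the
#' signal-free low-frequency corner of every pixel's grid), with a small
#' absolute lower bound so that exactly-zero torn pixels fail even in
#' noiseless simulations.
#'
#' @param cube A \code{TissueCube}.
#' @param mult Floor multiplier (default 5).
#' @return Scalar QC floor in amplitude units.
#' @export
cube_qc_floor <- function(cube, mult = 5) {
  n <- min(6L, dim(cube$amplitude)[3], dim(cube$amplitude)[4])
  corner <- cube$amplitude[, , seq_len(n), seq_len(n)]
  max(mult * stats::mad(as.numeric(corner), center = 0), 1e-8)
}

# raw diagonal intensity at the class normalization frequency, per pixel
raw_norm_intensity <- function(cube, sample_class = NULL) {
  sample_class <- sample_class %||% cube$meta$sample_class
  nf <- normalization_frequency(sample_class)
  i <- nearest_index(cube$pump_axis, nf)
  j <- nearest_index(cube$probe_axis, nf)
  if (is.na(i) || is.na(j)) stop("normalization frequency outside the axes")
  cube$amplitude[, , i, j]
}

#' Reject torn (signal-void) tissue regions
#'
#' A pixel is rejected when its raw diagonal amplitude at the class
#' normalization frequency falls below the QC floor, or when it lies
#' outside the lens mask. Contiguity is not required.
#'
#' @param cube A \code{TissueCube}.
#' @param qc_floor QC floor (default \code{\link{cube_qc_floor}(cube)}).
#' @param sample_class Sample class (default from cube metadata).
#' @return Logical usability mask (TRUE = usable).
#' @export
reject_torn_regions <- function(cube, qc_floor = NULL, sample_class = NULL) {
  if (sum(dim(cube$amplitude)[1:2]) == 0) stop("empty cube")
  qc_floor <- qc_floor %||% cube_qc_floor(cube)
  keep <- raw_norm_intensity(cube, sample_class) > qc_floor
  keep & cube$mask
}

#' Build a spatial feature map from a tissue cube
#'
#' Computes one feature per usable pixel and assembles the spatial map with
#' its QC mask (lens mask combined with per-pixel QC flags) and the fixed
#' display range for that feature.
#'
#' @param cube A \code{TissueCube}.
#' @param feature One of \code{"diag_ratio"}, \code{"xpeak_intensity"},
#'   \code{"peak_freq"}, \code{"anharm"}.
#' @param params List of overrides: \code{sample_class},
#'   \code{probe_freq}, \code{pump_freq}, \code{qc_floor}.
#' @return Object of class \code{FeatureMap}: \code{values} (matrix, NA
#'   where unusable), \code{qc_mask}, \code{feature_name},
#'   \code{display_range}.
#' @export
build_feature_map <- function(cube, feature, params = list()) {
  feature <- match.arg(feature, FEATURE_NAMES)
  sample_class <- params$sample_class %||% cube$meta$sample_class
  host <- cube$meta$host %||% "mouse"
  xp_default <- HOST_XPEAK[[host]]
  probe_freq <- params$probe_freq %||% unname(xp_default[["probe"]])
  pump_freq <- params$pump_freq %||% unname(xp_default[["pump"]])
  qc_floor <- params$qc_floor %||% cube_qc_floor(cube)
  nx <- dim(cube$amplitude)[1]; ny <- dim(cube$amplitude)[2]
  values <- matrix(NA_real_, nx, ny)
  qc <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!cube$mask[i, j]) next
    pf <- pixel_features(cube_pixel(cube, i, j), sample_class,
                         probe_freq = probe_freq, pump_freq = pump_freq,
                         qc_floor = qc_floor)
    if (isTRUE(pf$qc_flag)) next
    values[i, j] <- pf[[feature]]
    qc[i, j] <- is.finite(values[i, j])
  }
  if (!any(qc)) stop("no usable pixels in cube")
  structure(list(values = values, qc_mask = qc, feature_name = feature,
                 display_range = DISPLAY_RANGES[[feature]]),
            class = "FeatureMap")
}

#' @export
print.FeatureMap <- function(x, ...) {
  cat(sprintf("<FeatureMap %s %dx%d, %d usable px, display [%g, %g]>\n",
              x$feature_name, nrow(x$values), ncol(x$values),
              sum(x$qc_mask), x$display_range[1], x$display_range[2]))
  invisible(x)
}

#' Percent-of-locations frequency histogram
#'
#' Histogram of per-pixel peak frequencies over usable pixels, expressed as
#' percent of measured locations per bin (summing to 100); bins aligned to
#' the probe grid pitch.
#'
#' @param map A peak-frequency \code{FeatureMap} (or any map whose values
#'   are frequencies).
#' @param bin_width Bin width in cm^-1 (default the 2.5 cm^-1 probe pitch).
#' @return Object of class \code{FrequencyHistogram}: \code{bin_edges},
#'   \code{percent_of_locations}.
#' @export
frequency_histogram <- function(map, bin_width = PROBE_RESOLUTION) {
  v <- map$values[map$qc_mask]
  v <- v[is.finite(v)]
  if (!length(v)) stop("no usable pixels for histogram")
  # bins centred on the probe grid (1580 + k*pitch)
  anchor <- 1580 - bin_width / 2
  lo <- anchor + floor((min(v) - anchor) / bin_width) * bin_width
  hi <- anchor + ceiling((max(v) - anchor) / bin_width + 1e-12) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2L) edges <- c(lo, lo + bin_width)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(list(bin_edges = edges,
                 percent_of_locations = 100 * counts / sum(counts)),
            class = "FrequencyHistogram")
}

#' Per-pixel feature table for a cube
#'
#' Runs the full feature set over every lens pixel and returns the
#' tab-separable data-of-record table.
#'
#' @param cube A \code{TissueCube}.
#' @param params Overrides passed to \code{\link{pixel_features}} (see
#'   \code{\link{build_feature_map}}).
#' @return Data frame with columns \code{pixel_x}, \code{pixel_y},
#'   \code{diag_ratio}, \code{xpeak_intensity}, \code{peak_freq},
#'   \code{anharm}, \code{qc_flag}.
#' @export
feature_table <- function(cube, params = list()) {
  sample_class <- params$sample_class %||% cube$meta$sample_class
  host <- cube$meta$host %||% "mouse"
  xp_default <- HOST_XPEAK[[host]]
  probe_freq <- params$probe_freq %||% unname(xp_default[["probe"]])
  pump_freq <- params$pump_freq %||% unname(xp_default[["pump"]])
  qc_floor <- params$qc_floor %||% cube_qc_floor(cube)
  nx <- dim(cube$amplitude)[1]; ny <- dim(cube$amplitude)[2]
  rows <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!cube$mask[i, j]) next
    pf <- pixel_features(cube_pixel(cube, i, j), sample_class,
                         probe_freq = probe_freq, pump_freq = pump_freq,
                         qc_floor = qc_floor)
    rows[[length(rows) + 1L]] <-
      data.frame(pixel_x = i, pixel_y = j, diag_ratio = pf$diag_ratio,
                 xpeak_intensity = pf$xpeak_intensity,
                 peak_freq = pf$peak_freq, anharm = pf$anharm,
                 qc_flag = pf$qc_flag)
  }
  do.call(rbind, rows)
}
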
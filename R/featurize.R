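#' Featurize a set of recordings into spatial-spectral maps
#'
#' Runs the full representation pipeline: each recording is segmented into
#' non-overlapping `window_s`-second windows, each window is summarised as
#' per-electrode band power over `bands`, and each band-power table is
#' scattered onto the layout grid. The output has one map per window,
#' `sum(floor(T_rec / (window_s * fs)))` in total.
#'
#' @param recordings List of [raw_recording()] objects with identical
#'   channel label sets.
#' @param bands Band definition table (default [eeg_bands()]).
#' @param layout An [electrode_layout()]; defaults to the packaged
#'   62-channel layout at 32 x 32.
#' @param window_s Segmentation window in seconds.
#' @param psd Band-power method, `"welch"` or `"mean_square"`.
#' @param log10 If `TRUE`, powers are log10-transformed (a small floor of
#'   1e-30 guards exact zeros) before mapping.
#' @param standardize If `TRUE`, standardize each (cell, band) feature to
#'   zero mean / unit variance. Statistics are computed over these maps
#'   (intended to be the training split) unless `stats` is supplied, in
#'   which case they are reused (e.g. for a test split).
#' @param stats Optional standardization statistics (attribute
#'   `"standardization"` of a previous call).
#' @param mode Cell-fill mode passed to [build_spatial_spectral()].
#' @return List of `spatial_spectral_map` objects; if standardized, the
#'   list carries a `"standardization"` attribute (`list(mean, sd)`).
#' @export
featurize_dataset <- function(recordings, bands = eeg_bands(),
                              layout = electrode_layout(),
                              window_s = 4, psd = c("welch", "mean_square"),
                              log10 = FALSE, standardize = FALSE, stats = NULL,
                              mode = "scatter") {
  psd <- match.arg(psd)
  if (length(recordings) == 0L) return(list())
  ref <- sort(recordings[[1L]]$channel_labels)
  for (r in recordings)
    if (!identical(sort(r$channel_labels), ref))
      stop("featurize_dataset: heterogeneous channel label sets across recordings")
  maps <- list()
  for (rec in recordings) {
    for (seg in segment_recording(rec, window_s)) {
      bp <- band_power_table(seg, bands, method = psd)
      if (log10) bp <- log10(pmax(bp, 1e-30))
      m <- build_spatial_spectral(bp, layout, mode = mode, label = rec$label)
      attr(m, "subject") <- rec$subject
      maps[[length(maps) + 1L]] <- m
    }
  }
  if (standardize) {
    flat <- vapply(maps, as.numeric, numeric(length(maps[[1L]])))  # cells x N
    if (is.null(stats)) {
      mu <- rowMeans(flat)
      sd <- apply(flat, 1L, stats::sd)
      stats <- list(mean = mu, sd = sd)
    }
    sd_safe <- ifelse(stats$sd > 0, stats$sd, 1)
    maps <- lapply(maps, function(m) {
      z <- (as.numeric(m) - stats$mean) / sd_safe
      out <- array(z, dim(m))
      attributes(out)[c("label", "subject", "layout_version", "class")] <-
        attributes(m)[c("label", "subject", "layout_version", "class")]
      out
    })
    attr(maps, "standardization") <- stats
  }
  maps
}

#' Labels of a list of spatial-spectral maps
#' @param maps List of `spatial_spectral_map` objects.
#' @return Integer vector of class labels.
#' @export
map_labels <- function(maps)
  vapply(maps, function(m) as.integer(attr(m, "label")), integer(1))

#' Subjects of a list of spatial-spectral maps
#' @param maps List of `spatial_spectral_map` objects.
#' @return Vector of subject identifiers (NA where absent).
#' @export
map_subjects <- function(maps)
  sapply(maps, function(m) {
    s <- attr(m, "subject"); if (is.null(s)) NA else s
  })
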
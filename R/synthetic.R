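#' Specification for synthetic emotion-EEG data
#'
#' Describes a synthetic dataset with the structure of 62-channel,
#' 200 Hz emotion recordings: 1/f-shaped background noise on every channel
#' (10 uV RMS) plus, per class, an amplitude-modulated oscillation inside a
#' class-specific frequency band on a class-specific electrode group, at a
#' chosen signal-to-background band-power ratio.
#'
#' Default class assignments: class 0 - alpha over frontal electrodes,
#' class 1 - beta over temporal, class 2 - gamma over occipital, class 3
#' (4-class setups) - theta over central.
#'
#' @param n_classes 3 or 4 emotion classes.
#' @param n_subjects Number of subjects.
#' @param trials_per_class Trials per class per subject.
#' @param duration_s Trial duration in seconds.
#' @param fs Sampling rate (Hz).
#' @param snr Ratio of class-signal band power to background power in the
#'   same band (> 0).
#' @param seed Integer seed; every derived quantity is deterministic in it.
#' @param target_bands Optional character vector naming one band per class.
#' @param target_groups Optional list of electrode label subsets per class.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3, n_subjects = 1, trials_per_class = 10,
                           duration_s = 8, fs = 200, snr = 10, seed = 1L,
                           target_bands = NULL, target_groups = NULL) {
  stopifnot(n_classes %in% 2:5, snr > 0, duration_s > 0, fs > 0)
  ch <- eeg_channels_62()
  groups <- list(
    frontal   = ch[grepl("^(FP|AF|F[0-9Z])", ch)],
    temporal  = ch[grepl("^(FT|T[78]|TP)", ch)],
    occipital = ch[grepl("^(O|PO|CB)", ch)],
    central   = ch[grepl("^(C[0-9Z]|FC|CP)", ch)])
  if (is.null(target_bands)) target_bands <- c("alpha", "beta", "gamma", "theta", "delta")[seq_len(n_classes)]
  if (is.null(target_groups)) target_groups <- unname(groups[c(1, 2, 3, 4, 1)[seq_len(n_classes)]])
  bands <- eeg_bands()
  if (!all(target_bands %in% bands$name))
    stop("synthetic_spec: target bands must be drawn from the five canonical bands")
  for (b in target_bands)
    if (bands$hi[bands$name == b] >= fs / 2)
      stop("synthetic_spec: target band ", b, " exceeds the Nyquist frequency")
  structure(list(n_classes = n_classes, n_subjects = n_subjects,
                 trials_per_class = trials_per_class, duration_s = duration_s,
                 fs = fs, n_channels = 62L, snr = snr, seed = as.integer(seed),
                 target_bands = target_bands, target_groups = target_groups),
            class = "synthetic_spec")
}

# 1/f-shaped noise, length n, unit RMS: white Gaussian spectrum scaled by
# 1/sqrt(f) (power ~ 1/f) and inverse-transformed.
pink_noise <- function(n) {
  nf <- (n - 1L) %/% 2L
  amp <- 1 / sqrt(seq_len(nf))
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  full <- complex(length.out = n)
  if (nf > 0L) {
    full[2L:(nf + 1L)] <- spec
    full[n:(n - nf + 1L)] <- Conj(spec)
  }
  if (n %% 2L == 0L) full[n %/% 2L + 1L] <- stats::rnorm(1) / sqrt(n / 2)
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one synthetic EEG trial
#'
#' @param spec A [synthetic_spec()].
#' @param class_id Class index in `0:(n_classes-1)`.
#' @param seed Seed for this trial (defaults to `spec$seed`).
#' @param subject,session Identifiers stamped on the recording.
#' @return A [raw_recording()] labelled `class_id`.
#' @export
generate_recording <- function(spec, class_id, seed = spec$seed,
                               subject = 1L, session = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"),
            class_id >= 0, class_id < spec$n_classes)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  n <- round(spec$duration_s * spec$fs)
  ch <- eeg_channels_62()
  bg_rms <- 10                      # microvolts
  x <- matrix(0, spec$n_channels, n)
  for (i in seq_len(spec$n_channels)) x[i, ] <- bg_rms * pink_noise(n)
  band <- eeg_bands()[eeg_bands()$name == spec$target_bands[class_id + 1L], ]
  group <- spec$target_groups[[class_id + 1L]]
  rows <- match(group, ch)
  f0 <- stats::runif(1, band$lo + 0.1 * (band$hi - band$lo),
                     band$hi - 0.1 * (band$hi - band$lo))
  t <- (seq_len(n) - 1L) / spec$fs
  env <- 1 + 0.5 * sin(2 * pi * 0.2 * t + stats::runif(1, 0, 2 * pi))
  # background band power of 1/f noise with total power bg_rms^2:
  # fraction of power in [lo, hi) under the 1/f shape over [f1, fs/2]
  f1 <- 1 / spec$duration_s
  frac <- log(band$hi / band$lo) / log((spec$fs / 2) / f1)
  p_bg <- bg_rms^2 * frac
  amp <- sqrt(2 * spec$snr * p_bg / mean(env^2))
  carrier <- amp * env * sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
  x[rows, ] <- x[rows, ] + matrix(carrier, length(rows), n, byrow = TRUE)
  raw_recording(x, ch, fs = spec$fs, label = as.integer(class_id),
                subject = subject, session = session)
}

#' Generate a balanced synthetic dataset
#'
#' One recording per (subject, class, trial), with per-trial seeds derived
#' deterministically from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of [raw_recording()] objects,
#'   `n_subjects * n_classes * trials_per_class` long.
#' @export
generate_dataset <- function(spec) {
  recs <- list()
  k <- 0L
  for (s in seq_len(spec$n_subjects))
    for (cl in 0:(spec$n_classes - 1L))
      for (tr in seq_len(spec$trials_per_class)) {
        k <- k + 1L
        recs[[k]] <- generate_recording(
          spec, cl, seed = (spec$seed * 10007L + k * 97L) %% 2147483647L,
          subject = s, session = 1L)
      }
  recs
}

#' Directly generate linearly separable spatial-spectral maps
#'
#' A fast fixture for optimisation and ablation smoke tests: unit-variance
#' Gaussian 32 x 32 x 5 maps whose class means differ by `margin` inside
#' disjoint 8 x 8 cell blocks (class `c` gets the block at grid corner
#' `c`, in band slice `c mod 5`).
#'
#' @param n_per_class Maps per class.
#' @param n_classes Number of classes.
#' @param margin Mean offset of the class block (0 = indistinguishable).
#' @param seed Integer seed.
#' @param H,W,B Map dimensions.
#' @return List of labelled `spatial_spectral_map` objects,
#'   `n_per_class * n_classes` long.
#' @export
generate_separable_maps <- function(n_per_class, n_classes, margin, seed = 0L,
                                    H = 32, W = 32, B = 5) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  corners <- expand.grid(r = c(1L, max(1L, H - 7L)), c = c(1L, max(1L, W - 7L)))
  maps <- list()
  for (cl in 0:(n_classes - 1L)) {
    cr <- corners[(cl %% nrow(corners)) + 1L, ]
    rows <- cr$r:min(H, cr$r + 7L); cols <- cr$c:min(W, cr$c + 7L)
    b <- (cl %% B) + 1L
    for (i in seq_len(n_per_class)) {
      m <- array(stats::rnorm(H * W * B), c(H, W, B))
      m[rows, cols, b] <- m[rows, cols, b] + margin
      maps[[length(maps) + 1L]] <-
        structure(m, label = as.integer(cl), subject = 1L,
                  class = c("spatial_spectral_map", "array"))
    }
  }
  maps[order(rep(seq_len(n_per_class), n_classes))]  # interleave classes
}
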
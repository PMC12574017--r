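#' Filter specification for raw EMG
#'
#' The preprocessing chain is a sixth-order high-pass Butterworth at 15 Hz, a
#' second-order low-pass Butterworth at 375 Hz, and cascaded IIR notch filters
#' at 60, 120 and 180 Hz. All filters are applied causally (forward only),
#' matching real-time decoder use.
#'
#' @param fs sampling rate the filters are designed for, Hz.
#' @param hp_order,hp_cut high-pass order and cut-off (defaults 6, 15 Hz).
#' @param lp_order,lp_cut low-pass order and cut-off (defaults 2, 375 Hz).
#' @param notch_freqs notch centre frequencies (default 60, 120, 180 Hz).
#' @param notch_q notch quality factor (default 30).
#' @return an object of class `filter_spec` carrying the designed
#'   coefficient sets.
#' @export
filter_spec <- function(fs = 1000, hp_order = 6, hp_cut = 15,
                        lp_order = 2, lp_cut = 375,
                        notch_freqs = c(60, 120, 180), notch_q = 30) {
  nyq <- fs / 2
  if (lp_cut >= nyq) stop("low-pass cut-off (", lp_cut, " Hz) must be below Nyquist (", nyq, " Hz)")
  if (hp_cut >= lp_cut) stop("high-pass cut-off must be below the low-pass cut-off")
  if (any(notch_freqs >= nyq)) stop("notch frequencies must be below Nyquist")
  hp <- signal::butter(hp_order, hp_cut / nyq, type = "high")
  lp <- signal::butter(lp_order, lp_cut / nyq, type = "low")
  notches <- lapply(notch_freqs, function(f0) design_notch(f0, fs, notch_q))
  out <- list(fs = fs, hp_order = hp_order, hp_cut = hp_cut,
              lp_order = lp_order, lp_cut = lp_cut,
              notch_freqs = notch_freqs, notch_q = notch_q,
              hp = hp, lp = lp, notches = notches)
  class(out) <- "filter_spec"
  out
}

# Standard second-order IIR notch (biquad) at f0 with quality factor Q.
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a, f0 = f0, Q = Q)
}

# Magnitude response of a digital filter (b, a) at frequency f (Hz).
filter_gain_at <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

#' Causally filter a multichannel recording
#'
#' Applies the high-pass, low-pass and notch cascade of a [filter_spec()]
#' to every channel, forward only (no zero-phase filtering), so the output
#' is what an online decoder would see.
#'
#' @param raw an `emg_recording` or a numeric matrix (samples x channels).
#' @param spec a [filter_spec()]; defaults to `filter_spec(fs)` for the
#'   recording's rate.
#' @return same type as the input, filtered, same shape.
#' @export
apply_filters <- function(raw, spec = NULL) {
  v <- if (inherits(raw, "emg_recording")) raw$v else as.matrix(raw)
  fs <- if (inherits(raw, "emg_recording")) raw$fs else spec$fs
  if (is.null(spec)) spec <- filter_spec(fs)
  if (abs(fs - spec$fs) > 1e-9) stop("filter_spec designed for ", spec$fs,
                                     " Hz but recording is at ", fs, " Hz")
  out_v <- cpp_iir_filter(v, as.numeric(spec$hp$b), as.numeric(spec$hp$a))
  out_v <- cpp_iir_filter(out_v, as.numeric(spec$lp$b), as.numeric(spec$lp$a))
  for (nt in spec$notches) out_v <- cpp_iir_filter(out_v, nt$b, nt$a)
  if (inherits(raw, "emg_recording")) {
    raw$v <- out_v
    attr(raw, "filtered") <- TRUE
    raw
  } else out_v
}

#' All pairwise differential recordings
#'
#' One signal per unordered channel pair (i, j) with i < j, in lexicographic
#' order, with value `channel_i - channel_j`. For 32 channels this yields the
#' 496 differential recordings that, together with the single-ended channels,
#' make up the 528-feature set.
#'
#' @param v numeric matrix (samples x n channels), n >= 2.
#' @return a samples x `choose(n, 2)` matrix; attribute `channel_map` is a
#'   two-column matrix of the (i, j) pairs.
#' @export
differential_pairs <- function(v) {
  v <- as.matrix(v)
  n <- ncol(v)
  if (n < 2) {
    warning("fewer than 2 channels: no differential pairs")
    out <- v[, 0, drop = FALSE]
    attr(out, "channel_map") <- matrix(integer(0), 0, 2)
    return(out)
  }
  pairs <- t(combn(n, 2))  # lexicographic: (1,2), (1,3), ..., (n-1,n)
  out <- v[, pairs[, 1], drop = FALSE] - v[, pairs[, 2], drop = FALSE]
  colnames(out) <- paste0("d", pairs[, 1], "_", pairs[, 2])
  attr(out, "channel_map") <- pairs
  out
}

#' The fixed feature ordering of the 528-dimensional MAV set
#'
#' Single-ended channels 1..n first, then unordered pairs (i, j), i < j, in
#' lexicographic order. This ordering is frozen so fitted models are portable
#' across runs.
#'
#' @param n_channels channel count.
#' @return a data.frame with columns `feature`, `type` (`single`/`pair`),
#'   `i`, `j` (NA for single-ended).
#' @export
feature_channel_map <- function(n_channels = 32) {
  singles <- data.frame(type = "single", i = seq_len(n_channels), j = NA_integer_)
  if (n_channels >= 2) {
    pairs <- t(combn(n_channels, 2))
    pairs_df <- data.frame(type = "pair", i = pairs[, 1], j = pairs[, 2])
  } else pairs_df <- data.frame(type = character(0), i = integer(0), j = integer(0))
  out <- rbind(singles, pairs_df)
  out <- cbind(feature = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Smoothed mean-absolute-value features
#'
#' Computes MAV over a trailing window of `window_s` seconds, updated at
#' `rate_hz`. Frame k has timestamp `k / rate_hz`; a full window contains
#' `floor(window_s * fs)` samples; initial frames with partial windows use
#' the samples available so alignment with kinematics is preserved from t=0.
#'
#' @param v numeric matrix (samples x signals) at rate `fs`.
#' @param fs sampling rate, Hz.
#' @param window_s window length in seconds (default 0.3).
#' @param rate_hz frame update rate (default 30).
#' @return a frames x signals matrix of nonnegative MAV values; attribute
#'   `t` holds the frame timestamps.
#' @export
mav_features <- function(v, fs, window_s = 0.3, rate_hz = 30) {
  v <- as.matrix(v)
  n <- nrow(v)
  if (n < 1) stop("empty input")
  K <- floor(n / fs * rate_hz + 1e-9)
  if (K < 1) stop("recording shorter than one frame (", 1 / rate_hz, " s)")
  w <- floor(window_s * fs + 1e-9)
  ends <- pmin(n, floor(seq_len(K) / rate_hz * fs + 1e-9))
  starts <- pmax(1L, ends - w + 1L)
  cs <- apply(abs(v), 2, cumsum)
  cs <- rbind(0, cs)
  out <- (cs[ends + 1L, , drop = FALSE] - cs[starts, , drop = FALSE]) /
    (ends - starts + 1L)
  dimnames(out) <- NULL
  attr(out, "t") <- seq_len(K) / rate_hz
  out
}

#' Extract the full 528-feature MAV series from a filtered recording
#'
#' Fused single pass that computes MAV for the n single-ended channels and
#' all n(n-1)/2 differential pairs directly from the filtered channel matrix
#' (the differential signals are never materialised at the EMG rate). Equals
#' `mav_features(cbind(v, differential_pairs(v)))` to floating tolerance.
#'
#' @param filtered an `emg_recording` (already filtered) or samples x n
#'   matrix at rate `fs`.
#' @param fs sampling rate (taken from the recording if omitted).
#' @param window_s,rate_hz as in [mav_features()].
#' @return an object of class `feature_series`: list with `t` (frame times),
#'   `f` (frames x (n + n(n-1)/2) matrix), `channel_map`, `rate_hz`.
#' @export
extract_mav_features <- function(filtered, fs = NULL, window_s = 0.3,
                                 rate_hz = 30) {
  v <- if (inherits(filtered, "emg_recording")) filtered$v else as.matrix(filtered)
  if (is.null(fs)) fs <- if (inherits(filtered, "emg_recording")) filtered$fs else
    stop("fs required for matrix input")
  if (nrow(v) < 1) stop("empty input")
  f <- cpp_mav_pairwise(v, fs, rate_hz, window_s)
  K <- nrow(f)
  out <- list(t = seq_len(K) / rate_hz, f = f,
              channel_map = feature_channel_map(ncol(v)),
              rate_hz = rate_hz, window_s = window_s)
  class(out) <- "feature_series"
  out
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series: %d frames x %d features @ %g Hz>\n",
              nrow(x$f), ncol(x$f), x$rate_hz))
  invisible(x)
}

#' Align feature frames with kinematic frames
#'
#' Matches frames by nearest timestamp (both streams at a nominal common
#' rate), drops unmatched leading/trailing frames, and returns equal-length
#' paired sequences. Errors if the two rates differ by more than 1%.
#'
#' @param features a `feature_series`.
#' @param kin a `kin_trajectory`.
#' @return list with `Z` (frames x p features), `X` (frames x 3 kinematics),
#'   `t` (feature frame times), plus the per-frame labels `active_dof`,
#'   `phase`, `trial_id`, `block_id` carried over from the matched kinematic
#'   samples.
#' @export
align_features_to_kinematics <- function(features, kin) {
  stopifnot(inherits(features, "feature_series"), inherits(kin, "kin_trajectory"))
  if (abs(features$rate_hz - kin$fs) / kin$fs > 0.01) {
    stop("rate mismatch > 1%: features at ", features$rate_hz,
         " Hz, kinematics at ", kin$fs, " Hz")
  }
  tf <- features$t; tk <- kin$t
  # nearest kinematic sample for each feature frame
  idx <- findInterval(tf, tk)
  lo <- pmax(1L, idx); hi <- pmin(length(tk), idx + 1L)
  # prefer the earlier frame on (near-)ties so half-frame offsets pair
  # consistently instead of colliding on one kinematic sample
  j <- ifelse(abs(tf - tk[lo]) <= abs(tk[hi] - tf) + 1e-9, lo, hi)
  # keep frames whose nearest match is within half a frame period (with a
  # small guard so exact half-frame ties are kept)
  ok <- abs(tf - tk[j]) <= 0.5 / kin$fs + 1e-9
  keep <- which(ok)
  # drop any duplicated kinematic matches (can happen at stream edges)
  keep <- keep[!duplicated(j[keep])]
  j <- j[keep]
  list(
    Z = features$f[keep, , drop = FALSE],
    X = kin$x[j, , drop = FALSE],
    t = tf[keep],
    t_kin = tk[j],
    active_dof = kin$active_dof[j],
    active_movement = kin$active_movement[j],
    phase = kin$phase[j],
    trial_id = kin$trial_id[j],
    block_id = kin$block_id[j]
  )
}

#' Run the full preprocessing chain on a raw recording
#'
#' Filters the raw EMG ([apply_filters()]), extracts the fused MAV feature
#' set ([extract_mav_features()]) and aligns it with the generating
#' kinematics ([align_features_to_kinematics()]).
#'
#' @param raw an `emg_recording` with its `kin` trajectory attached.
#' @param spec optional [filter_spec()].
#' @param window_s,rate_hz MAV parameters.
#' @return the aligned list of [align_features_to_kinematics()].
#' @export
preprocess_recording <- function(raw, spec = NULL, window_s = 0.3,
                                 rate_hz = 30) {
  stopifnot(inherits(raw, "emg_recording"))
  filt <- apply_filters(raw, spec)
  feats <- extract_mav_features(filt, window_s = window_s, rate_hz = rate_hz)
  align_features_to_kinematics(feats, raw$kin)
}
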
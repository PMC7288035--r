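#' Filter specification
#'
#' @param kind `"high-pass"` or `"low-pass"`.
#' @param cutoff Cutoff frequency in Hz; must satisfy 0 < cutoff < rate/2 at
#'   application time.
#' @param order Filter order (applied twice, forward and backward, so the
#'   effective attenuation doubles in dB).
#' @param family Design family; only `"butterworth"` is implemented.
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("high-pass", "low-pass"), cutoff,
                        order = 4, family = "butterworth") {
  kind <- match.arg(kind)
  stopifnot(is.numeric(cutoff), cutoff > 0, order >= 1)
  if (family != "butterworth") stop("only the butterworth family is implemented")
  structure(list(kind = kind, cutoff = cutoff, order = as.integer(order),
                 family = family),
            class = "filter_spec")
}

# forward filtering started in steady state for the signal's first value, so a
# large DC offset causes no startup transient
#' @keywords internal
filt_ss <- function(b, a, x) {
  x0 <- x[1]
  y0 <- x0 * sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, length(b) - 1),
                            init.y = rep(y0, length(a) - 1)))
}

# zero-phase recursive filtering with odd-reflect padding (3 x order samples)
# and steady-state initialization at both ends
#' @keywords internal
zero_phase <- function(b, a, x, pad = 3 * (max(length(a), length(b)) - 1)) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  x1 <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- filt_ss(b, a, x1)
  y <- rev(filt_ss(b, a, rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' @keywords internal
apply_filter <- function(rec, spec) {
  if (spec$cutoff >= rec$rate / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 spec$cutoff, rec$rate / 2))
  type <- if (spec$kind == "high-pass") "high" else "low"
  bw <- signal::butter(spec$order, spec$cutoff / (rec$rate / 2), type = type)
  pad <- 3 * spec$order
  rec$samples <- t(apply(rec$samples, 1, function(r) zero_phase(bw$b, bw$a, r, pad)))
  rownames(rec$samples) <- rec$montage$channel
  rec
}

#' Remove DC offset and slow drift
#'
#' Zero-phase high-pass filtering (default 0.2 Hz, the sensor's lower
#' bandwidth limit). Removes the DC component and slow drifts while leaving
#' the in-band signal untouched; no time shift is introduced.
#'
#' @param rec An `eeg_recording`.
#' @param spec A high-pass [filter_spec()].
#' @return The filtered recording.
#' @export
remove_drift <- function(rec, spec = filter_spec("high-pass", 0.2, order = 4)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  if (spec$kind != "high-pass") stop("remove_drift requires a high-pass filter_spec")
  apply_filter(rec, spec)
}

#' Low-pass band limiting
#'
#' Zero-phase low-pass filtering (default 50 Hz, order 8). The two-pass
#' application attenuates power at 1.2 x cutoff by more than 20 dB.
#'
#' @param rec An `eeg_recording`.
#' @param spec A low-pass [filter_spec()].
#' @return The filtered recording.
#' @export
band_limit <- function(rec, spec = filter_spec("low-pass", 50, order = 8)) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  if (spec$kind != "low-pass") stop("band_limit requires a low-pass filter_spec")
  apply_filter(rec, spec)
}

#' Normalize recording amplitude to a symmetric range
#'
#' One affine map over the whole recording (all channels jointly) sending the
#' global minimum to `-bound` and the global maximum to `+bound`. A joint map
#' preserves the inter-channel amplitude relationships that topographic maps
#' display, and leaves all channel-pair Pearson correlations unchanged.
#'
#' @param rec An `eeg_recording`.
#' @param bound Target half-range (default 10).
#' @return The normalized recording (unitless samples).
#' @export
normalize_amplitude <- function(rec, bound = 10) {
  stopifnot(inherits(rec, "eeg_recording"), bound > 0)
  lo <- min(rec$samples)
  hi <- max(rec$samples)
  if (hi - lo <= 0) stop("cannot normalize a constant recording (zero range)")
  rec$samples <- 2 * bound * (rec$samples - lo) / (hi - lo) - bound
  rec
}

#' The full preprocessing chain
#'
#' Fixed order: high-pass (drift removal) -> low-pass (band limiting) ->
#' amplitude normalization. Shape (channels x samples) is preserved exactly
#' and the chain is deterministic.
#'
#' @param rec An `eeg_recording`.
#' @param hp,lp High- and low-pass cutoffs (Hz).
#' @param hp_order,lp_order Filter orders.
#' @param bound Normalization half-range.
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, hp = 0.2, lp = 50, hp_order = 4,
                                 lp_order = 8, bound = 10) {
  rec <- remove_drift(rec, filter_spec("high-pass", hp, hp_order))
  rec <- band_limit(rec, filter_spec("low-pass", lp, lp_order))
  rec <- normalize_amplitude(rec, bound)
  if (!all(is.finite(rec$samples))) stop("non-finite values after preprocessing")
  rec
}

#' Preprocess every recording of a study
#'
#' @param study An `eeg_study`.
#' @inheritParams preprocess_recording
#' @return The study with preprocessed recordings.
#' @export
preprocess_study <- function(study, hp = 0.2, lp = 50, hp_order = 4,
                             lp_order = 8, bound = 10) {
  stopifnot(inherits(study, "eeg_study"))
  study$recordings <- lapply(study$recordings, preprocess_recording,
                             hp = hp, lp = lp, hp_order = hp_order,
                             lp_order = lp_order, bound = bound)
  study
}
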
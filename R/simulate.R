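#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# counter-based seed derivation: recording k of a study keeps its seed when the
# pair count changes
#' @keywords internal
derive_seed <- function(seed, counter) {
  (as.double(seed) %% 2147483647 * 48271 + counter * 16807) %% 2147483647
}

#' @keywords internal
new_recording <- function(samples, rate, montage, pair = NA_character_,
                          role = NA_character_, system = NA_character_,
                          phase_boundary_s = 10, seed = NA_real_) {
  stopifnot(is.matrix(samples), nrow(samples) == nrow(montage))
  rownames(samples) <- montage$channel
  structure(list(samples = samples, rate = rate, montage = montage,
                 labels = list(pair = pair, role = role, system = system),
                 phase_boundary_s = phase_boundary_s, seed = seed),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  cat(sprintf("  pair=%s role=%s system=%s  phase boundary %g s\n",
              x$labels$pair, x$labels$role, x$labels$system,
              x$phase_boundary_s))
  invisible(x)
}

#' @keywords internal
recording_category <- function(rec) category_label(rec$labels$system, rec$labels$role)

#' Simulate one multichannel EEG recording
#'
#' Draws independent Gaussian channels, mixes them with a factor of the
#' target correlation matrix, band-limits the result to `band` (inside the
#' sensor bandwidth of 0.2-43 Hz) with a zero-phase Butterworth filter, and
#' scales channels to `signal_sd` microvolts. Because the same linear filter
#' is applied to every channel of an instantaneous mixture, the zero-lag
#' cross-channel correlation of the output equals `target` up to sampling
#' error. Optional artifacts are then added per channel: a DC offset plus a
#' slow (< 0.07 Hz) sinusoidal drift, and a 50 Hz line component with random
#' phase.
#'
#' @param target Valid correlation matrix (checked; an error names the most
#'   negative eigenvalue otherwise).
#' @param duration_s,rate_hz Recording length and sampling rate.
#' @param drift_amp,line_amp Artifact amplitudes in microvolts (0 disables).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param montage An [eeg_montage()].
#' @param band Passband (Hz) of the order-4 zero-phase Butterworth band-pass.
#' @param signal_sd Per-channel standard deviation (microvolt) of the
#'   band-limited signal before artifacts.
#' @param pair,role,system,phase_boundary_s Labels attached to the recording.
#' @return An `eeg_recording` (channels x samples).
#' @export
simulate_recording <- function(target, duration_s = 60, rate_hz = 128,
                               drift_amp = 100, line_amp = 2, seed = 1,
                               montage = eeg_montage(), band = c(1, 40),
                               signal_sd = 10, pair = NA_character_,
                               role = NA_character_, system = NA_character_,
                               phase_boundary_s = 10) {
  stopifnot(is.matrix(target), nrow(target) == ncol(target),
            nrow(target) == nrow(montage))
  n <- round(duration_s * rate_hz)
  if (n < 2) stop("duration_s * rate_hz must be at least 2")
  e <- eigen((target + t(target)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop(sprintf("target is not positive semi-definite (eigenvalue %.3g)",
                 min(e$values)))
  fac <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  nch <- nrow(target)
  with_seed(seed, {
    z <- matrix(stats::rnorm(nch * n), nch, n)
    x <- fac %*% z
    bp <- signal::butter(4, band / (rate_hz / 2), type = "pass")
    x <- t(apply(x, 1, function(r) zero_phase(bp$b, bp$a, r)))
    sds <- apply(x, 1, stats::sd)
    x <- x * (signal_sd / mean(sds))
    if (drift_amp > 0) {
      t_s <- seq_len(n) / rate_hz
      for (i in seq_len(nch)) {
        f0 <- stats::runif(1, 0.02, 0.07)
        ph <- stats::runif(1, 0, 2 * pi)
        dc <- stats::runif(1, -drift_amp, drift_amp)
        x[i, ] <- x[i, ] + dc + (drift_amp / 2) * sin(2 * pi * f0 * t_s + ph)
      }
    }
    if (line_amp > 0) {
      t_s <- seq_len(n) / rate_hz
      for (i in seq_len(nch)) {
        ph <- stats::runif(1, 0, 2 * pi)
        x[i, ] <- x[i, ] + line_amp * sin(2 * pi * 50 * t_s + ph)
      }
    }
    new_recording(x, rate_hz, montage, pair = pair, role = role,
                  system = system, phase_boundary_s = phase_boundary_s,
                  seed = seed)
  })
}

#' Generate a full synthetic study
#'
#' Generates `n_pairs` subject pairs, each with four 60 s recordings (process
#' owner and leader under both shopfloor-management systems), from one
#' condition profile per category. Per-recording seeds are derived from the
#' global seed with a counter so that recordings keep their identity when the
#' pair count changes. The leader-talks/PO-talks phase structure is recorded
#' as a metadata boundary at 10 s.
#'
#' @param n_pairs Number of subject pairs (the study design uses 14).
#' @param profiles Named list of four [condition_profile()]s (one per
#'   category), e.g. [condition_profiles()].
#' @param seed Global integer seed.
#' @param duration_s,rate_hz Recording length and sampling rate.
#' @param montage An [eeg_montage()].
#' @param signal_sd Per-channel signal scale in microvolts.
#' @return An `eeg_study`: list with `recordings` (length `n_pairs * 4`),
#'   `targets` (per-category target correlation matrices), and the study
#'   parameters.
#' @export
#' @examples
#' st <- generate_study(n_pairs = 1, seed = 7, duration_s = 4)
#' length(st$recordings)  # 4
generate_study <- function(n_pairs = 14, profiles = condition_profiles(),
                           seed = 1, duration_s = 60, rate_hz = 128,
                           montage = eeg_montage(), signal_sd = 10) {
  if (n_pairs < 1) stop("n_pairs must be at least 1")
  if (length(profiles) < 4) stop("four condition profiles are required")
  if (!all(CATEGORIES %in% names(profiles)))
    stop("profiles must be named by category: ", paste(CATEGORIES, collapse = ", "))
  targets <- lapply(profiles[CATEGORIES], build_target_correlation, montage = montage)
  roles <- c(HKT_PO = "process_owner", HKT_Leader = "leader",
             BSC_PO = "process_owner", BSC_Leader = "leader")
  systems <- c(HKT_PO = "HKT", HKT_Leader = "HKT",
               BSC_PO = "BSC", BSC_Leader = "BSC")
  recs <- vector("list", n_pairs * 4L)
  k <- 0L
  for (p in seq_len(n_pairs)) {
    pair_id <- sprintf("P%02d", p)
    for (cat in CATEGORIES) {
      k <- k + 1L
      prof <- profiles[[cat]]
      recs[[k]] <- simulate_recording(
        targets[[cat]], duration_s = duration_s, rate_hz = rate_hz,
        drift_amp = prof$drift_amp, line_amp = prof$line_amp,
        seed = derive_seed(seed, k), montage = montage,
        signal_sd = signal_sd, pair = pair_id, role = roles[[cat]],
        system = systems[[cat]])
    }
  }
  structure(list(recordings = recs, targets = targets, n_pairs = n_pairs,
                 seed = seed, duration_s = duration_s, rate_hz = rate_hz,
                 montage = montage),
            class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf("<eeg_study> %d pairs x 4 recordings (%g s @ %g Hz), seed %s\n",
              x$n_pairs, x$duration_s, x$rate_hz, format(x$seed)))
  invisible(x)
}
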
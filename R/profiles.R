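#' Define a condition profile for the synthetic generator
#'
#' A condition profile describes the cross-channel correlation structure of
#' one behavior category as a set of group-pair directives plus a baseline
#' off-diagonal correlation, together with artifact settings for the raw
#' signal (slow drift / DC offset amplitude and 50 Hz line-noise amplitude,
#' both on the microvolt scale of the unprocessed recording).
#'
#' @param condition Category label, one of `"HKT_PO"`, `"HKT_Leader"`,
#'   `"BSC_PO"`, `"BSC_Leader"`.
#' @param directives Data frame with columns `group_a`, `group_b` (sensor
#'   group names, see [sensor_groups()]), `relation` (`"within"` or
#'   `"between"`) and `level` (target correlation in \[-1, 1\]).
#'   `relation = "within"` requires `group_a == group_b`.
#' @param baseline Correlation assigned to all channel pairs not covered by a
#'   directive. Must be strictly below the smallest "strong" directive level.
#' @param drift_amp Amplitude (microvolt) of the DC offset and slow (< 0.1 Hz)
#'   drift added per channel.
#' @param line_amp Amplitude (microvolt) of the 50 Hz line component.
#' @return Object of class `condition_profile`.
#' @export
condition_profile <- function(condition, directives = NULL, baseline = 0,
                              drift_amp = 100, line_amp = 2) {
  if (!condition %in% CATEGORIES)
    stop("condition must be one of: ", paste(CATEGORIES, collapse = ", "))
  if (is.null(directives)) {
    directives <- data.frame(group_a = character(), group_b = character(),
                             relation = character(), level = numeric(),
                             stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(directives),
            all(c("group_a", "group_b", "relation", "level") %in% names(directives)))
  if (any(abs(directives$level) > 1)) stop("directive levels must lie in [-1, 1]")
  if (any(!directives$relation %in% c("within", "between")))
    stop("relation must be 'within' or 'between'")
  w <- directives$relation == "within"
  if (any(directives$group_a[w] != directives$group_b[w]))
    stop("'within' directives require group_a == group_b")
  if (abs(baseline) > 1) stop("baseline must lie in [-1, 1]")
  strong <- directives$level[abs(directives$level) >= 0.5]
  if (length(strong) && baseline >= min(abs(strong)))
    stop("baseline must be below the weakest strong directive level")
  structure(list(condition = condition, directives = directives,
                 baseline = baseline, drift_amp = drift_amp,
                 line_amp = line_amp),
            class = "condition_profile")
}

#' @keywords internal
dir_df <- function(...) {
  rows <- list(...)
  data.frame(
    group_a = vapply(rows, `[[`, "", 1L),
    group_b = vapply(rows, `[[`, "", 2L),
    relation = vapply(rows, `[[`, "", 3L),
    level = vapply(rows, function(r) as.numeric(r[[4L]]), 0),
    stringsAsFactors = FALSE
  )
}

#' Built-in condition profile presets
#'
#' Three presets, each a list of four [condition_profile()]s (one per
#' category):
#'
#' * `"hypotheses"` (default): encodes the five sensor-group hypotheses.
#'   Listening roles (leaders) couple the frontal and occipital groups
#'   (H1); speaking roles (process owners) show strong within-group but weak
#'   between-group frontal/occipital correlation (H2); every category has a
#'   strong within-frontal block (H3); HKT categories couple the frontal
#'   group to the temporal and parietal groups (H4) while BSC categories
#'   leave that coupling weak (H5). Levels: strong 0.65 (0.55 for the HKT
#'   leader's frontal-TPJ coupling), weak 0.2, baseline 0.15, with moderate
#'   within-temporal/parietal filler levels in the HKT categories so the
#'   directive set is close to a feasible correlation matrix.
#' * `"well_separated"`: a near-rank-one sign-pattern design used to verify
#'   that the soft sensor can learn category structure from single 0.5 s
#'   topomaps. Each category is one global sign pattern over the five sensor
#'   groups (within 0.98, between +-0.95, baseline 0); categories differ in
#'   the sign of the occipital, temporal/parietal and central groups.
#' * `"identity"`: no correlation structure at all (negative control).
#'
#' @param preset One of `"hypotheses"`, `"well_separated"`, `"identity"`.
#' @param drift_amp,line_amp Artifact settings forwarded to every profile.
#' @return Named list of four `condition_profile`s in category order.
#' @export
condition_profiles <- function(preset = c("hypotheses", "well_separated", "identity"),
                               drift_amp = 100, line_amp = 2) {
  preset <- match.arg(preset)
  mk <- function(cond, d, base)
    condition_profile(cond, d, baseline = base,
                      drift_amp = drift_amp, line_amp = line_amp)
  if (preset == "identity") {
    ps <- lapply(CATEGORIES, function(k) mk(k, NULL, 0))
  } else if (preset == "hypotheses") {
    ps <- list(
      mk("HKT_PO", dir_df(
        list("frontal", "frontal", "within", 0.65),
        list("occipital", "occipital", "within", 0.65),
        list("temporal", "temporal", "within", 0.35),
        list("parietal", "parietal", "within", 0.35),
        list("frontal", "occipital", "between", 0.20),
        list("frontal", "temporal", "between", 0.65),
        list("frontal", "parietal", "between", 0.65),
        list("temporal", "parietal", "between", 0.45)), 0.15),
      mk("HKT_Leader", dir_df(
        list("frontal", "frontal", "within", 0.65),
        list("occipital", "occipital", "within", 0.65),
        list("temporal", "temporal", "within", 0.35),
        list("parietal", "parietal", "within", 0.35),
        list("frontal", "occipital", "between", 0.65),
        list("frontal", "temporal", "between", 0.55),
        list("frontal", "parietal", "between", 0.55),
        list("temporal", "parietal", "between", 0.45),
        list("occipital", "temporal", "between", 0.35),
        list("occipital", "parietal", "between", 0.35)), 0.15),
      mk("BSC_PO", dir_df(
        list("frontal", "frontal", "within", 0.65),
        list("occipital", "occipital", "within", 0.65),
        list("frontal", "occipital", "between", 0.20),
        list("frontal", "temporal", "between", 0.20),
        list("frontal", "parietal", "between", 0.20)), 0.15),
      mk("BSC_Leader", dir_df(
        list("frontal", "frontal", "within", 0.65),
        list("occipital", "occipital", "within", 0.65),
        list("frontal", "occipital", "between", 0.65),
        list("frontal", "temporal", "between", 0.20),
        list("frontal", "parietal", "between", 0.20),
        list("occipital", "temporal", "between", 0.20),
        list("occipital", "parietal", "between", 0.20)), 0.15))
  } else {
    # sign pattern per category over (occipital, temporal+parietal, central);
    # frontal is always +1
    pat <- list(HKT_PO = c(-1, 1, 1), HKT_Leader = c(1, 1, -1),
                BSC_PO = c(-1, -1, -1), BSC_Leader = c(1, -1, 1))
    w <- 0.98; b <- 0.95
    groups <- c("frontal", "occipital", "temporal", "parietal", "central")
    sign_of <- function(p) c(frontal = 1, occipital = p[1], temporal = p[2],
                             parietal = p[2], central = p[3])
    ps <- lapply(CATEGORIES, function(k) {
      s <- sign_of(pat[[k]])
      rows <- list()
      for (i in seq_along(groups)) for (j in i:length(groups)) {
        gi <- groups[i]; gj <- groups[j]
        if (i == j) rows[[length(rows) + 1L]] <- list(gi, gj, "within", w)
        else rows[[length(rows) + 1L]] <- list(gi, gj, "between", b * s[[gi]] * s[[gj]])
      }
      mk(k, do.call(dir_df, rows), 0)
    })
  }
  names(ps) <- CATEGORIES
  ps
}
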
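#' The 16-channel 10-20 montage
#'
#' Returns the fixed 16-electrode montage used throughout the package: channel
#' names in recording order and 2D coordinates on the unit head disk
#' (azimuthal-equidistant projection of the standard 10-20 positions, nasion
#' up, right ear at positive x; the head rim is the unit circle).
#'
#' The channel order is fixed and shared by all correlation matrices, images
#' and recordings produced by the package.
#'
#' @return A data frame of class `eeg_montage` with columns `channel`, `x`,
#'   `y`.
#' @export
#' @examples
#' m <- eeg_montage()
#' nrow(m)  # 16
eeg_montage <- function() {
  m <- data.frame(
    channel = c("Fp1", "Fp2", "F4", "Fz", "F3", "T7", "C3", "Cz",
                "C4", "T8", "P4", "Pz", "P3", "O1", "Oz", "O2"),
    x = c(-0.246, 0.246, 0.355, 0.000, -0.355, -0.899, -0.433, 0.000,
          0.433, 0.899, 0.344, 0.000, -0.344, -0.234, 0.000, 0.234),
    y = c(0.837, 0.837, 0.489, 0.455, 0.489, 0.000, 0.000, 0.000,
          0.000, 0.000, -0.394, -0.357, -0.394, -0.757, -0.761, -0.757),
    stringsAsFactors = FALSE
  )
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' Named sensor groups over the montage
#'
#' The sensor groups used by the correlation hypotheses: `frontal` proxies the
#' prefrontal cortex, `temporal` and `parietal` together proxy the
#' temporoparietal junction, `occipital` the visual cortex. `central` collects
#' the remaining midline/central electrodes.
#'
#' @param montage An [eeg_montage()] (only used for validation).
#' @return Named list of character vectors of channel names.
#' @export
sensor_groups <- function(montage = eeg_montage()) {
  g <- list(
    frontal   = c("Fp1", "Fp2", "F3", "Fz", "F4"),
    occipital = c("O1", "Oz", "O2"),
    temporal  = c("T7", "T8"),
    parietal  = c("P3", "P4"),
    central   = c("C3", "Cz", "C4", "Pz")
  )
  stopifnot(all(unlist(g) %in% montage$channel))
  g
}

#' @keywords internal
resolve_group <- function(name, montage = eeg_montage()) {
  if (length(name) > 1L) {
    if (!all(name %in% montage$channel))
      stop("unknown channels: ", paste(setdiff(name, montage$channel), collapse = ", "))
    return(name)
  }
  g <- sensor_groups(montage)
  if (!name %in% names(g))
    stop("unknown sensor group '", name, "'; available: ",
         paste(names(g), collapse = ", "))
  g[[name]]
}

# fixed category vocabulary, in confusion-matrix order
CATEGORIES <- c("HKT_PO", "HKT_Leader", "BSC_PO", "BSC_Leader")

#' @keywords internal
category_label <- function(system, role) {
  paste0(system, "_", c(process_owner = "PO", leader = "Leader")[[role]])
}
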
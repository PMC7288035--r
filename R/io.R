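#' @keywords internal
pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

# shortest decimal representation of v that fits an 8-char EDF header field
#' @keywords internal
num_field <- function(v) {
  for (d in 7:1) {
    s <- formatC(signif(v, d), format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  stop("value does not fit an EDF numeric field: ", v)
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: 16-bit samples, one 1 s data record
#' per second of signal, per-channel physical scaling over the channel's
#' range. Labels (pair, role, system, phase boundary, seed) are stored in the
#' local recording identification field.
#'
#' @param rec An `eeg_recording` whose length is a whole number of seconds.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  spr <- as.integer(round(rec$rate))
  if (n %% spr != 0) stop("EDF export requires a whole number of 1 s records")
  nrec <- n %/% spr
  pmin <- apply(rec$samples, 1, min)
  pmax <- apply(rec$samples, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  meta <- sprintf("pair=%s system=%s role=%s phase=%g seed=%s",
                  rec$labels$pair, rec$labels$system, rec$labels$role,
                  rec$phase_boundary_s, format(rec$seed))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                      # patient id (anonymous)
  wr(meta, 80)                           # recording id carries the labels
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(format(256 * (1 + ns)), 8)
  wr("", 44)
  wr(format(nrec), 8)
  wr("1", 8)                             # 1 s per record
  wr(format(ns), 4)
  for (ch in rec$montage$channel) wr(ch, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  pmin <- vapply(pmin, function(v) as.numeric(num_field(v)), 0)
  pmax <- vapply(pmax, function(v) as.numeric(num_field(v)), 0)
  pmax[pmax <= pmin] <- pmin[pmax <= pmin] + 1
  for (v in pmin) wr(num_field(v), 8)
  for (v in pmax) wr(num_field(v), 8)
  for (i in seq_len(ns)) wr(format(dmin), 8)
  for (i in seq_len(ns)) wr(format(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(format(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) {
      dig <- round((rec$samples[i, idx] - pmin[i]) / scale[i] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]; reads 16-bit EDF with equal sampling rate on
#' all channels. Channel labels must match the montage exactly (an error
#' otherwise); samples are returned in montage order.
#'
#' @param path EDF file.
#' @param montage An [eeg_montage()].
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, montage = eeg_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  rd(80)                                  # patient
  meta <- rd(80)
  rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (!setequal(labels, montage$channel))
    stop(sprintf("channel labels do not match the %d-channel montage (file has %d: %s)",
                 nrow(montage), ns, paste(labels, collapse = ", ")))
  if (length(unique(spr)) != 1) stop("channels with unequal sampling rates")
  rate <- spr[1] / recdur
  x <- matrix(0, ns, nrec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      x[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- (dig - dmin[i]) * scale[i] + pmin[i]
    }
  }
  x <- x[match(montage$channel, labels), , drop = FALSE]
  kv <- strsplit(strsplit(meta, " ")[[1]], "=")
  get_kv <- function(k) {
    hit <- Filter(function(p) p[1] == k, kv)
    if (length(hit)) hit[[1]][2] else NA_character_
  }
  new_recording(x, rate, montage,
                pair = get_kv("pair"), role = get_kv("role"),
                system = get_kv("system"),
                phase_boundary_s = as.numeric(get_kv("phase") %||% 10),
                seed = as.numeric(get_kv("seed")))
}

#' Write / read a recording
#'
#' `"delimited"` writes a tab-separated file (one row per sample, one column
#' per channel, header = channel names) plus a JSON sidecar
#' (`<path>.json`) with rate, labels and phase boundary; the round-trip is
#' exact. `"edf"` uses [write_edf()]/[read_edf()]; the round-trip error is
#' bounded by the per-channel 16-bit quantization step.
#'
#' @param rec An `eeg_recording`.
#' @param path Output file.
#' @param format `"delimited"` or `"edf"` (`read_recording` defaults to
#'   `"auto"`: by file extension).
#' @return `write_recording`: invisibly `path`; `read_recording`: an
#'   `eeg_recording`.
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(write_edf(rec, path))
  dt <- data.table::as.data.table(t(rec$samples))
  data.table::setnames(dt, rec$montage$channel)
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(
    list(rate = rec$rate, pair = rec$labels$pair, role = rec$labels$role,
         system = rec$labels$system, phase_boundary_s = rec$phase_boundary_s,
         seed = rec$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param montage An [eeg_montage()]; file channels must match it.
#' @param rate Sampling rate override for delimited files without a sidecar.
#' @rdname write_recording
#' @export
read_recording <- function(path, format = c("auto", "delimited", "edf"),
                           montage = eeg_montage(), rate = 128) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") return(read_edf(path, montage))
  dt <- data.table::fread(path, sep = "\t")
  if (!setequal(names(dt), montage$channel))
    stop(sprintf("channel labels do not match the %d-channel montage (file has %d)",
                 nrow(montage), ncol(dt)))
  x <- t(as.matrix(dt[, montage$channel, with = FALSE]))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  new_recording(x, meta$rate %||% rate, montage,
                pair = meta$pair %||% NA_character_,
                role = meta$role %||% NA_character_,
                system = meta$system %||% NA_character_,
                phase_boundary_s = meta$phase_boundary_s %||% 10,
                seed = meta$seed %||% NA_real_)
}

#' Write a study to disk with a manifest
#'
#' One file per recording (named `{pair}_{system}_{role}.{ext}`) plus
#' `manifest.json` listing pair, role, system, seed and file name per
#' recording together with the study parameters.
#'
#' @param study An `eeg_study`.
#' @param dir Output directory.
#' @param format `"delimited"` or `"edf"`.
#' @return Invisibly, the manifest list.
#' @export
write_study <- function(study, dir, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(study, "eeg_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "edf") "edf" else "tsv"
  entries <- lapply(study$recordings, function(rec) {
    fn <- sprintf("%s_%s_%s.%s", rec$labels$pair, rec$labels$system,
                  rec$labels$role, ext)
    write_recording(rec, file.path(dir, fn), format)
    list(file = fn, pair = rec$labels$pair, role = rec$labels$role,
         system = rec$labels$system,
         category = category_label(rec$labels$system, rec$labels$role),
         seed = rec$seed)
  })
  manifest <- list(n_pairs = study$n_pairs, seed = study$seed,
                   rate_hz = study$rate_hz, duration_s = study$duration_s,
                   format = format, recordings = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `manifest.json`.
#' @param montage An [eeg_montage()].
#' @return An `eeg_study`.
#' @export
read_study <- function(dir, montage = eeg_montage()) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  recs <- lapply(mf$recordings, function(e)
    read_recording(file.path(dir, e$file), montage = montage,
                   rate = mf$rate_hz))
  structure(list(recordings = recs, targets = NULL,
                 n_pairs = mf$n_pairs, seed = mf$seed,
                 duration_s = mf$duration_s, rate_hz = mf$rate_hz,
                 montage = montage),
            class = "eeg_study")
}

#' Read topomap PNGs listed in a labels manifest
#'
#' @param dir Directory written by [write_topomaps()].
#' @param manifest Optional manifest data frame (defaults to
#'   `labels.csv` in `dir`).
#' @return List with `images` (H x W x 3 x N array, values in \[0, 1\]) and
#'   `meta`.
#' @export
read_topomaps <- function(dir, manifest = NULL) {
  if (is.null(manifest))
    manifest <- utils::read.csv(file.path(dir, "labels.csv"),
                                stringsAsFactors = FALSE)
  first <- png::readPNG(file.path(dir, manifest$filename[1]))
  images <- array(0, c(dim(first)[1], dim(first)[2], 3L, nrow(manifest)))
  images[, , , 1] <- first[, , 1:3]
  for (i in seq_len(nrow(manifest))[-1])
    images[, , , i] <- png::readPNG(file.path(dir, manifest$filename[i]))[, , 1:3]
  list(images = images, meta = manifest)
}
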
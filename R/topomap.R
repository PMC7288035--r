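#' Split a recording into fixed-length segments
#'
#' Non-overlapping consecutive windows; a trailing remainder shorter than one
#' window is dropped.
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds; `window_s * rate` must be an
#'   integer (0.5 s at 128 Hz gives 64-sample segments).
#' @return List of `eeg_segment` objects with fields `samples`
#'   (channels x window), `start_s`, `labels`, `montage`.
#' @export
#' @examples
#' st <- generate_study(n_pairs = 1, seed = 1, duration_s = 2)
#' length(segment_recording(st$recordings[[1]]))  # 4
segment_recording <- function(rec, window_s = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  w <- window_s * rec$rate
  if (abs(w - round(w)) > 1e-9) stop("window_s * rate must be an integer")
  w <- as.integer(round(w))
  n <- ncol(rec$samples)
  if (w > n) stop("window is longer than the recording")
  nseg <- n %/% w
  lapply(seq_len(nseg), function(i) {
    structure(list(samples = rec$samples[, ((i - 1L) * w + 1L):(i * w), drop = FALSE],
                   start_s = (i - 1L) * window_s,
                   labels = rec$labels, montage = rec$montage),
              class = "eeg_segment")
  })
}

#' Per-channel scalar summary of a segment
#'
#' Reduces each channel of a segment to one scalar, in montage order. The
#' default is the mean (the "average activity" shown by a topographic map);
#' `rms` is available as an alternative.
#'
#' @param seg An `eeg_segment`.
#' @param method `"mean"` or `"rms"`.
#' @return Named numeric vector of length 16.
#' @export
channel_summary <- function(seg, method = c("mean", "rms")) {
  stopifnot(inherits(seg, "eeg_segment"))
  method <- match.arg(method)
  v <- switch(method,
              mean = rowMeans(seg$samples),
              rms  = sqrt(rowMeans(seg$samples^2)))
  stats::setNames(as.numeric(v), seg$montage$channel)
}

# thin-plate kernel phi(r) = r^2 log r, phi(0) = 0
#' @keywords internal
tps_kernel <- function(r) ifelse(r > 0, r^2 * log(r), 0)

#' Exact scalp interpolant over the montage
#'
#' Thin-plate-spline radial-basis interpolation of one scalar per electrode
#' over the 2D head disk. The interpolant reproduces the electrode values
#' exactly and extends smoothly (including its affine part) to the disk
#' border.
#'
#' @param values Numeric vector, one finite value per montage channel.
#' @param montage An [eeg_montage()].
#' @return A function `f(points)` taking an n x 2 matrix of (x, y) positions
#'   and returning interpolated values.
#' @export
scalp_interpolant <- function(values, montage = eeg_montage()) {
  stopifnot(length(values) == nrow(montage), all(is.finite(values)))
  p <- as.matrix(montage[, c("x", "y")])
  if (anyDuplicated(p)) stop("montage has coincident electrode positions")
  n <- nrow(p)
  K <- tps_kernel(as.matrix(stats::dist(p)))
  P <- cbind(1, p)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  wc <- solve(A, c(values, 0, 0, 0))
  w <- wc[1:n]; cc <- wc[(n + 1):(n + 3)]
  function(points) {
    points <- matrix(points, ncol = 2)
    d <- sqrt(outer(points[, 1], p[, 1], "-")^2 +
              outer(points[, 2], p[, 2], "-")^2)
    as.numeric(tps_kernel(d) %*% w + cc[1] + points %*% cc[2:3])
  }
}

# cached per-(montage, grid_n) design: disk mask and grid kernel matrix, so a
# study's thousands of segments reuse one factorization-sized precomputation
.topo_cache <- new.env(parent = emptyenv())

#' @keywords internal
grid_design <- function(montage, grid_n) {
  key <- paste0(grid_n, "|", paste(signif(c(montage$x, montage$y), 7), collapse = ","))
  hit <- .topo_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- as.matrix(montage[, c("x", "y")])
  n <- nrow(p)
  K <- tps_kernel(as.matrix(stats::dist(p)))
  P <- cbind(1, p)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Ainv <- solve(A)
  g <- seq(-1, 1, length.out = grid_n)
  gx <- rep(g, each = grid_n)   # column-major: rows vary fastest
  gy <- rep(g, times = grid_n)
  inside <- gx^2 + gy^2 <= 1
  pts <- cbind(gx[inside], gy[inside])
  d <- sqrt(outer(pts[, 1], p[, 1], "-")^2 + outer(pts[, 2], p[, 2], "-")^2)
  G <- cbind(tps_kernel(d), 1, pts)   # (npix_inside) x (n + 3)
  des <- list(Ainv = Ainv, G = G, inside = inside, grid_n = grid_n, n = n)
  .topo_cache[[key]] <- des
  des
}

#' Interpolate a scalar scalp field on a pixel grid
#'
#' Evaluates the thin-plate interpolant of 16 electrode values on a
#' `grid_n` x `grid_n` grid spanning \[-1, 1\]^2; pixels outside the unit
#' head disk are `NA`.
#'
#' @inheritParams scalp_interpolant
#' @param grid_n Grid resolution in pixels per side.
#' @return `grid_n` x `grid_n` numeric matrix (row = y from top to bottom is
#'   *not* applied here; the matrix is in plain Cartesian orientation with
#'   `[i, j]` at `x = grid[i]`, `y = grid[j]`), `NA` outside the disk.
#' @export
interpolate_scalp_field <- function(values, montage = eeg_montage(),
                                    grid_n = 360) {
  stopifnot(length(values) == nrow(montage), all(is.finite(values)))
  des <- grid_design(montage, grid_n)
  w <- des$Ainv %*% c(values, 0, 0, 0)
  field <- rep(NA_real_, grid_n * grid_n)
  field[des$inside] <- as.numeric(des$G %*% w)
  matrix(field, grid_n, grid_n)
}

#' The jet colormap
#'
#' Conventional piecewise-linear jet: dark blue -> blue -> cyan -> green ->
#' yellow -> red -> dark red.
#'
#' @param v Numeric vector in \[0, 1\].
#' @return n x 3 matrix of RGB values in \[0, 1\].
#' @export
jet_colormap <- function(v) {
  clamp <- function(x) pmin(pmax(x, 0), 1)
  cbind(r = clamp(1.5 - 4 * abs(v - 0.75)),
        g = clamp(1.5 - 4 * abs(v - 0.50)),
        b = clamp(1.5 - 4 * abs(v - 0.25)))
}

#' Render a scalp field as an 8-bit jet image
#'
#' Per-image min-max scaling: the field minimum maps to the low (dark blue)
#' end, the maximum to the high (dark red) end. A constant field maps to the
#' colormap midpoint. Pixels outside the head disk get the uniform white
#' background. Output is deterministic for a given field.
#'
#' @param field Matrix from [interpolate_scalp_field()] (`NA` outside the
#'   disk).
#' @return `topomap_image`: H x W x 3 integer array with values 0-255 and
#'   attributes `zmin`, `zmax` (the scaling bounds).
#' @export
render_topomap <- function(field) {
  stopifnot(is.matrix(field))
  zmin <- min(field, na.rm = TRUE)
  zmax <- max(field, na.rm = TRUE)
  # a numerically constant field maps to the colormap midpoint
  degenerate <- (zmax - zmin) <= 1e-9 * max(abs(zmax), abs(zmin), 1)
  v <- if (!degenerate) (field - zmin) / (zmax - zmin) else
    array(0.5, dim(field))
  v[is.na(field)] <- NA
  inside <- !is.na(v)
  rgb01 <- jet_colormap(v[inside])
  img <- array(255L, c(nrow(field), ncol(field), 3L))
  for (k in 1:3) {
    plane <- img[, , k]
    plane[inside] <- as.integer(round(255 * rgb01[, k]))
    img[, , k] <- plane
  }
  structure(img, zmin = zmin, zmax = zmax, class = "topomap_image")
}

#' Topographic-map image of one segment
#'
#' Channel summary -> scalp interpolation -> jet rendering, in one call.
#'
#' @param seg An `eeg_segment`.
#' @param grid_n Image side length in pixels (360 for the full-size maps).
#' @param method Channel summary method, see [channel_summary()].
#' @return A `topomap_image` with the segment's labels attached as attribute
#'   `labels`.
#' @export
topomap_image <- function(seg, grid_n = 360, method = "mean") {
  v <- channel_summary(seg, method)
  img <- render_topomap(interpolate_scalp_field(v, seg$montage, grid_n))
  attr(img, "labels") <- seg$labels
  img
}

# image array orientation for files/classifier input: row = image row (top of
# the head at the top), column = x left to right
#' @keywords internal
image_to_raster <- function(img) {
  aperm(img[, dim(img)[2]:1, , drop = FALSE], c(2, 1, 3))
}

#' Render every segment of a study
#'
#' Returns all topomap images of a study as one numeric array (values in
#' \[0, 1\], 8-bit quantized) plus a label table. Intended for desk-scale
#' classifier work (`grid_n` well below 360); use [write_topomaps()] to
#' stream full-size images to PNG files instead.
#'
#' @param study An `eeg_study` (normally preprocessed).
#' @param grid_n Image side length in pixels.
#' @param window_s Segment window in seconds.
#' @param method Channel summary method.
#' @return List with `images` (grid_n x grid_n x 3 x N array) and `meta`
#'   (data frame: pair, role, system, category, segment).
#' @export
study_images <- function(study, grid_n = 90, window_s = 0.5, method = "mean") {
  stopifnot(inherits(study, "eeg_study"))
  segs <- unlist(lapply(study$recordings, segment_recording, window_s = window_s),
                 recursive = FALSE)
  n <- length(segs)
  images <- array(0, c(grid_n, grid_n, 3L, n))
  meta <- data.frame(pair = character(n), role = character(n),
                     system = character(n), category = character(n),
                     segment = integer(n), stringsAsFactors = FALSE)
  seg_counter <- list()
  for (i in seq_len(n)) {
    s <- segs[[i]]
    img <- topomap_image(s, grid_n = grid_n, method = method)
    images[, , , i] <- image_to_raster(unclass(img)) / 255
    key <- paste(s$labels$pair, s$labels$system, s$labels$role)
    idx <- (seg_counter[[key]] <- (seg_counter[[key]] %||% 0L) + 1L)
    meta$pair[i] <- s$labels$pair
    meta$role[i] <- s$labels$role
    meta$system[i] <- s$labels$system
    meta$category[i] <- category_label(s$labels$system, s$labels$role)
    meta$segment[i] <- idx
  }
  list(images = images, meta = meta)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study's topomaps as PNG files plus a labels manifest
#'
#' File names follow `{pair}_{system}_{role}_{segment}.png`; the manifest
#' (`labels.csv`) lists every file with its category.
#'
#' @inheritParams study_images
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_topomaps <- function(study, dir, grid_n = 360, window_s = 0.5,
                           method = "mean") {
  stopifnot(inherits(study, "eeg_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (rec in study$recordings) {
    segs <- segment_recording(rec, window_s)
    for (i in seq_along(segs)) {
      img <- topomap_image(segs[[i]], grid_n = grid_n, method = method)
      fn <- sprintf("%s_%s_%s_%03d.png", rec$labels$pair, rec$labels$system,
                    rec$labels$role, i)
      png::writePNG(image_to_raster(unclass(img)) / 255, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(
        filename = fn, pair = rec$labels$pair, role = rec$labels$role,
        system = rec$labels$system,
        category = category_label(rec$labels$system, rec$labels$role),
        segment = i, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}
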
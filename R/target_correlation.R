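#' Nearest correlation matrix by eigenvalue clipping
#'
#' Projects a symmetric matrix with unit diagonal onto the set of valid
#' correlation matrices (symmetric positive semi-definite, unit diagonal) by
#' alternating eigenvalue clipping and diagonal renormalization.
#'
#' @param m Symmetric matrix with unit diagonal.
#' @param maxit Maximum number of clip/renormalize sweeps.
#' @param tol Eigenvalue tolerance: iteration stops once the smallest
#'   eigenvalue exceeds `-tol`.
#' @return The projected matrix, with attribute `delta` (the maximum absolute
#'   elementwise change) and `iterations`.
#' @export
nearest_correlation <- function(m, maxit = 100, tol = 1e-8) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  x <- (m + t(m)) / 2
  it <- 0L
  for (i in seq_len(maxit)) {
    e <- eigen(x, symmetric = TRUE)
    if (min(e$values) > -tol) break
    it <- i
    x <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    d <- sqrt(pmax(diag(x), .Machine$double.eps))
    x <- x / outer(d, d)
    x <- (x + t(x)) / 2
    diag(x) <- 1
  }
  dimnames(x) <- dimnames(m)
  attr(x, "delta") <- max(abs(x - m))
  attr(x, "iterations") <- it
  x
}

#' Build the target correlation matrix of a condition profile
#'
#' Expands the group-pair directives of a [condition_profile()] into a full
#' 16 x 16 correlation matrix: every channel pair covered by a directive gets
#' the directive's level (later directives overwrite earlier ones), all other
#' off-diagonal entries get the baseline, the diagonal is 1. The result is
#' then projected to the nearest valid correlation matrix with
#' [nearest_correlation()]; if the projection moves any entry by more than
#' `max_delta` a warning reports the largest change.
#'
#' @param profile A [condition_profile()].
#' @param montage An [eeg_montage()].
#' @param max_delta Tolerated projection change before warning.
#' @param project Set `FALSE` to return the raw blockwise construction
#'   without the PSD projection (for inspection; such a matrix may not be a
#'   valid correlation matrix).
#' @return 16 x 16 correlation matrix with channel dimnames and attributes
#'   `delta`, `condition`.
#' @export
#' @examples
#' p <- condition_profiles()[["HKT_PO"]]
#' r <- build_target_correlation(p)
#' range(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
build_target_correlation <- function(profile, montage = eeg_montage(),
                                     max_delta = 0.05, project = TRUE) {
  stopifnot(inherits(profile, "condition_profile"))
  ch <- montage$channel
  n <- length(ch)
  m <- matrix(profile$baseline, n, n, dimnames = list(ch, ch))
  dirs <- profile$directives
  for (k in seq_len(nrow(dirs))) {
    a <- match(resolve_group(dirs$group_a[k], montage), ch)
    b <- match(resolve_group(dirs$group_b[k], montage), ch)
    if (dirs$relation[k] == "between" && length(intersect(a, b)))
      stop("'between' directive with overlapping groups: ",
           dirs$group_a[k], " / ", dirs$group_b[k])
    m[a, b] <- dirs$level[k]
    m[b, a] <- dirs$level[k]
  }
  diag(m) <- 1
  if (!project) {
    attr(m, "condition") <- profile$condition
    attr(m, "provenance") <- "target_raw"
    return(m)
  }
  out <- nearest_correlation(m)
  if (attr(out, "delta") > max_delta)
    warning(sprintf(
      "directive set for %s is not jointly feasible; projection moved an entry by %.3f",
      profile$condition, attr(out, "delta")))
  attr(out, "condition") <- profile$condition
  attr(out, "provenance") <- "target"
  out
}
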
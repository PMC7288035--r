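#' Channel-correlation matrix of a recording
#'
#' Zero-lag Pearson correlation between every channel pair, over the full
#' recording or excluding the first 10 s leader-talks phase.
#'
#' @param rec An `eeg_recording` (at least 2 samples, no zero-variance
#'   channel).
#' @param span `"full"` or `"exclude_first_10s"`.
#' @return 16 x 16 symmetric matrix, unit diagonal, channel dimnames,
#'   attribute `provenance = "recording"`.
#' @export
correlation_matrix <- function(rec, span = c("full", "exclude_first_10s")) {
  stopifnot(inherits(rec, "eeg_recording"))
  span <- match.arg(span)
  x <- rec$samples
  if (span == "exclude_first_10s") {
    skip <- round(rec$phase_boundary_s * rec$rate)
    x <- x[, (skip + 1):ncol(x), drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance channel: ",
         paste(rec$montage$channel[sds == 0], collapse = ", "))
  m <- stats::cor(t(x))
  attr(m, "provenance") <- "recording"
  m
}

#' Average correlation matrices across recordings
#'
#' Elementwise average of same-montage correlation matrices. The default
#' averages on the Fisher z scale (`tanh(mean(atanh(r)))`), which is less
#' biased for strong correlations than the arithmetic mean; the diagonal is
#' forced to 1.
#'
#' @param mats Non-empty list of correlation matrices with identical
#'   dimnames.
#' @param method `"fisher_z"` or `"arithmetic"`.
#' @return The averaged matrix, `provenance = "category_average"`.
#' @export
average_correlation <- function(mats, method = c("fisher_z", "arithmetic")) {
  method <- match.arg(method)
  if (length(mats) == 0) stop("empty list of matrices")
  dn <- dimnames(mats[[1]])
  for (m in mats)
    if (!identical(dimnames(m), dn)) stop("matrices have mismatched montages")
  arr <- simplify2array(mats)
  avg <- if (method == "arithmetic") {
    apply(arr, c(1, 2), mean)
  } else {
    z <- atanh(pmin(pmax(arr, -1 + 1e-15), 1 - 1e-15))
    tanh(apply(z, c(1, 2), mean))
  }
  diag(avg) <- 1
  dimnames(avg) <- dn
  attr(avg, "provenance") <- "category_average"
  avg
}

#' Per-category averaged correlation matrices of a study
#'
#' @param study An `eeg_study` (normally preprocessed).
#' @param span,method Passed to [correlation_matrix()] and
#'   [average_correlation()].
#' @return Named list of four averaged matrices in category order.
#' @export
category_correlations <- function(study, span = "full", method = "fisher_z") {
  stopifnot(inherits(study, "eeg_study"))
  cats <- vapply(study$recordings, recording_category, "")
  out <- lapply(CATEGORIES, function(k) {
    mats <- lapply(study$recordings[cats == k], correlation_matrix, span = span)
    average_correlation(mats, method = method)
  })
  names(out) <- CATEGORIES
  out
}

#' Difference of two correlation matrices
#'
#' Elementwise `a - b`; antisymmetric under operand swap. The attribute
#' `zlim` carries the symmetric colorscale bound (maximum absolute entry)
#' used when such differences are displayed.
#'
#' @param a,b Correlation matrices with identical dimnames.
#' @return Difference matrix, `provenance = "difference"`.
#' @export
cor_difference <- function(a, b) {
  if (!identical(dimnames(a), dimnames(b))) stop("montage mismatch")
  d <- unclass(a) - unclass(b)
  attributes(d) <- list(dim = dim(d), dimnames = dimnames(a))
  attr(d, "provenance") <- "difference"
  attr(d, "zlim") <- max(abs(d))
  d
}

#' Aggregate correlation entries over a sensor-group pair
#'
#' For `relation = "between"` the statistics run over all |a| x |b| cross
#' entries (groups must be disjoint); for `"within"` over the off-diagonal
#' entries inside the group (`a` and `b` must coincide).
#'
#' @param m Correlation matrix with channel dimnames.
#' @param a,b Group names (see [sensor_groups()]) or character vectors of
#'   channels.
#' @param relation `"between"` or `"within"`.
#' @param montage An [eeg_montage()].
#' @return List with `min`, `max`, `mean`, `n`, and `entries` (data frame
#'   ch_a, ch_b, value).
#' @export
group_summary <- function(m, a, b = a, relation = c("between", "within"),
                          montage = eeg_montage()) {
  relation <- match.arg(relation)
  ca <- resolve_group(a, montage)
  cb <- resolve_group(b, montage)
  if (relation == "within") {
    if (!setequal(ca, cb)) stop("'within' requires identical groups")
    pr <- t(utils::combn(ca, 2))
  } else {
    if (length(intersect(ca, cb))) stop("'between' requires disjoint groups")
    pr <- as.matrix(expand.grid(ch_a = ca, ch_b = cb, stringsAsFactors = FALSE))
  }
  vals <- m[cbind(pr[, 1], pr[, 2])]
  entries <- data.frame(ch_a = pr[, 1], ch_b = pr[, 2], value = as.numeric(vals),
                        stringsAsFactors = FALSE)
  list(min = min(vals), max = max(vals), mean = mean(vals),
       n = nrow(entries), entries = entries)
}

#' The five sensor-group hypotheses
#'
#' H1: leaders couple the frontal and occipital groups (strong, between).
#' H2: process owners show strong within-frontal and within-occipital
#' correlation. H3: every category shows strong within-frontal correlation.
#' H4: HKT categories couple the frontal group to the temporal and parietal
#' groups (strong). H5: BSC categories leave that coupling weak.
#'
#' @param theta_strong Threshold for "strong": supported when the minimum
#'   pooled entry reaches it (0.5 by default, just below the 0.52-0.71 range
#'   typical of a clearly strong coupling; 0.6 already counts as strong).
#' @param theta_weak Threshold for "weak": supported when the maximum pooled
#'   entry stays at or below it.
#' @return List of `hypothesis_spec` objects.
#' @export
hypothesis_specs <- function(theta_strong = 0.5, theta_weak = 0.4) {
  stopifnot(theta_weak < theta_strong)
  spec <- function(id, categories, pairs, expectation) {
    structure(list(id = id, categories = categories, pairs = pairs,
                   expectation = expectation,
                   theta = if (expectation == "strong") theta_strong else theta_weak),
              class = "hypothesis_spec")
  }
  list(
    spec("H1", c("HKT_Leader", "BSC_Leader"),
         list(list("frontal", "occipital", "between")), "strong"),
    spec("H2", c("HKT_PO", "BSC_PO"),
         list(list("frontal", "frontal", "within"),
              list("occipital", "occipital", "within")), "strong"),
    spec("H3", CATEGORIES,
         list(list("frontal", "frontal", "within")), "strong"),
    spec("H4", c("HKT_PO", "HKT_Leader"),
         list(list("frontal", "temporal", "between"),
              list("frontal", "parietal", "between")), "strong"),
    spec("H5", c("BSC_PO", "BSC_Leader"),
         list(list("frontal", "temporal", "between"),
              list("frontal", "parietal", "between")), "weak")
  )
}

#' Evaluate the sensor-group hypotheses on category matrices
#'
#' For each hypothesis and each applicable category, the relevant entries are
#' pooled over the hypothesis' group pairs and judged against the threshold:
#' a strong expectation is `supported` when even the minimum entry reaches
#' `theta_strong`, a weak expectation when even the maximum stays at or below
#' `theta_weak`; the verdict is `mixed` when only the mean satisfies the
#' threshold, and `not_supported` otherwise.
#'
#' @param category_matrices Named list of correlation matrices (e.g. from
#'   [category_correlations()]).
#' @param specs List of hypothesis specs, see [hypothesis_specs()].
#' @return A `hypothesis_report` data frame (one row per hypothesis x
#'   category: id, category, expectation, threshold, n, min, max, mean,
#'   verdict) with the pooled entries attached as attribute `entries`.
#' @export
evaluate_hypotheses <- function(category_matrices, specs = hypothesis_specs()) {
  rows <- list()
  entries <- list()
  for (sp in specs) {
    missing <- setdiff(sp$categories, names(category_matrices))
    if (length(missing))
      stop("missing category matrices: ", paste(missing, collapse = ", "))
    for (cat in sp$categories) {
      m <- category_matrices[[cat]]
      ent <- do.call(rbind, lapply(sp$pairs, function(p) {
        group_summary(m, p[[1]], p[[2]], relation = p[[3]])$entries
      }))
      vmin <- min(ent$value); vmax <- max(ent$value); vmean <- mean(ent$value)
      verdict <- if (sp$expectation == "strong") {
        if (vmin >= sp$theta) "supported"
        else if (vmean >= sp$theta) "mixed"
        else "not_supported"
      } else {
        if (vmax <= sp$theta) "supported"
        else if (vmean <= sp$theta) "mixed"
        else "not_supported"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = sp$id, category = cat, expectation = sp$expectation,
        threshold = sp$theta, n = nrow(ent), min = vmin, max = vmax,
        mean = vmean, verdict = verdict, stringsAsFactors = FALSE)
      entries[[paste(sp$id, cat, sep = ".")]] <- ent
    }
  }
  rep <- do.call(rbind, rows)
  attr(rep, "entries") <- entries
  class(rep) <- c("hypothesis_report", "data.frame")
  rep
}

#' @export
print.hypothesis_report <- function(x, ...) {
  cat("<hypothesis_report>\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
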
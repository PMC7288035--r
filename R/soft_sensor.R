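#' Pair-disjoint train/validation/test split
#'
#' Randomly assigns each subject pair to exactly one of train, validation or
#' test, so that all images of a pair share its split and the classifier
#' cannot learn pair identity. Deterministic given the seed.
#'
#' @param study An `eeg_study`, or a character vector of pair IDs.
#' @param n_train,n_val,n_test Pair counts; must sum to the number of pairs
#'   (the study design uses 10/2/2 of 14, i.e. roughly 72/14/14 percent).
#' @param seed Integer seed.
#' @return A `split_plan` data frame (pair, split).
#' @export
plan_split <- function(study, n_train = 10, n_val = 2, n_test = 2, seed = 1) {
  pairs <- if (inherits(study, "eeg_study"))
    unique(vapply(study$recordings, function(r) r$labels$pair, "")) else
    unique(as.character(study))
  n <- length(pairs)
  if (n_train + n_val + n_test != n)
    stop(sprintf("split counts %d/%d/%d do not sum to the %d pairs",
                 n_train, n_val, n_test, n))
  perm <- with_seed(seed, sample(pairs))
  plan <- data.frame(
    pair = perm,
    split = rep(c("train", "validation", "test"), c(n_train, n_val, n_test)),
    stringsAsFactors = FALSE)
  plan <- plan[order(plan$pair), ]
  rownames(plan) <- NULL
  class(plan) <- c("split_plan", "data.frame")
  plan
}

#' Classifier architecture specification
#'
#' Four (by default) repeated blocks of convolution + ReLU + max-pooling,
#' then flatten, one dense ReLU layer, dropout, and a softmax output over the
#' four categories. Optimized with Adam under categorical cross-entropy.
#'
#' @param input_shape Image shape (height, width, channels); 360 x 360 x 3
#'   full-size, smaller for desk-scale training.
#' @param filters Convolution filter counts per block.
#' @param kernel Square kernel side (odd; same-padding).
#' @param pool Max-pool side/stride.
#' @param dense Width of the dense layer.
#' @param dropout Dropout rate in \[0, 1) on the dense layer.
#' @param n_classes Output width (4 categories).
#' @param lr Adam learning rate.
#' @param batch_size,epochs,patience Training schedule; early stopping
#'   restores the best-validation-loss weights after `patience` epochs
#'   without improvement.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(input_shape = c(360, 360, 3),
                            filters = c(16, 32, 64, 128), kernel = 3,
                            pool = 2, dense = 128, dropout = 0.2,
                            n_classes = 4, lr = 1e-3, batch_size = 32,
                            epochs = 30, patience = 5) {
  stopifnot(length(input_shape) == 3, kernel %% 2 == 1,
            dropout >= 0, dropout < 1, n_classes >= 2, length(filters) >= 1)
  h <- input_shape[1]; w <- input_shape[2]
  for (i in seq_along(filters)) {
    h <- h %/% pool; w <- w %/% pool
    if (h < 1 || w < 1) stop("input collapses to zero size at block ", i)
  }
  structure(list(input_shape = as.integer(input_shape),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), dense = as.integer(dense),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 flat = as.integer(h * w * filters[length(filters)])),
            class = "classifier_spec")
}

#' Number of trainable parameters of a classifier spec
#'
#' @param spec A [classifier_spec()].
#' @return Integer parameter count (weights + biases).
#' @export
n_params <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  cin <- spec$input_shape[3]
  total <- 0
  for (f in spec$filters) {
    total <- total + (cin * spec$kernel^2 + 1) * f
    cin <- f
  }
  total + (spec$flat + 1) * spec$dense + (spec$dense + 1) * spec$n_classes
}

#' Build an (untrained) soft-sensor classifier
#'
#' Initializes weights (He-normal, deterministic given the seed) for the
#' architecture described by `spec`.
#'
#' @param spec A [classifier_spec()].
#' @param seed Weight-initialization seed.
#' @return An `eeg_classifier`.
#' @export
build_classifier <- function(spec = classifier_spec(), seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  w <- cpp_cnn_init(spec$input_shape[1], spec$input_shape[2],
                    spec$input_shape[3], spec$filters, spec$kernel,
                    spec$pool, spec$dense, spec$n_classes, as.integer(seed))
  structure(list(spec = spec, weights = w, trained = FALSE,
                 history = NULL, seed = seed),
            class = "eeg_classifier")
}

#' @export
print.eeg_classifier <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<eeg_classifier> %dx%dx%d input, blocks [%s], dense %d, %s\n",
              s$input_shape[1], s$input_shape[2], s$input_shape[3],
              paste(s$filters, collapse = ","), s$dense,
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  %s parameters\n", format(n_params(s), big.mark = ",")))
  invisible(x)
}

#' @keywords internal
check_images <- function(images, spec) {
  d <- dim(images)
  if (length(d) != 4 || !all(d[1:3] == spec$input_shape))
    stop(sprintf("images must be a %dx%dx%dxN array; got [%s]",
                 spec$input_shape[1], spec$input_shape[2], spec$input_shape[3],
                 paste(d, collapse = "x")))
  invisible(d[4])
}

#' @keywords internal
category_index <- function(labels) {
  y <- match(as.character(labels), CATEGORIES)
  if (anyNA(y)) stop("unlabeled or unknown category in labels")
  y - 1L
}

#' Train the soft sensor with a pair-disjoint split
#'
#' Streams the training and validation images defined by `plan` through
#' mini-batch Adam; records per-epoch training/validation loss and accuracy,
#' and retains the weights of the best validation-loss epoch. Any test-pair
#' image in the training or validation stream is a hard error (leakage
#' guard).
#'
#' @param model An `eeg_classifier`.
#' @param images H x W x 3 x N array (values in \[0, 1\]) as produced by
#'   [study_images()].
#' @param meta Data frame with one row per image, columns `pair` and
#'   `category`.
#' @param plan A [plan_split()] plan covering every pair in `meta`.
#' @param epochs,batch_size,lr,patience Override the spec's schedule.
#' @param seed Shuffle/dropout seed.
#' @param verbose Print per-epoch progress.
#' @return The trained model; `$history` holds the epoch log.
#' @export
train_classifier <- function(model, images, meta, plan,
                             epochs = NULL, batch_size = NULL, lr = NULL,
                             patience = NULL, seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "eeg_classifier"), inherits(plan, "split_plan"),
            all(c("pair", "category") %in% names(meta)))
  n <- check_images(images, model$spec)
  if (nrow(meta) != n) stop("meta must have one row per image")
  if (!all(meta$pair %in% plan$pair)) stop("meta contains pairs missing from the plan")
  conflicted <- tapply(plan$split, plan$pair, function(s) length(unique(s)) > 1)
  if (any(conflicted))
    stop("leakage: pair assigned to more than one split: ",
         paste(names(conflicted)[conflicted], collapse = ", "))
  split_of <- stats::setNames(plan$split, plan$pair)[meta$pair]
  tr <- which(split_of == "train")
  va <- which(split_of == "validation")
  if (!length(tr) || !length(va)) stop("train and validation sets must be non-empty")
  test_pairs <- plan$pair[plan$split == "test"]
  if (any(meta$pair[c(tr, va)] %in% test_pairs))
    stop("leakage: test-pair images found in the training stream")
  sp <- model$spec
  fit <- cpp_cnn_train(
    images[, , , tr, drop = FALSE], category_index(meta$category[tr]),
    images[, , , va, drop = FALSE], category_index(meta$category[va]),
    model$weights, sp$filters, sp$kernel, sp$pool, sp$dense, sp$n_classes,
    epochs %||% sp$epochs, batch_size %||% sp$batch_size, lr %||% sp$lr,
    sp$dropout, patience %||% sp$patience, as.integer(seed), verbose)
  model$weights <- fit$weights
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model
}

#' @param object An `eeg_classifier`.
#' @param images H x W x 3 x N array matching the spec's input shape.
#' @param ... Unused.
#' @return N x 4 matrix of class probabilities (rows sum to 1).
#' @rdname build_classifier
#' @export
predict.eeg_classifier <- function(object, images, ...) {
  check_images(images, object$spec)
  sp <- object$spec
  p <- cpp_cnn_predict(images, object$weights, sp$filters, sp$kernel,
                       sp$pool, sp$dense, sp$n_classes)
  colnames(p) <- CATEGORIES
  p
}

#' Confusion matrix of the soft sensor on labeled images
#'
#' Argmax prediction per image, tallied into a 4 x 4 matrix with rows = true
#' category and columns = predicted category, in the fixed category order.
#'
#' @param model A trained `eeg_classifier`.
#' @param images H x W x 3 x N array.
#' @param labels Character/factor of true categories (one per image; an
#'   unlabeled image is an error).
#' @return A `confusion_matrix` (4 x 4 integer matrix).
#' @export
evaluate_classifier <- function(model, images, labels) {
  n <- check_images(images, model$spec)
  if (length(labels) != n) stop("one label per image is required")
  y <- category_index(labels)
  p <- predict(model, images)
  pred <- max.col(p, ties.method = "first") - 1L
  cm <- matrix(0L, 4, 4, dimnames = list(true = CATEGORIES, predicted = CATEGORIES))
  for (i in seq_len(n)) cm[y[i] + 1L, pred[i] + 1L] <- cm[y[i] + 1L, pred[i] + 1L] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Classification accuracy from a confusion matrix
#'
#' Sum of the diagonal (correctly classified counts of the four categories)
#' divided by the total count.
#'
#' @param cm Square count matrix.
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}
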
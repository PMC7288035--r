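tiny_spec <- function(...) {
  classifier_spec(input_shape = c(16, 16, 3), filters = c(4, 8), dense = 16,
                  ...)
}

tiny_images <- function(n, seed = 1) {
  set.seed(seed)
  array(runif(16 * 16 * 3 * n), c(16, 16, 3, n))
}

test_that("split plans partition pairs exhaustively and deterministically", {
  pairs <- sprintf("P%02d", 1:14)
  plan <- plan_split(pairs, 10, 2, 2, seed = 4)
  expect_setequal(plan$pair, pairs)
  expect_equal(unname(table(plan$split)[c("train", "validation", "test")]),
               c(10L, 2L, 2L), ignore_attr = TRUE)
  expect_identical(plan, plan_split(pairs, 10, 2, 2, seed = 4))
  expect_false(identical(plan, plan_split(pairs, 10, 2, 2, seed = 5)))
  expect_error(plan_split(pairs, 10, 2, 1, seed = 1), "do not sum")
})

test_that("image counts follow the split: 4 pairs at 2/1/1 give 960/480/480", {
  st <- generate_study(n_pairs = 4, seed = 6)   # full 60 s recordings
  plan <- plan_split(st, 2, 1, 1, seed = 6)
  nseg <- vapply(st$recordings, function(r) length(segment_recording(r)), 0L)
  expect_true(all(nseg == 120))
  pair_of <- vapply(st$recordings, function(r) r$labels$pair, "")
  imgs_per_split <- vapply(c("train", "validation", "test"), function(s) {
    sum(nseg[pair_of %in% plan$pair[plan$split == s]])
  }, 0L)
  expect_equal(unname(imgs_per_split), c(960L, 480L, 480L))
})

test_that("the classifier emits four probabilities summing to one", {
  m <- build_classifier(tiny_spec(), seed = 3)
  p <- predict(m, tiny_images(6))
  expect_equal(dim(p), c(6, 4))
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 6), tolerance = 1e-6)
  # deterministic weight init
  m2 <- build_classifier(tiny_spec(), seed = 3)
  expect_identical(predict(m2, tiny_images(6)), p)
  # shape guard
  expect_error(predict(m, array(0, c(8, 8, 3, 2))), "must be a 16x16x3")
})

test_that("parameter counts match the closed-form layer arithmetic", {
  # tiny: conv (3*9+1)*4 + (4*9+1)*8 ; flatten 4*4*8 = 128 ; dense/out
  expect_equal(n_params(tiny_spec()),
               112 + 296 + (128 + 1) * 16 + (16 + 1) * 4)
  # full-size default: 360 -> 180 -> 90 -> 45 -> 22, flatten 22*22*128
  sp <- classifier_spec()
  expect_equal(sp$flat, 22 * 22 * 128)
  expect_equal(n_params(sp),
               (3 * 9 + 1) * 16 + (16 * 9 + 1) * 32 + (32 * 9 + 1) * 64 +
                 (64 * 9 + 1) * 128 + (61952 + 1) * 128 + (128 + 1) * 4)
})

test_that("training records history and learns a separable toy problem", {
  # two visually distinct image families
  n <- 48
  X <- array(0, c(16, 16, 3, n))
  y <- rep(c("HKT_PO", "BSC_Leader"), each = n / 2)
  set.seed(2)
  for (i in seq_len(n)) {
    base <- if (y[i] == "HKT_PO") 0.9 else 0.1
    X[, , , i] <- base + rnorm(16 * 16 * 3, sd = 0.05)
  }
  meta <- data.frame(pair = rep(sprintf("P%02d", 1:8), times = n / 8),
                     category = y, stringsAsFactors = FALSE)
  # pairs were assigned cyclically so every pair holds both classes
  plan <- plan_split(sprintf("P%02d", 1:8), 5, 2, 1, seed = 1)
  sp <- tiny_spec(epochs = 2, batch_size = 8, patience = 5)
  m <- train_classifier(build_classifier(sp, seed = 1), X, meta, plan, seed = 1)
  expect_equal(nrow(m$history), 2)
  expect_true(all(c("train_loss", "val_loss", "train_acc", "val_acc") %in%
                    names(m$history)))
  sp2 <- tiny_spec(epochs = 15, batch_size = 8, patience = 15, lr = 5e-3,
                   dropout = 0)
  m2 <- train_classifier(build_classifier(sp2, seed = 1), X, meta, plan, seed = 1)
  expect_gt(max(m2$history$train_acc), 0.9)
})

test_that("test-pair images in the training stream are a hard error", {
  X <- tiny_images(8)
  meta <- data.frame(pair = rep(c("A", "B", "C", "D"), each = 2),
                     category = rep(CATS, 2), stringsAsFactors = FALSE)
  plan <- plan_split(c("A", "B", "C", "D"), 2, 1, 1, seed = 2)
  m <- build_classifier(tiny_spec(epochs = 1), seed = 1)
  # an image whose pair the plan does not cover
  meta_bad <- meta
  meta_bad$pair[1] <- "Z"
  expect_error(train_classifier(m, X, meta_bad, plan), "missing from the plan")
  # a tampered plan that routes the test pair into training as well
  plan2 <- rbind(plan, data.frame(pair = plan$pair[plan$split == "test"],
                                  split = "train"))
  class(plan2) <- class(plan)
  expect_error(train_classifier(m, X, meta, plan2), "leakage")
})

test_that("evaluation tallies argmax predictions with conserved row sums", {
  m <- build_classifier(tiny_spec(), seed = 1)
  X <- tiny_images(20)
  labels <- sample(CATS, 20, replace = TRUE)
  cm <- evaluate_classifier(m, X, labels)
  expect_equal(dim(cm), c(4, 4))
  expect_equal(unname(rowSums(cm)), unname(table(factor(labels, CATS))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 20)
  expect_error(evaluate_classifier(m, X, labels[1:3]), "one label per image")
  expect_error(evaluate_classifier(m, X, rep(NA, 20)), "unlabeled")
})

test_that("accuracy is trace over total", {
  expect_equal(accuracy(diag(c(5, 5, 5, 5))), 1)
  expect_equal(accuracy(matrix(3, 4, 4)), 0.25)
  cm <- matrix(c(50, 10, 0, 0,
                 5, 55, 0, 0,
                 0, 0, 60, 0,
                 0, 0, 20, 40), 4, 4, byrow = TRUE)
  expect_equal(accuracy(cm), 205 / 240)
  # matches the brute-force definition on random matrices
  set.seed(3)
  for (i in 1:5) {
    r <- matrix(sample(0:30, 16, TRUE), 4, 4)
    expect_equal(accuracy(r), sum(diag(r)) / sum(r))
  }
  expect_error(accuracy(matrix(0, 4, 4)), "empty")
})

test_that("accuracy is invariant to shuffling the evaluation set", {
  m <- build_classifier(tiny_spec(), seed = 2)
  X <- tiny_images(16, seed = 5)
  labels <- rep(CATS, each = 4)
  ord <- sample(16)
  a1 <- accuracy(evaluate_classifier(m, X, labels))
  a2 <- accuracy(evaluate_classifier(m, X[, , , ord, drop = FALSE], labels[ord]))
  expect_equal(a1, a2)
})
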
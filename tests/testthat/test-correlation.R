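test_that("correlation entries match the textbook formula", {
  x <- matrix(rnorm(16 * 100), 16)
  rec <- make_recording(x, rate = 100)
  m <- correlation_matrix(rec)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 16))
  for (pair in list(c(1, 2), c(3, 14), c(7, 16))) {
    expect_equal(m[pair[1], pair[2]],
                 pearson_bf(x[pair[1], ], x[pair[2], ]), tolerance = 1e-12)
  }
  # the 4-sample hand example
  expect_equal(pearson_bf(c(1, 2, 3, 4), c(2, 4, 5, 9)),
               cor(c(1, 2, 3, 4), c(2, 4, 5, 9)), tolerance = 1e-12)
})

test_that("identical and sign-flipped channels give r = 1 and r = -1", {
  x <- matrix(rnorm(16 * 50), 16)
  x[2, ] <- x[1, ]
  x[3, ] <- -x[1, ]
  m <- correlation_matrix(make_recording(x, rate = 50))
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], -1)
})

test_that("a zero-variance channel is an error naming the channel", {
  x <- matrix(rnorm(16 * 50), 16)
  x[6, ] <- 2
  expect_error(correlation_matrix(make_recording(x, rate = 50)),
               MONTAGE$channel[6])
})

test_that("the analysis span can exclude the 10 s leader-talks phase", {
  x <- matrix(rnorm(16 * 2560), 16)  # 20 s at 128 Hz
  rec <- make_recording(x)
  m <- correlation_matrix(rec, span = "exclude_first_10s")
  expect_equal(m[1, 2], pearson_bf(x[1, 1281:2560], x[2, 1281:2560]),
               tolerance = 1e-12)
})

test_that("averaging is elementwise, identity on one matrix, Fisher-z by default", {
  x <- matrix(rnorm(16 * 60), 16)
  m1 <- correlation_matrix(make_recording(x, rate = 60))
  expect_equal(average_correlation(list(m1)), m1,
               ignore_attr = "provenance")

  a <- diag_cor(); a[1, 2] <- a[2, 1] <- 0.2
  b <- diag_cor(); b[1, 2] <- b[2, 1] <- 0.8
  avg_a <- average_correlation(list(a, b), "arithmetic")
  expect_equal(avg_a[1, 2], 0.5)
  avg_f <- average_correlation(list(a, b), "fisher_z")
  expect_equal(avg_f[1, 2], tanh((atanh(0.2) + atanh(0.8)) / 2))
  same <- average_correlation(list(a, a))
  expect_equal(same[1, 2], 0.2)
  expect_error(average_correlation(list()), "empty")
})

test_that("group summaries enumerate the right entries", {
  m <- diag_cor()
  fr <- sensor_groups()$frontal
  oc <- sensor_groups()$occipital
  # identity matrix: all within-frontal off-diagonals are zero
  s <- group_summary(m, "frontal", relation = "within")
  expect_equal(s$n, 10)
  expect_equal(c(s$min, s$max), c(0, 0))
  expect_equal(group_summary(m, "occipital", relation = "within")$n, 3)

  m[fr, oc] <- 0.6; m[oc, fr] <- 0.6
  m[fr[1], oc[1]] <- m[oc[1], fr[1]] <- 0.3
  s2 <- group_summary(m, "frontal", "occipital", "between")
  expect_equal(s2$n, 15)
  expect_equal(s2$min, 0.3)
  expect_equal(s2$max, 0.6)
  expect_equal(s2$mean, (14 * 0.6 + 0.3) / 15)

  tp <- c(sensor_groups()$temporal, sensor_groups()$parietal)
  expect_equal(group_summary(m, "frontal", tp, "between")$n, 20)
  expect_error(group_summary(m, "frontal", "frontal", "between"), "disjoint")
  expect_error(group_summary(m, "frontal", "occipital", "within"), "identical")
})

test_that("difference matrices are antisymmetric with a symmetric colorscale", {
  a <- diag_cor(); a[1, 2] <- a[2, 1] <- 0.7
  b <- diag_cor(); b[1, 2] <- b[2, 1] <- 0.5
  d <- cor_difference(a, b)
  expect_equal(d[1, 2], 0.2)
  expect_equal(unname(diag(d)), rep(0, 16))
  expect_equal(unclass(cor_difference(b, a)), -unclass(d),
               ignore_attr = TRUE)
  expect_equal(attr(d, "zlim"), 0.2)
  expect_equal(cor_difference(a, a)[1, 2], 0)
  bad <- a; dimnames(bad) <- NULL
  expect_error(cor_difference(a, bad), "montage mismatch")
})

test_that("hypothesis verdicts follow the threshold rules", {
  mk <- function(fill) {
    m <- diag_cor()
    fr <- sensor_groups()$frontal
    m[fr, fr] <- fill; diag(m) <- 1
    m
  }
  mats <- list(HKT_PO = mk(0.7), HKT_Leader = mk(0.7),
               BSC_PO = mk(0.7), BSC_Leader = mk(0.7))
  rep <- evaluate_hypotheses(mats)
  h3 <- rep[rep$id == "H3", ]
  expect_true(all(h3$verdict == "supported"))
  # identity everywhere: strong expectations all unsupported
  id_mats <- list(HKT_PO = diag_cor(), HKT_Leader = diag_cor(),
                  BSC_PO = diag_cor(), BSC_Leader = diag_cor())
  rep_id <- evaluate_hypotheses(id_mats)
  strong <- rep_id[rep_id$expectation == "strong", ]
  expect_true(all(strong$verdict == "not_supported"))

  # mixed: frontal x temporal/parietal entries straddle the weak threshold
  m5 <- diag_cor()
  fr <- sensor_groups()$frontal
  tp <- c(sensor_groups()$temporal, sensor_groups()$parietal)
  m5[fr, tp] <- 0.28; m5[tp, fr] <- 0.28
  m5[fr[1], tp[4]] <- m5[tp[4], fr[1]] <- 0.65
  mats5 <- list(HKT_PO = m5, HKT_Leader = m5, BSC_PO = m5, BSC_Leader = m5)
  rep5 <- evaluate_hypotheses(mats5)
  h5 <- rep5[rep5$id == "H5", ]
  expect_true(all(h5$verdict == "mixed"))   # mean 0.30 <= 0.4 but max 0.65 > 0.4

  expect_error(evaluate_hypotheses(mats[1:2]), "missing category")
})

test_that("correlation is invariant under joint affine transforms", {
  x <- matrix(rnorm(16 * 200), 16)
  rec <- make_recording(x, rate = 100)
  rec2 <- make_recording(-2.5 * x + 7, rate = 100)
  m1 <- correlation_matrix(rec)
  m2 <- correlation_matrix(rec2)
  expect_equal(m1, m2, tolerance = 1e-12)
})
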
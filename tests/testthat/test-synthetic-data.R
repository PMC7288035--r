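test_that("montage has 16 uniquely named electrodes inside the head disk", {
  expect_equal(nrow(MONTAGE), 16)
  expect_false(anyDuplicated(MONTAGE$channel) > 0)
  expect_true(all(MONTAGE$x^2 + MONTAGE$y^2 <= 1))
  g <- sensor_groups()
  expect_equal(lengths(g[c("frontal", "occipital", "temporal", "parietal")]),
               c(frontal = 5L, occipital = 3L, temporal = 2L, parietal = 2L))
})

test_that("target matrix is built blockwise from directives over the baseline", {
  # no directives, zero baseline: identity
  p0 <- condition_profile("HKT_PO", baseline = 0)
  expect_equal(unname(build_target_correlation(p0)), diag(16),
               ignore_attr = TRUE)

  # one between directive 0.6 over baseline 0.1 (pre-projection construction)
  d <- data.frame(group_a = "frontal", group_b = "occipital",
                  relation = "between", level = 0.6)
  p1 <- condition_profile("HKT_PO", d, baseline = 0.1)
  m <- build_target_correlation(p1, project = FALSE)
  fr <- sensor_groups()$frontal
  oc <- sensor_groups()$occipital
  expect_equal(unname(m[fr, oc]), matrix(0.6, 5, 3))
  expect_equal(m["C3", "Cz"], 0.1)
  expect_equal(unname(diag(m)), rep(1, 16))
  expect_equal(m, t(m), ignore_attr = TRUE)
  # the projected version is PSD and still close to the construction
  mp <- suppressWarnings(build_target_correlation(p1))
  expect_gte(min(eigen(mp, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("unknown group names are a configuration error", {
  d <- data.frame(group_a = "sphenoidal", group_b = "occipital",
                  relation = "between", level = 0.5)
  p <- condition_profile("HKT_PO", d, baseline = 0)
  expect_error(build_target_correlation(p), "unknown sensor group")
})

test_that("infeasible directive sets are projected to PSD with reported delta", {
  # three groups pairwise -0.9 cannot all hold simultaneously
  d <- data.frame(group_a = c("frontal", "frontal", "occipital"),
                  group_b = c("occipital", "temporal", "temporal"),
                  relation = "between", level = -0.9)
  p <- condition_profile("HKT_PO", d, baseline = 0)
  expect_warning(m <- build_target_correlation(p), "not jointly feasible")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_gt(attr(m, "delta"), 0)
  expect_equal(unname(diag(m)), rep(1, 16))
})

test_that("every preset target is a valid correlation matrix", {
  for (preset in c("hypotheses", "well_separated", "identity")) {
    for (p in condition_profiles(preset)) {
      m <- build_target_correlation(p)
      expect_equal(m, t(m))
      expect_equal(unname(diag(m)), rep(1, 16))
      expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
      expect_lte(attr(m, "delta"), 0.05)
    }
  }
})

test_that("independent channels stay empirically uncorrelated", {
  rec <- simulate_recording(diag_cor(), 60, 128, drift_amp = 0, line_amp = 0,
                            seed = 7)
  r <- cor(t(rec$samples))
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)
})

test_that("simulation is byte-identical for a fixed seed and distinct otherwise", {
  a <- simulate_recording(diag_cor(), 2, 128, seed = 5)
  b <- simulate_recording(diag_cor(), 2, 128, seed = 5)
  c <- simulate_recording(diag_cor(), 2, 128, seed = 6)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("a 0.7 target entry is recovered within the replicate-simulation spread", {
  # tolerance frozen from 200 replicate simulations (60 s at 128 Hz, no
  # artifacts): |r_hat - 0.7| had 95% quantile 0.016 and maximum 0.023
  m <- diag_cor()
  m["Fp1", "Fp2"] <- m["Fp2", "Fp1"] <- 0.7
  rec <- simulate_recording(m, 60, 128, drift_amp = 0, line_amp = 0, seed = 31)
  expect_equal(cor(rec$samples["Fp1", ], rec$samples["Fp2", ]), 0.7,
               tolerance = 0.03)
})

test_that("a non-PSD target is rejected naming the eigenvalue", {
  m <- diag_cor()
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- -0.9
  expect_error(simulate_recording(m, 1, 128, seed = 1),
               "not positive semi-definite \\(eigenvalue")
})

test_that("generate_study produces n_pairs x 4 labeled recordings deterministically", {
  st <- generate_study(n_pairs = 1, seed = 3, duration_s = 2)
  expect_length(st$recordings, 4)
  cats <- vapply(st$recordings, function(r)
    eegsm:::category_label(r$labels$system, r$labels$role), "")
  expect_setequal(cats, CATS)

  st14 <- generate_study(n_pairs = 3, seed = 3, duration_s = 2)
  expect_length(st14$recordings, 12)
  # same global seed: identical; the first pair is unchanged by adding pairs
  st2 <- generate_study(n_pairs = 1, seed = 3, duration_s = 2)
  expect_identical(st$recordings[[1]]$samples, st2$recordings[[1]]$samples)
  expect_identical(st$recordings[[2]]$samples, st14$recordings[[2]]$samples)
  # different seed: different data
  st3 <- generate_study(n_pairs = 1, seed = 4, duration_s = 2)
  expect_false(identical(st$recordings[[1]]$samples, st3$recordings[[1]]$samples))
})

test_that("generate_study insists on four named profiles", {
  expect_error(generate_study(1, condition_profiles()[1:3], seed = 1,
                              duration_s = 2),
               "four condition profiles")
  expect_error(generate_study(0, seed = 1), "at least 1")
})

test_that("phase boundary metadata marks the leader-talks interval", {
  st <- generate_study(n_pairs = 1, seed = 8, duration_s = 2)
  expect_true(all(vapply(st$recordings, function(r) r$phase_boundary_s, 0) == 10))
})
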
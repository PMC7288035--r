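# shared fixtures, all built in code

MONTAGE <- eeg_montage()
CATS <- c("HKT_PO", "HKT_Leader", "BSC_PO", "BSC_Leader")

# a recording with known samples and labels
make_recording <- function(samples, rate = 128, pair = "P01",
                           role = "process_owner", system = "HKT") {
  eegsm:::new_recording(samples, rate, MONTAGE, pair = pair, role = role,
                        system = system)
}

diag_cor <- function() {
  m <- diag(16)
  dimnames(m) <- list(MONTAGE$channel, MONTAGE$channel)
  m
}

# independent brute-force Pearson (textbook formula, no stats::cor)
pearson_bf <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx2 <- dx2 + (x[i] - mx)^2
    dy2 <- dy2 + (y[i] - my)^2
  }
  num / sqrt(dx2 * dy2)
}

with_seed_helper <- function(seed, code) eegsm:::with_seed(seed, code)

# tiny 2-pair study reused by several files (cached per session)
.fixture_env <- new.env()
small_study <- function() {
  if (is.null(.fixture_env$small)) {
    st <- generate_study(n_pairs = 2, seed = 42, duration_s = 8)
    .fixture_env$small <- preprocess_study(st)
  }
  .fixture_env$small
}

# the full-size default study used by the acceptance checks (cached)
acceptance_study <- function() {
  if (is.null(.fixture_env$full)) {
    st <- generate_study(n_pairs = 14, seed = 2024)
    .fixture_env$full <- list(raw = st, prep = preprocess_study(st))
  }
  .fixture_env$full
}
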
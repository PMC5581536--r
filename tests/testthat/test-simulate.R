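test_that("profile error rate implements the count-weighted mean", {
  p1 <- quality_profile(20L, 100)
  expect_equal(profile_error_rate(p1), 0.01)
  # bins 0.1 and 0.01 with equal counts
  p2 <- quality_profile(c(10L, 20L), c(1, 1))
  expect_equal(profile_error_rate(p2), 0.055)
  set.seed(91)
  for (i in 1:20) {
    ph <- sample(0:40, 5)
    cnt <- matrix(runif(15, 1, 100), nrow = 3)
    pr <- quality_profile(ph, cnt)
    e <- 10^(-ph / 10)
    expect_gte(profile_error_rate(pr), min(e))
    expect_lte(profile_error_rate(pr), max(e))
  }
})

test_that("profile inflation hits the requested rate exactly", {
  pr <- quality_profile(c(30L, 10L), c(1000, 1))
  expect_identical(attr(inflate_profile(pr, profile_error_rate(pr)),
                        "added_count"), 0)
  out <- inflate_profile(pr, 0.02)
  expect_lt(abs(profile_error_rate(out) - 0.02), 1e-9)
  expect_true(all(out$counts - pr$counts >= 0))
  # unreachable target: above the unweighted bin mean
  expect_error(inflate_profile(pr, 0.9), "unreachable")
  # the deflation direction is equally unreachable
  expect_error(inflate_profile(pr, 1e-4), "unreachable")
})

test_that("the inflated rate moves monotonically toward the bin mean", {
  set.seed(92)
  for (i in 1:30) {
    ph <- sort(sample(3:40, 4))
    cnt <- runif(4, 1, 1000)
    pr <- quality_profile(ph, cnt)
    e <- 10^(-ph / 10)
    rates <- vapply(c(0, 1, 10, 100, 1e4, 1e6), function(C) {
      profile_error_rate(quality_profile(ph, cnt + C))
    }, numeric(1))
    expect_true(all(diff(rates) >= -1e-12) || all(diff(rates) <= 1e-12))
    expect_lt(abs(rates[length(rates)] - mean(e)), 1e-3)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_pairs = 50, seed = 31)
  a <- simulate_pairs(cfg)
  b <- simulate_pairs(cfg)
  expect_identical(a, b)
  d <- tempfile(); dir.create(d)
  simulate_pairs(cfg, out_prefix = file.path(d, "x"))
  simulate_pairs(cfg, out_prefix = file.path(d, "y"))
  expect_identical(read_fastq(file.path(d, "x_1.fq.gz")),
                   read_fastq(file.path(d, "y_1.fq.gz")))
  tr <- read_truth(file.path(d, "x_truth.tsv"))
  expect_equal(tr$insert_length, a$truth$insert_length)
  expect_equal(attr(tr, "read_length"), 125)
  unlink(d, recursive = TRUE)
})

test_that("error-free reads are exact insert/adapter concatenations", {
  sim <- simulate_pairs(sim_config(n_pairs = 300, error_rate = 0, seed = 37))
  rl <- 125
  with_ad <- which(!is.na(sim$truth$adapter_start))
  expect_gt(length(with_ad), 0)
  for (i in head(with_ad, 50)) {
    L <- sim$truth$insert_length[i]
    expect_equal(substr(sim$r1$seq[i], 1, L), sim$truth$insert_seq[i])
    got_ad <- substr(sim$r1$seq[i], L + 1, min(rl, L + 34))
    expect_equal(got_ad, substr(readtrim:::.TRUSEQ_R1, 1, nchar(got_ad)))
    # truth adapter_start is the first adapter base in the error-free read
    expect_equal(sim$truth$adapter_start[i], L)
  }
  # no-adapter geometry: insert at least the read length, zero adapter bases
  no_ad <- which(is.na(sim$truth$adapter_start))
  for (i in head(no_ad, 30)) {
    L <- sim$truth$insert_length[i]
    expect_gte(L, rl)
    expect_equal(sim$r1$seq[i], substr(sim$truth$insert_seq[i], 1, rl))
  }
})

test_that("the realised substitution rate matches the target within 3 SD", {
  sim <- simulate_pairs(sim_config(n_pairs = 20000, error_rate = 0.002,
                                   seed = 41))
  rl <- 125
  # compare reads to their error-free reconstruction over the insert part
  n_err <- 0L; n_tot <- 0L
  idx <- seq_len(1000)
  for (i in idx) {
    L <- min(sim$truth$insert_length[i], rl)
    truth_prefix <- substr(sim$truth$insert_seq[i], 1, L)
    got <- substr(sim$r1$seq[i], 1, L)
    n_err <- n_err + sum(charToRaw(got) != charToRaw(truth_prefix))
    n_tot <- n_tot + L
  }
  p <- sim$realized_error_rate
  sd3 <- 3 * sqrt(p * (1 - p) / n_tot)
  expect_lt(abs(n_err / n_tot - p), sd3 + 1e-9)
})

test_that("profile-driven simulation draws qualities from the profile", {
  ph <- c(20L, 30L)
  cnt <- matrix(rep(c(1, 3), each = 20), nrow = 20)
  pr <- quality_profile(ph, cnt)
  sim <- simulate_pairs(sim_config(n_pairs = 200, read_length = 20,
                                   adapter1 = "AGATCGGAAGAGC",
                                   adapter2 = "AGATCGGAAGAGC",
                                   profile = pr, seed = 43))
  qs <- unique(unlist(lapply(sim$r1$qual, phred_from_string)))
  expect_setequal(qs, ph)
})
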
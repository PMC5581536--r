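test_that("random match probability follows the binomial upper tail", {
  expect_equal(random_match_prob(0, 10), 1.0)
  expect_equal(random_match_prob(4, 4), 0.25^4)
  # direct summation of the three top binomial terms
  direct <- sum(choose(10, 8:10) * 0.25^(8:10) * 0.75^(2:0))
  expect_equal(random_match_prob(8, 10), direct, tolerance = 1e-12)
  expect_error(random_match_prob(5, 4), "exceed")
})

test_that("insert candidates recover the construction geometry", {
  set.seed(21)
  p <- default_params()
  pr <- build_pair(100)
  cands <- find_insert_candidates(pr$read1, pr$read2, p)
  expect_equal(cands$insert_length[1], 100)
  expect_equal(cands$overlap_len[1], 100)
  expect_equal(cands$mismatches[1], 0)

  # insert longer than the read: partial 3' overlap, no overhangs
  long <- build_pair(150)
  cl <- find_insert_candidates(long$read1, long$read2, p)
  expect_equal(cl$insert_length[1], 150)
  expect_equal(cl$overlap_len[1], 100)
})

test_that("unrelated random read pairs yield no candidates", {
  set.seed(22)
  p <- default_params()
  hits <- 0L
  for (i in 1:100) {
    r1 <- read_record("a", random_seq(125), rep(40L, 125))
    r2 <- read_record("a", random_seq(125), rep(40L, 125))
    hits <- hits + nrow(find_insert_candidates(r1, r2, p))
  }
  expect_equal(hits, 0L)
})

test_that("adapter confirmation is symmetric across the pair", {
  set.seed(23)
  p <- default_params()
  pr <- build_pair(100)
  cands <- find_insert_candidates(pr$read1, pr$read2, p)
  res <- confirm_adapters(cands[1, ], pr$read1, pr$read2, p)
  expect_s3_class(res, "insert_match_result")
  expect_true(res$adapter1_confirmed && res$adapter2_confirmed)
  expect_equal(res$insert_length, 100)

  # corrupt the read2 overhang: adapter1 alone still confirms, and the
  # same trim point applies to both reads
  r2bad <- pr$read2
  r2bad$bases <- paste0(substr(r2bad$bases, 1, 100), random_seq(25))
  res2 <- confirm_adapters(cands[1, ], pr$read1, r2bad, p)
  expect_true(res2$adapter1_confirmed)
  expect_false(res2$adapter2_confirmed)
  expect_equal(res2$insert_length, 100)

  # both overhangs random: no confirmation
  r1bad <- pr$read1
  r1bad$bases <- paste0(substr(r1bad$bases, 1, 100), random_seq(25))
  expect_null(confirm_adapters(cands[1, ], r1bad, r2bad, p))
})

test_that("error correction takes the higher-quality base as consensus", {
  # overlap of 4: read1 has an A@30 where rc(read2) has G@10
  r1 <- read_record("p", "AACG", c(30L, 30L, 30L, 30L))
  #      rc(read2) = GACG with G@10 at column 1 (mismatch vs A@30)
  r2 <- read_record("p", reverse_complement("GACG"), c(20L, 20L, 20L, 10L))
  res <- list(insert_length = 4L)
  ec <- error_correct(r1, r2, res, correction_policy("best"))
  expect_equal(ec$read1$bases, "AACG")
  expect_equal(ec$read2$bases, reverse_complement("AACG"))
  expect_equal(ec$corrections, 1L)
  # consensus quality becomes the max of the two
  expect_equal(rev(ec$read2$qualities)[1], 30L)

  # quality tie, mode N: both become N
  r1t <- read_record("p", "AAAA", rep(20L, 4))
  r2t <- read_record("p", reverse_complement("GAAA"), rep(20L, 4))
  ecN <- error_correct(r1t, r2t, res, correction_policy("N"))
  expect_equal(substr(ecN$read1$bases, 1, 1), "N")
  expect_equal(substr(reverse_complement(ecN$read2$bases), 1, 1), "N")
  expect_equal(ecN$corrections, 2L)

  # tie, mode keep: unchanged
  ecK <- error_correct(r1t, r2t, res, correction_policy("keep"))
  expect_equal(ecK$read1$bases, "AAAA")
  expect_equal(ecK$corrections, 0L)

  # tie, mode best: the read with higher mean quality wins
  r2b <- read_record("p", reverse_complement("GAAA"),
                     c(20L, 30L, 30L, 30L))
  ecB <- error_correct(r1t, r2b, res, correction_policy("best"))
  expect_equal(substr(r1t$bases, 1, 1), "A")
  expect_equal(substr(ecB$read1$bases, 1, 1), "G")

  # identical overlaps: zero corrections
  pr <- build_pair(60)
  ec0 <- error_correct(pr$read1, pr$read2, list(insert_length = 60L),
                       correction_policy("best"))
  expect_equal(ec0$corrections, 0L)
  expect_equal(ec0$read1$bases, pr$read1$bases)

  # mode none: untouched
  ecNone <- error_correct(r1, r2, res, correction_policy("none"))
  expect_identical(ecNone$read1, r1)
})

test_that("correction never decreases consensus quality", {
  set.seed(24)
  for (i in 1:25) {
    L <- sample(20:124, 1)
    pr <- build_pair(L, q = 30L)
    # inject disagreements with differing qualities
    b <- charToRaw(pr$read1$bases)
    pos <- sample(L, 5)
    b[pos] <- charToRaw("A")
    pr$read1$bases <- rawToChar(b)
    pr$read1$qualities[pos] <- sample(c(10L, 35L), 5, TRUE)
    ec <- error_correct(pr$read1, pr$read2, list(insert_length = L),
                        correction_policy("best"))
    expect_gte(min(ec$read1$qualities - pmin(pr$read1$qualities, 30L)), 0)
    expect_equal(nchar(ec$read1$bases), 125)
    expect_equal(nchar(ec$read2$bases), 125)
  }
})

test_that("merging produces one read covering the full insert", {
  set.seed(25)
  pr <- build_pair(100)
  res <- list(insert_length = 100L)
  class(res) <- "insert_match_result"
  m <- merge_pair(pr$read1, pr$read2, res)
  expect_equal(nchar(m$bases), 100)
  expect_equal(m$bases, pr$insert)

  long <- build_pair(150)
  resl <- list(insert_length = 150L)
  class(resl) <- "insert_match_result"
  ml <- merge_pair(long$read1, long$read2, resl)
  expect_equal(nchar(ml$bases), 150)    # 125 + 125 - 100
  expect_equal(ml$bases, long$insert)
})

test_that("insert path trims both mates to the insert length", {
  set.seed(26)
  p <- default_params()
  pr <- build_pair(100)
  res <- insert_trim_pair(pr$read1, pr$read2, p)
  expect_equal(res$outcome, "insert")
  expect_equal(nchar(res$read1$bases), 100)
  expect_equal(nchar(res$read2$bases), 100)
  expect_equal(res$read1$bases, pr$insert)
})

test_that("error-free pairs recover the exact insert length for every geometry", {
  set.seed(27)
  p <- default_params()
  for (L in seq(10, 124, by = 3)) {
    pr <- build_pair(L)
    res <- insert_trim_pair(pr$read1, pr$read2, p)
    expect_equal(nchar(res$read1$bases), L, info = paste("L =", L))
    expect_equal(nchar(res$read2$bases), L, info = paste("L =", L))
  }
})

test_that("adapter dimers fall back to adapter matching and trim to zero", {
  p <- default_params()
  q <- rep(40L, 125)
  set.seed(28)
  r1 <- read_record("d", substr(paste0(p$adapter1$sequence, random_seq(125)),
                                1, 125), q)
  r2 <- read_record("d", substr(paste0(p$adapter2$sequence, random_seq(125)),
                                1, 125), q)
  res <- insert_trim_pair(r1, r2, p)
  expect_equal(res$outcome, "adapter_fallback")
  expect_equal(nchar(res$read1$bases), 0)
  expect_equal(nchar(res$read2$bases), 0)
  expect_false(length_filter(res$read1, res$read2, 25))
})

test_that("adapter-free long-insert pairs pass through untouched", {
  set.seed(29)
  p <- default_params()
  # no 3' overlap at all (insert 300)
  ins <- random_seq(300)
  r1 <- read_record("x", substr(ins, 1, 125), rep(40L, 125))
  r2 <- read_record("x", substr(reverse_complement(ins), 1, 125),
                    rep(40L, 125))
  res <- insert_trim_pair(r1, r2, p)
  expect_equal(res$outcome, "untrimmed")
  expect_equal(nchar(res$read1$bases), 125)

  # partial 3' overlap (insert 150): recognised, nothing trimmed
  pr <- build_pair(150)
  res2 <- insert_trim_pair(pr$read1, pr$read2, p)
  expect_equal(res2$outcome, "insert_untrimmed")
  expect_equal(nchar(res2$read1$bases), 125)
})

test_that("whenever the insert path fires, trimmed mate lengths are equal", {
  set.seed(30)
  p <- default_params()
  for (i in 1:40) {
    L <- sample(10:200, 1)
    pr <- build_pair(L)
    # sprinkle a few substitution errors
    for (rd in c("read1", "read2")) {
      b <- charToRaw(pr[[rd]]$bases)
      pos <- sample(125, sample(0:2, 1))
      for (x in pos) b[x] <- charToRaw(sample(c("A", "C", "G", "T"), 1))
      pr[[rd]]$bases <- rawToChar(b)
    }
    res <- insert_trim_pair(pr$read1, pr$read2, p)
    if (res$outcome == "insert") {
      expect_equal(nchar(res$read1$bases), nchar(res$read2$bases))
    }
    expect_equal(res$read1$name, res$read2$name)
  }
})

test_that("a lopsided-quality mate is overwritten from the better mate", {
  set.seed(31)
  pr <- build_pair(80, q = 38L)
  # degrade read2: wrong bases at high error probability
  pr$read2$qualities <- rep(5L, 125)
  b <- charToRaw(pr$read2$bases)
  pos <- sample(80, 10)
  for (x in pos) b[x] <- charToRaw(sample(c("A", "C", "G", "T"), 1))
  pr$read2$bases <- rawToChar(b)
  p <- default_params()
  pol <- correction_policy("best", overwrite_poor_read = TRUE)
  res <- insert_trim_pair(pr$read1, pr$read2, p, pol)
  expect_equal(res$outcome, "insert")
  # after overwrite + trimming, read2 is the reverse complement of read1
  expect_equal(reverse_complement(res$read2$bases), res$read1$bases)
})
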
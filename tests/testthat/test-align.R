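test_that("a 3' adapter occurring as an exact suffix region is found", {
  sp <- adapter_spec("AGATCGGAA")
  loc <- semiglobal_align(sp, "CCCCCAGATCGGAA")
  expect_equal(loc$read_start, 5)
  expect_equal(loc$read_stop, 14)
  expect_equal(loc$matches, 9)
  expect_equal(loc$errors, 0)
})

test_that("no alignment is reported when every overlap is too noisy", {
  sp <- adapter_spec("AGATCGGAA")
  expect_null(semiglobal_align(sp, "CCCCCCCCCC"))
})

test_that("partial adapter occurrences running off the 3' end are found", {
  # only the first 5 adapter bases fit at the read end
  sp <- adapter_spec("AGATCGGAA")
  loc <- semiglobal_align(sp, "TTTTTTTTTTAGATC")
  expect_equal(loc$read_start, 10)
  expect_equal(loc$read_stop, 15)
  expect_equal(loc$adapter_stop, 5)
  expect_equal(loc$errors, 0)
})

test_that("5' adapters mirror the 3' semantics", {
  sp <- adapter_spec("AGATT", where = "front")
  loc <- semiglobal_align(sp, "AGATTCCCGG")
  expect_equal(loc$read_start, 0)
  expect_equal(loc$read_stop, 5)
  r <- read_record("x", "AGATTCCCGG", rep(30L, 10))
  expect_equal(trim_by_location(r, "front", loc)$bases, "CCCGG")
})

test_that("alignment agrees with the brute-force DP oracle", {
  set.seed(101)
  for (i in 1:150) {
    m <- sample(3:20, 1)
    n <- sample(3:20, 1)
    rate <- sample(c(0.1, 0.2, 0.3), 1)
    expect_same_alignment(random_seq(m), random_seq(n),
                          max_error_rate = rate)
  }
})

test_that("the column cost cutoff never changes the result", {
  set.seed(102)
  for (i in 1:150) {
    sp <- adapter_spec(random_seq(sample(4:25, 1)),
                       max_error_rate = sample(c(0.1, 0.2), 1))
    read <- random_seq(sample(5:60, 1))
    a <- semiglobal_align(sp, read, use_cutoff = TRUE)
    b <- semiglobal_align(sp, read, use_cutoff = FALSE)
    expect_identical(a, b)
  }
})

test_that("accepted alignments satisfy the acceptance rule", {
  set.seed(103)
  for (i in 1:200) {
    sp <- adapter_spec(random_seq(sample(3:15, 1)),
                       max_error_rate = 0.2, min_overlap = 4L)
    loc <- semiglobal_align(sp, random_seq(sample(4:40, 1)))
    if (is.null(loc)) next
    alen <- loc$adapter_stop - loc$adapter_start
    expect_gte(alen, 4)
    expect_lte(loc$errors / alen, 0.2 + 1e-9)
    expect_lte(loc$matches, alen)
  }
})

test_that("widening an adapter character to a superset code never loses matches", {
  set.seed(104)
  for (i in 1:100) {
    ad <- random_seq(sample(5:12, 1))
    read <- random_seq(sample(10:30, 1))
    base <- semiglobal_align(adapter_spec(ad), read)
    pos <- sample(nchar(ad), 1)
    wide <- paste0(substr(ad, 1, pos - 1), "N",
                   substr(ad, pos + 1, nchar(ad)))
    widened <- semiglobal_align(adapter_spec(wide), read)
    if (!is.null(base)) {
      expect_false(is.null(widened))
      expect_gte(widened$matches, base$matches)
    }
  }
})

test_that("N in the read mismatches concrete adapter characters but matches adapter N", {
  sp <- adapter_spec("AAAA", max_error_rate = 0)
  expect_null(semiglobal_align(sp, "CCCCNNNN"))
  spN <- adapter_spec("NNNN", max_error_rate = 0)
  loc <- semiglobal_align(spN, "CCCCNNNN")
  expect_equal(loc$matches, 4)
})

test_that("hamming fast path equals the aligner for anchored no-indel adapters", {
  expect_error(hamming_align(adapter_spec("ACGT"), "ACGTACGT"),
               "anchored")
  loc <- hamming_align(adapter_spec("AGATT", where = "front",
                                    anchored = TRUE, allow_indels = FALSE),
                       "AGATTCCC")
  expect_equal(c(loc$read_start, loc$read_stop, loc$errors), c(0, 5, 0))
  loc2 <- hamming_align(adapter_spec("AGATT", where = "front",
                                     anchored = TRUE, allow_indels = FALSE,
                                     max_error_rate = 0.2), "AGCTTCCC")
  expect_equal(c(loc2$errors, loc2$matches), c(1, 4))  # 1/5 = 0.2 allowed
  set.seed(105)
  for (i in 1:200) {
    where <- sample(c("back", "front"), 1)
    sp <- adapter_spec(random_seq(sample(3:10, 1)), where = where,
                       anchored = TRUE, allow_indels = FALSE,
                       max_error_rate = sample(c(0.1, 0.25, 0.4), 1))
    read <- random_seq(sample(nchar(sp$sequence):25, 1))
    h <- hamming_align(sp, read)
    s <- semiglobal_align(sp, read)
    if (is.null(h)) {
      expect_null(s)
    } else {
      expect_equal(h[c("read_start", "read_stop", "errors", "matches")],
                   s[c("read_start", "read_stop", "errors", "matches")])
    }
  }
})

test_that("trim_by_location removes the right span and qualities in lockstep", {
  r <- read_record("x", "CCCCCAGATCGGAA", c(rep(40L, 5), rep(10L, 9)))
  loc <- semiglobal_align(adapter_spec("AGATCGGAA"), r)
  tr <- trim_by_location(r, "back", loc)
  expect_equal(tr$bases, "CCCCC")
  expect_equal(tr$qualities, rep(40L, 5))
  expect_identical(trim_by_location(r, "back", NULL), r)
  bad <- list(read_start = 2, read_stop = 99)
  expect_error(trim_by_location(r, "back", bad), "outside")
})
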
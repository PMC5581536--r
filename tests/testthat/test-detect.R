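test_that("poly-A pre-trimming removes the run and everything 3' of it", {
  expect_equal(polyA_pretrim(paste0("CCGT", strrep("A", 8), "GTC")), "CCGT")
  inner <- paste0("CC", strrep("A", 7), "GG")
  expect_equal(polyA_pretrim(inner), inner)      # below the run length
  expect_equal(polyA_pretrim(strrep("A", 20)), "")
})

test_that("complexity is Shannon entropy in bits over base frequencies", {
  expect_equal(complexity("AAAAAA"), 0)
  expect_equal(complexity("ACGTACGT"), 2)
  expect_equal(complexity("AACC"), 1)    # exactly 1.0: NOT low-complexity
  expect_error(complexity(""), "empty")
  expect_true(all(complexity(c("ACGGGG", "ATATAT", "ACGTTT")) >= 0))
  expect_true(all(complexity(c("ACGGGG", "ATATAT", "ACGTTT")) <= 2))
})

test_that("the abundance threshold follows N(l-k+1)O/4^k", {
  p <- detect_params()   # N = 10000, O = 100
  thr <- abundance_threshold(p, l = 125, k = 12)
  expect_equal(thr, 10000 * (125 - 12 + 1) * 100 / 4^12)
  expect_gt(7, thr)      # counts of 7 and above qualify
  expect_lt(6, thr + 1)  # ... but 6 does not
  expect_equal(abundance_threshold(detect_params(sample_size = 1,
                                                 overrepresentation = 1),
                                   l = 4, k = 1), 1)
  expect_error(abundance_threshold(p, l = 10, k = 12), "exceed")
  # monotone in O: a huge factor disqualifies everything
  big <- detect_params(overrepresentation = 1e12)
  expect_gt(abundance_threshold(big, 125, 12), 1e6)
})

test_that("a planted adapter is recovered as the top hit and labelled", {
  set.seed(61)
  planted <- "AGATCGGAAGAGCACACGTCTGAA"   # 24 bases
  reads <- random_reads(10000, 125)
  carry <- seq_len(10000) %% 10 < 4
  reads[carry] <- planted_reads(sum(carry), planted)
  params <- detect_params(known_contaminants = default_contaminants())
  rep <- detect_adapters(reads, params)
  expect_gt(nrow(rep), 0)
  expect_true(grepl(planted, rep$sequence[1], fixed = TRUE) ||
                grepl(rep$sequence[1], planted, fixed = TRUE))
  expect_match(rep$known_name[1], "TruSeq")
  expect_gte(rep$known_identity[1], 0.9)
})

test_that("adapter-free random reads produce an empty report", {
  set.seed(62)
  for (trial in 1:3) {
    reads <- random_reads(10000, 125)
    rep <- detect_adapters(reads, detect_params())
    expect_equal(nrow(rep), 0)
  }
})

test_that("identical reads merge into a single containment-free hit", {
  reads <- rep("ACGTTGCAACGGTCAGTCCATGCATTGCA", 500)
  rep <- detect_adapters(reads, detect_params(sample_size = 500))
  expect_equal(nrow(rep), 1)
  expect_equal(rep$sequence[1], reads[1])  # assembled back to the full read
})

test_that("report invariants: no containment, counts above threshold, capped size", {
  set.seed(63)
  planted <- "AGATCGGAAGAGCACACGTCTGAA"
  reads <- random_reads(10000, 125)
  carry <- seq_len(10000) %% 2 == 0
  reads[carry] <- planted_reads(sum(carry), planted, pre_range = 55:65)
  params <- detect_params()
  rep <- detect_adapters(reads, params)
  expect_lte(nrow(rep), params$max_report)
  if (nrow(rep) > 1) {
    for (i in seq_len(nrow(rep))) {
      others <- rep$sequence[-i]
      expect_false(any(vapply(others, grepl, logical(1),
                              x = rep$sequence[i], fixed = TRUE)))
    }
  }
  l <- 125
  for (i in seq_len(nrow(rep))) {
    thr <- abundance_threshold(params, l, rep$kmer_len[i])
    expect_gt(rep$count[i], thr)
  }
})

test_that("an empty sample warns and returns an empty report", {
  expect_warning(out <- detect_adapters(character(0), detect_params()),
                 "empty")
  expect_equal(nrow(out), 0)
})
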
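test_that("identical reads give point-mass distributions", {
  df <- data.frame(name = sprintf("r%d", 1:100),
                   seq = rep("ACGC", 100), qual = rep("IIII", 100))
  qc <- collect_qc(df, "pre")
  expect_equal(qc$n_reads, 100)
  expect_equal(qc$n_bases, 400)
  # per-position quality: all mass at q40
  expect_true(all(qc$per_position_quality[, "40"] == 100))
  expect_equal(sum(qc$per_position_quality), 400)
  # GC content of ACGC is 75%
  expect_equal(qc$gc_hist[75 + 1], 100)
  expect_equal(sum(qc$gc_hist), 100)
  expect_equal(qc$length_hist[4 + 1], 100)
  # column sums of position x Phred matrix equal covering read counts
  expect_true(all(rowSums(qc$per_position_quality) == 100))
  expect_true(all(rowSums(qc$base_composition) == 100))
})

test_that("merging summaries equals collecting over the concatenation", {
  set.seed(81)
  sim <- simulate_pairs(sim_config(n_pairs = 120, seed = 19))
  a <- sim$r1[1:50, ]
  b <- sim$r1[51:120, ]
  merged <- merge_qc(collect_qc(a, "pre"), collect_qc(b, "pre"))
  whole <- collect_qc(sim$r1, "pre")
  expect_equal(merged$per_position_quality, whole$per_position_quality)
  expect_equal(merged$base_composition, whole$base_composition)
  expect_equal(merged$gc_hist, whole$gc_hist)
  expect_equal(merged$mean_quality_hist, whole$mean_quality_hist)
  expect_equal(merged$length_hist, whole$length_hist)
  expect_equal(merged$n_bases, whole$n_bases)
})

test_that("QC collection never alters trimming output", {
  set.seed(82)
  d <- tempfile(); dir.create(d)
  simulate_pairs(sim_config(n_pairs = 100, seed = 23),
                 out_prefix = file.path(d, "in"))
  base <- trim_config(adapter1 = readtrim:::.TRUSEQ_R1,
                      adapter2 = readtrim:::.TRUSEQ_R2)
  withqc <- trim_config(adapter1 = readtrim:::.TRUSEQ_R1,
                        adapter2 = readtrim:::.TRUSEQ_R2, qc = "both")
  for (cfg in list(base, withqc)) {
    run_pipeline(cfg, in1 = file.path(d, "in_1.fq.gz"),
                 in2 = file.path(d, "in_2.fq.gz"),
                 out1 = file.path(d, if (identical(cfg$qc, "none"))
                   "a_1.fq" else "b_1.fq"),
                 out2 = file.path(d, if (identical(cfg$qc, "none"))
                   "a_2.fq" else "b_2.fq"))
  }
  expect_equal(read_fastq(file.path(d, "a_1.fq")),
               read_fastq(file.path(d, "b_1.fq")))
  unlink(d, recursive = TRUE)
})

test_that("post-trim 3' quality is no worse than pre-trim", {
  set.seed(83)
  n <- 200
  quals <- vapply(1:n, function(i) {
    phred_to_string(c(sample(25:40, 40, TRUE), sample(2:18, 10, TRUE)))
  }, character(1))
  df <- data.frame(name = sprintf("r%d", 1:n),
                   seq = vapply(1:n, function(i) random_seq(50),
                                character(1)),
                   qual = quals)
  pre <- collect_qc(df, "pre")
  post_df <- readtrim:::df_quality_trim(df, 20, FALSE)
  post <- collect_qc(post_df, "post")
  tail_mean <- function(qc) {
    m <- qc$per_position_quality
    rows <- seq(max(1, nrow(m) - 9), nrow(m))
    w <- m[rows, , drop = FALSE]
    sum(t(w) * (0:93)) / sum(w)
  }
  expect_gte(tail_mean(post), tail_mean(pre))
})

test_that("QC JSON round-trips losslessly and byte-stably", {
  set.seed(84)
  sim <- simulate_pairs(sim_config(n_pairs = 40, seed = 29))
  qc <- collect_qc(sim$r1, "pre")
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_qc_json(list(pre = qc), f1)
  back <- read_qc_json(f1)
  expect_equal(back$pre$per_position_quality, qc$per_position_quality)
  expect_equal(back$pre$n_reads, qc$n_reads)
  write_qc_json(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty input yields a zeroed summary that still serializes
  empty <- collect_qc(data.frame(name = character(0), seq = character(0),
                                 qual = character(0)), "pre")
  expect_equal(empty$n_reads, 0)
  f3 <- tempfile(fileext = ".json")
  write_qc_json(list(pre = empty), f3)
  expect_equal(read_qc_json(f3)$pre$n_bases, 0)
  unlink(c(f1, f2, f3))
})
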
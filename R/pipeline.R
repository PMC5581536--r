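# Per-read modifiers, filters and the end-to-end trimming pipeline.

#' Trim low-quality bases from the 3' end of a read
#'
#' Partial-sum method: scanning from the 3' end, the running sum of
#' `(cutoff - q)` is accumulated and the read is cut at the position where
#' that sum is maximal (equivalently, the suffix a brute-force search over
#' all cut points identifies as optimal is removed). Ties keep the longer
#' read; `cutoff = 0` is the identity.
#'
#' @param read A [read_record()].
#' @param cutoff Phred quality threshold.
#' @return The trimmed [read_record()].
#' @export
quality_trim <- function(read, cutoff) {
  stopifnot(inherits(read, "read_record"), cutoff >= 0)
  if (cutoff == 0) return(read)
  keep <- cpp_quality_trim_index(read$bases, phred_to_string(read$qualities),
                                 as.integer(cutoff), FALSE)
  shorten_record(read, keep)
}

#' Quality trimming for two-channel (NextSeq) chemistry
#'
#' NextSeq instruments encode G as the absence of signal ("dark" cycles),
#' so a run of G calls at the 3' end can be an artifact carrying spuriously
#' high quality. The scan is the same as [quality_trim()], but G bases are
#' treated as quality 0, so trailing G runs are removed regardless of their
#' claimed quality.
#'
#' @inheritParams quality_trim
#' @export
nextseq_trim <- function(read, cutoff) {
  stopifnot(inherits(read, "read_record"), cutoff >= 1)
  keep <- cpp_quality_trim_index(read$bases, phred_to_string(read$qualities),
                                 as.integer(cutoff), TRUE)
  shorten_record(read, keep)
}

#' Remove a fixed number of bases from the read ends
#'
#' @inheritParams quality_trim
#' @param front_n,back_n Number of leading / trailing bases to remove
#'   unconditionally (clamped at the read length).
#' @export
fixed_trim <- function(read, front_n = 0L, back_n = 0L) {
  stopifnot(inherits(read, "read_record"), front_n >= 0, back_n >= 0)
  n <- nchar(read$bases)
  from <- min(front_n, n) + 1L
  to <- max(from - 1L, n - back_n)
  keep <- seq_len(n) >= from & seq_len(n) <= to
  read_record(read$name, substr(read$bases, from, to),
              read$qualities[keep], mate = read$mate)
}

#' Trim a linked (5' + 3') adapter pair
#'
#' Finds the 5' adapter first; the 3' adapter is then searched only
#' downstream of it, and the span between the two is retained. If the 5'
#' adapter is absent the read is returned with attribute
#' `linked_untrimmed = TRUE`.
#'
#' @inheritParams quality_trim
#' @param five_prime A `"front"` [adapter_spec()] (anchored by default use).
#' @param three_prime A `"back"` [adapter_spec()].
#' @export
linked_adapter_trim <- function(read, five_prime, three_prime) {
  stopifnot(inherits(read, "read_record"),
            inherits(five_prime, "adapter_spec"),
            inherits(three_prime, "adapter_spec"),
            five_prime$where == "front", three_prime$where == "back")
  loc5 <- semiglobal_align(five_prime, read)
  if (is.null(loc5)) {
    attr(read, "linked_untrimmed") <- TRUE
    return(read)
  }
  read <- trim_by_location(read, "front", loc5)
  loc3 <- semiglobal_align(three_prime, read)
  trim_by_location(read, "back", loc3)
}

#' Length filter for trimmed reads
#'
#' A pair is discarded when either mate is shorter than `min_length`
#' after trimming; short-insert reads map spuriously and are conventionally
#' dropped.
#'
#' @param read1 A [read_record()].
#' @param read2 A [read_record()] or `NULL` for single-end data.
#' @param min_length Minimum kept length in bases.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
length_filter <- function(read1, read2 = NULL, min_length) {
  stopifnot(min_length >= 0)
  ok <- nchar(read1$bases) >= min_length
  if (!is.null(read2)) ok <- ok && nchar(read2$bases) >= min_length
  ok
}

#' Configuration for the trimming pipeline
#'
#' @param adapter1,adapter2 3' adapters for read 1 / read 2
#'   ([adapter_spec()] or IUPAC string); `adapter2` is ignored for
#'   single-end input.
#' @param aligner `"insert"` (paired-end insert matching with adapter-match
#'   fallback) or `"adapter"` (independent semi-global adapter matching in
#'   each read).
#' @param quality_cutoff Phred threshold for 3' quality trimming; 0
#'   disables.
#' @param nextseq_mode Use two-channel (poly-G aware) quality trimming.
#' @param cut_front,cut_back Fixed numbers of bases removed from each read
#'   before any matching.
#' @param min_length Minimum read length after trimming; shorter pairs are
#'   discarded. Default 25.
#' @param min_insert_overlap,max_mismatch_frac,max_random_match_prob
#'   Insert-match specificity thresholds, see [insert_match_params()].
#' @param correction A [correction_policy()]. Default: no correction.
#' @param threads Number of worker processes. Default 1.
#' @param output_mode `"worker"` (workers compress, one serializer writes),
#'   `"writer"` (one serializer compresses and writes), `"parallel"` (each
#'   worker writes its own files) or `"auto"` (worker compression at 8+
#'   threads, writer compression below).
#' @param batch_size Reads per worker batch. Default 5000.
#' @param qc Collect quality-control metrics: `"none"`, `"pre"`, `"post"`
#'   or `"both"`.
#' @return An object of class `trim_config`.
#' @export
trim_config <- function(adapter1 = NULL, adapter2 = NULL,
                        aligner = c("insert", "adapter"),
                        quality_cutoff = 0L, nextseq_mode = FALSE,
                        cut_front = 0L, cut_back = 0L, min_length = 25L,
                        min_insert_overlap = 10L, max_mismatch_frac = 0.2,
                        max_random_match_prob = 1e-6,
                        correction = correction_policy("none"),
                        threads = 1L,
                        output_mode = c("auto", "worker", "writer",
                                        "parallel"),
                        batch_size = 5000L, qc = c("none", "pre", "post",
                                                   "both")) {
  aligner <- match.arg(aligner)
  output_mode <- match.arg(output_mode)
  qc <- match.arg(qc)
  if (is.character(adapter1)) adapter1 <- adapter_spec(adapter1)
  if (is.character(adapter2)) adapter2 <- adapter_spec(adapter2)
  stopifnot(min_length >= 0, threads >= 1, batch_size >= 1,
            inherits(correction, "correction_policy"))
  structure(list(adapter1 = adapter1, adapter2 = adapter2,
                 aligner = aligner,
                 quality_cutoff = as.integer(quality_cutoff),
                 nextseq_mode = nextseq_mode,
                 cut_front = as.integer(cut_front),
                 cut_back = as.integer(cut_back),
                 min_length = as.integer(min_length),
                 min_insert_overlap = as.integer(min_insert_overlap),
                 max_mismatch_frac = max_mismatch_frac,
                 max_random_match_prob = max_random_match_prob,
                 correction = correction, threads = as.integer(threads),
                 output_mode = output_mode,
                 batch_size = as.integer(batch_size), qc = qc),
            class = "trim_config")
}

config_insert_params <- function(config) {
  insert_match_params(config$adapter1, config$adapter2,
                      min_insert_overlap = config$min_insert_overlap,
                      max_mismatch_frac = config$max_mismatch_frac,
                      max_random_match_prob = config$max_random_match_prob)
}

# ---- batch processing ------------------------------------------------------

# Apply the modifier stack to one batch of records.  `r2` may be NULL
# (single-end).  Returns list(r1, r2, stats).
process_batch <- function(r1, r2, config) {
  n <- nrow(r1)
  stats <- empty_stats(paired = !is.null(r2))
  stats$pairs_read <- n
  if (!n) return(list(r1 = r1, r2 = r2, stats = stats))

  # fixed-base trimming first: removes technical bases before any matching
  if (config$cut_front > 0L || config$cut_back > 0L) {
    pre <- nchar(r1$seq)
    r1 <- df_fixed_trim(r1, config$cut_front, config$cut_back)
    stats$bases_fixed <- stats$bases_fixed + sum(pre - nchar(r1$seq))
    if (!is.null(r2)) {
      pre <- nchar(r2$seq)
      r2 <- df_fixed_trim(r2, config$cut_front, config$cut_back)
      stats$bases_fixed <- stats$bases_fixed + sum(pre - nchar(r2$seq))
    }
  }

  # adapter removal
  if (config$aligner == "insert" && !is.null(r2)) {
    params <- config_insert_params(config)
    policy <- config$correction
    pre1 <- nchar(r1$seq); pre2 <- nchar(r2$seq)
    # work on plain vectors: element assignment into data-frame columns
    # copies the whole column every time
    seq1 <- r1$seq; qual1 <- r1$qual
    seq2 <- r2$seq; qual2 <- r2$qual
    nm1 <- r1$name; nm2 <- r2$name
    outcomes <- character(n)
    for (i in seq_len(n)) {
      rec1 <- structure(list(name = nm1[i], bases = seq1[i],
                             qualities = phred_from_string(qual1[i]),
                             mate = 1L), class = "read_record")
      rec2 <- structure(list(name = nm2[i], bases = seq2[i],
                             qualities = phred_from_string(qual2[i]),
                             mate = 2L), class = "read_record")
      res <- insert_trim_pair(rec1, rec2, params, policy)
      outcomes[i] <- res$outcome
      seq1[i] <- res$read1$bases
      qual1[i] <- phred_to_string(res$read1$qualities)
      seq2[i] <- res$read2$bases
      qual2[i] <- phred_to_string(res$read2$qualities)
    }
    r1$seq <- seq1; r1$qual <- qual1
    r2$seq <- seq2; r2$qual <- qual2
    tab <- table(outcomes)
    stats$outcomes[names(tab)] <- stats$outcomes[names(tab)] + as.vector(tab)
    stats$reads_with_adapter <-
      stats$reads_with_adapter + sum(nchar(r1$seq) < pre1) +
      sum(nchar(r2$seq) < pre2)
    stats$bases_adapter <- stats$bases_adapter +
      sum(pre1 - nchar(r1$seq)) + sum(pre2 - nchar(r2$seq))
  } else if (!is.null(config$adapter1)) {
    pre <- nchar(r1$seq)
    r1 <- df_adapter_trim(r1, config$adapter1)
    stats$reads_with_adapter <- stats$reads_with_adapter +
      sum(nchar(r1$seq) < pre)
    stats$bases_adapter <- stats$bases_adapter + sum(pre - nchar(r1$seq))
    if (!is.null(r2)) {
      ad2 <- if (is.null(config$adapter2)) config$adapter1
             else config$adapter2
      pre <- nchar(r2$seq)
      r2 <- df_adapter_trim(r2, ad2)
      stats$reads_with_adapter <- stats$reads_with_adapter +
        sum(nchar(r2$seq) < pre)
      stats$bases_adapter <- stats$bases_adapter + sum(pre - nchar(r2$seq))
    }
    stats$outcomes[["adapter_match"]] <- n
  }

  # quality trimming after adapter removal
  if (config$quality_cutoff > 0L || config$nextseq_mode) {
    cutoff <- max(config$quality_cutoff,
                  if (config$nextseq_mode) 1L else 0L)
    pre <- nchar(r1$seq)
    r1 <- df_quality_trim(r1, cutoff, config$nextseq_mode)
    stats$bases_quality <- stats$bases_quality + sum(pre - nchar(r1$seq))
    if (!is.null(r2)) {
      pre <- nchar(r2$seq)
      r2 <- df_quality_trim(r2, cutoff, config$nextseq_mode)
      stats$bases_quality <- stats$bases_quality + sum(pre - nchar(r2$seq))
    }
  }

  # minimum-length filter
  keep <- nchar(r1$seq) >= config$min_length
  if (!is.null(r2)) keep <- keep & nchar(r2$seq) >= config$min_length
  stats$pairs_written <- sum(keep)
  stats$pairs_discarded <- n - sum(keep)
  list(r1 = r1[keep, , drop = FALSE],
       r2 = if (!is.null(r2)) r2[keep, , drop = FALSE],
       stats = stats)
}

df_fixed_trim <- function(df, front_n, back_n) {
  n <- nchar(df$seq)
  from <- pmin(front_n, n) + 1L
  to <- pmax(from - 1L, n - back_n)
  df$seq <- substr(df$seq, from, to)
  df$qual <- substr(df$qual, from, to)
  df
}

df_quality_trim <- function(df, cutoff, nextseq) {
  keep <- cpp_quality_trim_index(df$seq, df$qual, as.integer(cutoff),
                                 nextseq)
  df$seq <- substr(df$seq, 1L, keep)
  df$qual <- substr(df$qual, 1L, keep)
  df
}

df_adapter_trim <- function(df, adapter) {
  seqs <- df$seq; quals <- df$qual
  for (i in seq_along(seqs)) {
    loc <- semiglobal_align(adapter, seqs[i])
    if (is.null(loc)) next
    if (adapter$where == "back") {
      seqs[i] <- substr(seqs[i], 1L, loc$read_start)
      quals[i] <- substr(quals[i], 1L, loc$read_start)
    } else {
      n <- nchar(seqs[i])
      seqs[i] <- substr(seqs[i], loc$read_stop + 1L, n)
      quals[i] <- substr(quals[i], loc$read_stop + 1L, n)
    }
  }
  df$seq <- seqs
  df$qual <- quals
  df
}

# ---- statistics ------------------------------------------------------------

empty_stats <- function(paired = TRUE) {
  structure(list(pairs_read = 0L, pairs_written = 0L, pairs_discarded = 0L,
                 reads_with_adapter = 0L, bases_fixed = 0L,
                 bases_adapter = 0L, bases_quality = 0L,
                 outcomes = c(insert = 0L, insert_untrimmed = 0L,
                              adapter_fallback = 0L, untrimmed = 0L,
                              adapter_match = 0L),
                 paired = paired, output_files = character(0)),
            class = "trim_stats")
}

merge_stats <- function(a, b) {
  for (f in c("pairs_read", "pairs_written", "pairs_discarded",
              "reads_with_adapter", "bases_fixed", "bases_adapter",
              "bases_quality")) {
    a[[f]] <- a[[f]] + b[[f]]
  }
  a$outcomes <- a$outcomes + b$outcomes
  a$output_files <- union(a$output_files, b$output_files)
  a
}

#' @export
print.trim_stats <- function(x, ...) {
  unit <- if (x$paired) "pairs" else "reads"
  cat("<trim_stats>\n",
      sprintf("  %s read:      %d\n", unit, x$pairs_read),
      sprintf("  %s written:   %d\n", unit, x$pairs_written),
      sprintf("  %s discarded: %d\n", unit, x$pairs_discarded),
      sprintf("  reads with adapter: %d\n", x$reads_with_adapter),
      sprintf("  bases removed (fixed/adapter/quality): %d/%d/%d\n",
              x$bases_fixed, x$bases_adapter, x$bases_quality),
      sep = "")
  oc <- x$outcomes[x$outcomes > 0]
  if (length(oc)) {
    cat("  outcomes:", paste(names(oc), oc, sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Convert trimming statistics to a JSON summary
#'
#' @param stats A `trim_stats` object as returned by [run_pipeline()].
#' @param path Optional path to write the JSON document to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
stats_to_json <- function(stats, path = NULL) {
  obj <- list(schema = "readtrim/stats/1",
              pairs = list(read = stats$pairs_read,
                           written = stats$pairs_written,
                           discarded = stats$pairs_discarded),
              reads_with_adapter = stats$reads_with_adapter,
              bases_removed = list(fixed = stats$bases_fixed,
                                   adapter = stats$bases_adapter,
                                   quality = stats$bases_quality),
              outcomes = as.list(stats$outcomes),
              output_files = stats$output_files)
  if (!is.null(stats$qc_pre)) obj$qc_pre <- qc_to_list(stats$qc_pre)
  if (!is.null(stats$qc_post)) obj$qc_post <- qc_to_list(stats$qc_post)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

# ---- the pipeline ----------------------------------------------------------

#' Run the trimming pipeline on FASTQ files
#'
#' Execution contract: a reader cursor produces fixed-size batches
#' preserving file order; worker processes apply the full modifier and
#' filter stack to whole batches; output is written according to
#' `config$output_mode`. In `"worker"` mode each worker gzip-compresses its
#' batch and a single serializer concatenates the compressed members into
#' one ordered stream; in `"writer"` mode a single serializer compresses
#' and writes one stream; in `"parallel"` mode each worker writes its own
#' output file pair (gzip members, safe to concatenate). All modes yield
#' the same multiset of output records, and read pairs remain in sync
#' within any one output stream.
#'
#' @param config A [trim_config()].
#' @param in1,in2 Input FASTQ paths (`in2 = NULL` for single-end or
#'   interleaved input).
#' @param out1,out2 Output FASTQ paths. With paired input and `out2 = NULL`
#'   the output is interleaved. In `"parallel"` mode the worker index is
#'   inserted before the file extension.
#' @param interleaved Treat `in1` as interleaved paired-end input.
#' @return A `trim_stats` object; `$output_files` lists every file written.
#' @export
run_pipeline <- function(config, in1, in2 = NULL, out1, out2 = NULL,
                         interleaved = FALSE) {
  stopifnot(inherits(config, "trim_config"))
  if (!dir.exists(dirname(out1))) {
    stop("output not writable: ", out1, call. = FALSE)
  }
  input <- read_fastq_pair(in1, in2, interleaved)
  paired <- !is.null(input$r2)
  mode <- config$output_mode
  if (mode == "auto") mode <- if (config$threads >= 8L) "worker" else "writer"

  n <- nrow(input$r1)
  starts <- seq(1L, max(n, 1L), by = config$batch_size)
  if (!n) starts <- integer(0)
  batches <- lapply(starts, function(s) {
    idx <- s:min(s + config$batch_size - 1L, n)
    list(r1 = input$r1[idx, , drop = FALSE],
         r2 = if (paired) input$r2[idx, , drop = FALSE])
  })

  qc_pre <- if (config$qc %in% c("pre", "both")) {
    collect_qc(rbind(input$r1, if (paired) input$r2), stage = "pre")
  }

  worker <- function(b) process_batch(b$r1, b$r2, config)
  results <- if (config$threads > 1L && length(batches) > 1L) {
    parallel::mclapply(batches, worker, mc.cores = config$threads)
  } else {
    lapply(batches, worker)
  }
  for (r in results) {
    if (inherits(r, "try-error") || !is.list(r)) {
      stop("worker failed: ", paste(r, collapse = " "), call. = FALSE)
    }
  }

  stats <- Reduce(merge_stats, lapply(results, `[[`, "stats"),
                  empty_stats(paired))
  stats$paired <- paired

  out_r2 <- !is.null(out2) && paired
  written <- character(0)
  if (mode %in% c("worker", "writer")) {
    texts1 <- lapply(results, function(r) {
      fastq_lines(if (paired && !out_r2) interleave_records(r$r1, r$r2)
                  else r$r1)
    })
    texts2 <- if (out_r2) lapply(results, function(r) fastq_lines(r$r2))
    if (mode == "worker" && grepl("\\.gz$", out1)) {
      # workers compress; the serializer concatenates gzip members
      gz1 <- compress_members(texts1, config$threads)
      write_members(gz1, out1)
      if (out_r2) write_members(compress_members(texts2, config$threads),
                                out2)
    } else {
      write_text_stream(texts1, out1)
      if (out_r2) write_text_stream(texts2, out2)
    }
    written <- c(out1, if (out_r2) out2)
  } else {
    # parallel write: one output file (pair) per worker slot; the slot that
    # would have hosted the serializer processes batches too
    slots <- config$threads + 1L
    assign <- if (length(results)) {
      rep_len(seq_len(slots), length(results))
    } else integer(0)
    for (w in unique(assign)) {
      rs <- results[assign == w]
      f1 <- worker_path(out1, w)
      write_text_stream(lapply(rs, function(r) {
        fastq_lines(if (paired && !out_r2) interleave_records(r$r1, r$r2)
                    else r$r1)
      }), f1)
      written <- c(written, f1)
      if (out_r2) {
        f2 <- worker_path(out2, w)
        write_text_stream(lapply(rs, function(r) fastq_lines(r$r2)), f2)
        written <- c(written, f2)
      }
    }
  }
  stats$output_files <- written

  if (config$qc %in% c("post", "both")) {
    kept1 <- do.call(rbind, lapply(results, `[[`, "r1"))
    kept2 <- if (paired) do.call(rbind, lapply(results, `[[`, "r2"))
    stats$qc_post <- collect_qc(rbind(kept1, kept2), stage = "post")
  }
  if (!is.null(qc_pre)) stats$qc_pre <- qc_pre
  stats
}

worker_path <- function(path, w) {
  sub("(\\.(fastq|fq)(\\.gz)?)$", sprintf(".worker%d\\1", w), path)
}

compress_members <- function(texts, threads) {
  pack <- function(tx) {
    if (!length(tx)) return(raw(0))
    tf <- tempfile(fileext = ".gz")
    on.exit(unlink(tf))
    con <- gzfile(tf, "wb")
    writeLines(tx, con)
    close(con)
    readBin(tf, "raw", file.size(tf))
  }
  if (threads > 1L && length(texts) > 1L) {
    parallel::mclapply(texts, pack, mc.cores = threads)
  } else {
    lapply(texts, pack)
  }
}

write_members <- function(members, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (m in members) if (length(m)) writeBin(m, con)
  invisible(path)
}

write_text_stream <- function(texts, path) {
  con <- open_out(path)
  on.exit(close(con))
  for (tx in texts) if (length(tx)) writeLines(tx, con)
  invisible(path)
}
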
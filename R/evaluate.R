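# Scoring trimmed output against simulator ground truth.
#
# Per read: "wrongly trimmed" = the read contains no adapter but bases were
# removed anyway; "over-trimmed" = adapter present but too many bases
# removed; "under-trimmed" = adapter present but too few removed.  Bases
# over-/under-trimmed are the corresponding position differences; pairs
# discarded by the length filter are counted separately.

#' Classify a trimmed read against its ground truth
#'
#' @param trimmed_length Length of the read after trimming.
#' @param adapter_start True 0-based adapter start (equals the insert
#'   length), or `NA` when the read contains no adapter.
#' @param original_length Read length before trimming.
#' @return A list with `category` (one of `"correct"`, `"wrongly"`,
#'   `"over"`, `"under"`) and the base deltas `over_bases`/`under_bases`.
#' @examples
#' classify_read(100, 100, 125)  # correct
#' classify_read(98, 100, 125)   # over-trimmed by 2 bases
#' classify_read(120, NA, 125)   # wrongly trimmed, 5 bases
#' @export
classify_read <- function(trimmed_length, adapter_start, original_length) {
  stopifnot(trimmed_length <= original_length)
  if (is.na(adapter_start)) {
    if (trimmed_length < original_length) {
      return(list(category = "wrongly",
                  over_bases = original_length - trimmed_length,
                  under_bases = 0L))
    }
    return(list(category = "correct", over_bases = 0L, under_bases = 0L))
  }
  if (trimmed_length > adapter_start) {
    list(category = "under", over_bases = 0L,
         under_bases = trimmed_length - adapter_start)
  } else if (trimmed_length < adapter_start) {
    list(category = "over", over_bases = adapter_start - trimmed_length,
         under_bases = 0L)
  } else {
    list(category = "correct", over_bases = 0L, under_bases = 0L)
  }
}

classify_vec <- function(trimmed_length, adapter_start, original_length) {
  no_ad <- is.na(adapter_start)
  category <- rep("correct", length(trimmed_length))
  over <- integer(length(trimmed_length))
  under <- integer(length(trimmed_length))
  w <- no_ad & trimmed_length < original_length
  category[w] <- "wrongly"
  over[w] <- original_length - trimmed_length[w]
  u <- !no_ad & trimmed_length > adapter_start
  category[u] <- "under"
  under[u] <- trimmed_length[u] - adapter_start[u]
  o <- !no_ad & trimmed_length < adapter_start
  category[o] <- "over"
  over[o] <- adapter_start[o] - trimmed_length[o]
  list(category = category, over = over, under = under)
}

#' Score trimmed FASTQ output against a simulator truth table
#'
#' Aggregates [classify_read()] over both mates of every pair. Pairs
#' present in the truth table but absent from the trimmed output are
#' counted as discarded (by the minimum-length filter), not as trimming
#' errors. Reads are resolved to truth records by name; an unresolvable
#' record aborts with its name.
#'
#' @param trimmed1,trimmed2 Trimmed FASTQ paths or record data frames
#'   (mate 2 may be `NULL` together with `merged = TRUE`).
#' @param truth Truth table (data frame from [simulate_pairs()] or a path
#'   written by [write_truth()]).
#' @param read_length Original (untrimmed) read length; defaults to the
#'   truth table's `read_length` attribute.
#' @param merged Score a merged single-read stream: each merged record is
#'   compared once, per pair, against the true insert length.
#' @return An object of class `accuracy_report`: per-category read counts
#'   and fractions, over-/under-trimmed base counts, read- and base-level
#'   total error percentages, and discarded-pair statistics. Fractions use
#'   total reads (2 per pair) as denominator; `as_json()`-style output via
#'   [report_to_json()] also carries the per-pair denominators.
#' @export
evaluate_accuracy <- function(trimmed1, trimmed2 = NULL, truth,
                              read_length = NULL, merged = FALSE) {
  if (is.character(truth)) truth <- read_truth(truth)
  if (is.null(read_length)) read_length <- attr(truth, "read_length")
  if (is.null(read_length)) {
    stop("read_length not given and absent from the truth table",
         call. = FALSE)
  }
  load_df <- function(x) {
    if (is.character(x) && length(x) == 1L) read_fastq(x) else x
  }
  t1 <- load_df(trimmed1)
  resolve <- function(nm) {
    idx <- match(base_read_name(nm), base_read_name(truth$name))
    if (anyNA(idx)) {
      stop("record '", nm[which(is.na(idx))[1]],
           "' has no truth entry", call. = FALSE)
    }
    idx
  }

  n_pairs <- nrow(truth)
  if (merged) {
    idx <- resolve(t1$name)
    cl <- classify_vec(nchar(t1$seq), truth$insert_length[idx] *
                         ifelse(is.na(truth$adapter_start[idx]), NA, 1L),
                       pmax(nchar(t1$seq), read_length))
    # merged records: compare merged length to the true insert length;
    # records for adapter-free pairs are classified against NA (wrongly
    # trimmed iff shorter than the original read)
    counts <- table(factor(cl$category,
                           levels = c("correct", "wrongly", "over",
                                      "under")))
    discarded <- n_pairs - nrow(t1)
    total_units <- n_pairs
    over_b <- sum(cl$over); under_b <- sum(cl$under)
    unit <- "pairs"
  } else {
    t2 <- load_df(trimmed2)
    if (is.null(t2)) stop("trimmed2 required unless merged = TRUE",
                          call. = FALSE)
    if (nrow(t1) != nrow(t2)) {
      stop("trimmed mate files differ in record count", call. = FALSE)
    }
    i1 <- resolve(t1$name)
    i2 <- resolve(t2$name)
    cl1 <- classify_vec(nchar(t1$seq), truth$adapter_start[i1],
                        read_length)
    cl2 <- classify_vec(nchar(t2$seq), truth$adapter_start[i2],
                        read_length)
    counts <- table(factor(c(cl1$category, cl2$category),
                           levels = c("correct", "wrongly", "over",
                                      "under")))
    discarded <- n_pairs - nrow(t1)
    total_units <- 2L * n_pairs
    over_b <- sum(cl1$over) + sum(cl2$over)
    under_b <- sum(cl1$under) + sum(cl2$under)
    unit <- "reads"
  }
  total_bases <- as.numeric(total_units) * read_length
  err_units <- sum(counts[c("wrongly", "over", "under")])
  structure(list(
    unit = unit,
    total_pairs = n_pairs,
    total_units = total_units,
    read_length = read_length,
    wrongly = as.integer(counts[["wrongly"]]),
    over = as.integer(counts[["over"]]),
    under = as.integer(counts[["under"]]),
    correct = as.integer(counts[["correct"]]),
    wrongly_frac = counts[["wrongly"]] / total_units,
    over_frac = counts[["over"]] / total_units,
    under_frac = counts[["under"]] / total_units,
    read_error_pct = 100 * err_units / total_units,
    over_bases = over_b,
    under_bases = under_b,
    base_error_pct = 100 * (over_b + under_b) / total_bases,
    discarded_pairs = as.integer(discarded),
    discarded_frac = discarded / n_pairs),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  cat(sprintf("  %-16s %10s %10s\n", "", "count", "fraction"))
  for (f in c("wrongly", "over", "under")) {
    cat(sprintf("  %-16s %10d %9.4f%%\n", paste0(f, " trimmed"), x[[f]],
                100 * x[[paste0(f, "_frac")]]))
  }
  cat(sprintf("  %-16s %10d\n", "correct", x$correct))
  cat(sprintf("  %s-level total error: %.4f%%\n", substr(x$unit, 1, 4),
              x$read_error_pct))
  cat(sprintf("  bases over/under-trimmed: %d / %d (total error %.5f%%)\n",
              x$over_bases, x$under_bases, x$base_error_pct))
  cat(sprintf("  discarded pairs: %d (%.2f%%)\n", x$discarded_pairs,
              100 * x$discarded_frac))
  invisible(x)
}

#' Serialize an accuracy report to JSON
#'
#' Carries both per-read and per-pair denominators.
#'
#' @param report An `accuracy_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when `path` is given).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$schema <- "readtrim/accuracy/1"
  obj$per_pair <- list(
    wrongly_frac = report$wrongly / report$total_pairs,
    over_frac = report$over / report$total_pairs,
    under_frac = report$under / report$total_pairs)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
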
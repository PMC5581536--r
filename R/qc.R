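# Quality-control metrics, collected in a single pass and mergeable so
# that per-worker summaries can be combined.

#' Collect quality-control metrics over a set of reads
#'
#' Single-pass accumulation of: the per-position quality distribution
#' (position x Phred count matrix), the per-read mean-quality histogram,
#' the per-position base composition (A/C/G/T/N), the GC-content histogram
#' and the read-length distribution. Collection is a pure observer — it
#' never alters the reads.
#'
#' @param reads A data frame with `seq`/`qual` columns, a FASTQ path, or a
#'   list of [read_record()]s.
#' @param stage `"pre"` or `"post"` (before/after trimming).
#' @return An object of class `qc_summary`.
#' @export
collect_qc <- function(reads, stage = c("pre", "post")) {
  stage <- match.arg(stage)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.list(reads) && !is.data.frame(reads) && length(reads) &&
      inherits(reads[[1]], "read_record")) {
    reads <- data.frame(
      name = vapply(reads, `[[`, character(1), "name"),
      seq = vapply(reads, `[[`, character(1), "bases"),
      qual = vapply(reads, function(r) phred_to_string(r$qualities),
                    character(1)))
  }
  n <- nrow(reads)
  maxlen <- if (n) max(nchar(reads$seq), 0L) else 0L
  qmat <- matrix(0L, nrow = maxlen, ncol = 94L,
                 dimnames = list(NULL, as.character(0:93)))
  bmat <- matrix(0L, nrow = maxlen, ncol = 5L,
                 dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  qsum <- rep(0, n)
  gc <- rep(0L, n)
  lens <- if (n) nchar(reads$seq) else integer(0)
  for (p in seq_len(maxlen)) {
    covered <- lens >= p
    if (!any(covered)) next
    qv <- utf8ToInt(paste(substr(reads$qual[covered], p, p),
                          collapse = "")) - 33L
    tb <- tabulate(qv + 1L, nbins = 94L)
    qmat[p, ] <- tb
    bv <- substr(reads$seq[covered], p, p)
    bv[!bv %in% c("A", "C", "G", "T")] <- "N"
    bt <- table(factor(bv, levels = c("A", "C", "G", "T", "N")))
    bmat[p, ] <- as.integer(bt)
    qsum[covered] <- qsum[covered] + qv
    gc[covered] <- gc[covered] + (bv %in% c("G", "C"))
  }
  nonempty <- lens > 0L
  mean_q <- floor(ifelse(nonempty, qsum / lens, 0))
  meanq_hist <- tabulate(mean_q[nonempty] + 1L, nbins = 94L)
  gc_hist <- tabulate(round(100 * gc[nonempty] / lens[nonempty]) + 1L,
                      nbins = 101L)
  len_hist <- tabulate(lens + 1L, nbins = maxlen + 1L)
  structure(list(schema = "readtrim/qc/1", stage = stage,
                 n_reads = n, n_bases = sum(lens),
                 per_position_quality = qmat,
                 mean_quality_hist = meanq_hist,
                 base_composition = bmat,
                 gc_hist = gc_hist,
                 length_hist = len_hist),
            class = "qc_summary")
}

#' Merge two QC summaries
#'
#' Merging summaries collected over two read sets equals collecting over
#' their concatenation, which allows per-worker accumulation.
#'
#' @param a,b `qc_summary` objects from the same stage.
#' @return The merged `qc_summary`.
#' @export
merge_qc <- function(a, b) {
  stopifnot(inherits(a, "qc_summary"), inherits(b, "qc_summary"))
  grow <- function(m, rows) {
    if (nrow(m) >= rows) return(m)
    rbind(m, matrix(0L, nrow = rows - nrow(m), ncol = ncol(m),
                    dimnames = list(NULL, colnames(m))))
  }
  rows <- max(nrow(a$per_position_quality), nrow(b$per_position_quality))
  padv <- function(x, len) c(x, rep(0L, len - length(x)))
  lh <- max(length(a$length_hist), length(b$length_hist))
  structure(list(schema = a$schema, stage = a$stage,
                 n_reads = a$n_reads + b$n_reads,
                 n_bases = a$n_bases + b$n_bases,
                 per_position_quality =
                   grow(a$per_position_quality, rows) +
                   grow(b$per_position_quality, rows),
                 mean_quality_hist = a$mean_quality_hist +
                   b$mean_quality_hist,
                 base_composition = grow(a$base_composition, rows) +
                   grow(b$base_composition, rows),
                 gc_hist = a$gc_hist + b$gc_hist,
                 length_hist = padv(a$length_hist, lh) +
                   padv(b$length_hist, lh)),
            class = "qc_summary")
}

qc_to_list <- function(x) {
  list(schema = x$schema, stage = x$stage, n_reads = x$n_reads,
       n_bases = x$n_bases,
       per_position_quality = unname(apply(x$per_position_quality, 1,
                                           as.integer, simplify = FALSE)),
       mean_quality_hist = as.integer(x$mean_quality_hist),
       base_composition = unname(apply(x$base_composition, 1, as.integer,
                                       simplify = FALSE)),
       gc_hist = as.integer(x$gc_hist),
       length_hist = as.integer(x$length_hist))
}

qc_from_list <- function(l) {
  nr <- length(l$per_position_quality)
  qmat <- matrix(0L, nrow = nr, ncol = 94L,
                 dimnames = list(NULL, as.character(0:93)))
  bmat <- matrix(0L, nrow = nr, ncol = 5L,
                 dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  for (i in seq_len(nr)) {
    qmat[i, ] <- l$per_position_quality[[i]]
    bmat[i, ] <- l$base_composition[[i]]
  }
  structure(list(schema = l$schema, stage = l$stage, n_reads = l$n_reads,
                 n_bases = l$n_bases, per_position_quality = qmat,
                 mean_quality_hist = as.integer(l$mean_quality_hist),
                 base_composition = bmat,
                 gc_hist = as.integer(l$gc_hist),
                 length_hist = as.integer(l$length_hist)),
            class = "qc_summary")
}

#' Write QC summaries to a JSON file
#'
#' One JSON document per sample with a versioned schema; the document
#' round-trips losslessly through [read_qc_json()].
#'
#' @param summaries A single `qc_summary` or a named list of them (e.g.
#'   `list(pre = ..., post = ...)`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(summaries, path) {
  if (inherits(summaries, "qc_summary")) {
    summaries <- setNames(list(summaries), summaries$stage)
  }
  obj <- list(schema = "readtrim/qc-report/1",
              summaries = lapply(summaries, qc_to_list))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot write QC summary to ", path, call. = FALSE)
  }
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Read QC summaries back from JSON
#'
#' @param path A file written by [write_qc_json()].
#' @return Named list of `qc_summary` objects.
#' @export
read_qc_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = FALSE)
  lapply(obj$summaries, qc_from_list)
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("<qc_summary> stage %s: %d reads, %d bases\n",
              x$stage, x$n_reads, x$n_bases))
  invisible(x)
}
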
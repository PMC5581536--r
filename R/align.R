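# Semi-global alignment of an adapter pattern against a read.
#
# The aligner minimises edit distance over all allowed shifts of the adapter
# relative to the read, does not penalise the end gaps implied by the
# adapter type, and accepts a shift when edits / aligned-adapter-length does
# not exceed the maximum error rate.  Among accepted shifts, the one with
# the most matching columns wins.

#' Specify an adapter pattern and its matching policy
#'
#' @param sequence IUPAC adapter string (degenerate codes allowed).
#' @param where `"back"` for a 3' adapter (removed together with everything
#'   after it) or `"front"` for a 5' adapter (removed together with
#'   everything before it).
#' @param anchored If `TRUE`, the adapter only matches as a full-length
#'   suffix (`"back"`) or prefix (`"front"`) of the read.
#' @param max_error_rate Maximum allowed edits divided by the length of the
#'   aligned part of the adapter. Default 0.1.
#' @param min_overlap Minimum number of aligned adapter characters. Default 3.
#' @param allow_indels Allow insertions/deletions in the alignment. Default
#'   `TRUE`.
#' @return An object of class `adapter_spec`.
#' @examples
#' adapter_spec("AGATCGGAAGAGC")
#' adapter_spec("XACGT", where = "front", anchored = TRUE)  # error: bad IUPAC
#' @export
adapter_spec <- function(sequence, where = c("back", "front"),
                         anchored = FALSE, max_error_rate = 0.1,
                         min_overlap = 3L, allow_indels = TRUE) {
  where <- match.arg(where)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nchar(sequence)) stop("adapter sequence must be non-empty",
                             call. = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% names(.IUPAC_MASKS))
  if (length(bad)) {
    stop("invalid IUPAC character '", chars[bad[1]], "' at position ",
         bad[1], call. = FALSE)
  }
  stopifnot(max_error_rate >= 0, max_error_rate <= 1, min_overlap >= 1)
  structure(list(sequence = toupper(sequence), where = where,
                 anchored = anchored, max_error_rate = max_error_rate,
                 min_overlap = as.integer(min_overlap),
                 allow_indels = allow_indels),
            class = "adapter_spec")
}

#' @export
print.adapter_spec <- function(x, ...) {
  cat("<adapter_spec> ", x$sequence, " (", x$where,
      if (x$anchored) ", anchored", "), max error rate ", x$max_error_rate,
      ", min overlap ", x$min_overlap,
      if (!x$allow_indels) ", no indels", "\n", sep = "")
  invisible(x)
}

as_location <- function(lst) {
  if (is.null(lst)) return(NULL)
  structure(lst, class = "alignment_location")
}

#' Align an adapter to a read by semi-global alignment
#'
#' Computes edit distances between adapter prefixes and read prefixes with
#' the standard dynamic-programming recurrence, using base cases that allow
#' a read prefix (3' adapters) or read suffix (5' adapters) to be skipped at
#' no cost. Candidate end positions are discarded when their error rate
#' (edits divided by the aligned adapter length) exceeds
#' `adapter$max_error_rate` or when fewer than `adapter$min_overlap` adapter
#' characters are aligned; among the survivors the candidate with the most
#' matching columns is returned. Only a single DP column is held in memory,
#' and a cost cutoff abandons each column as soon as the edit count provably
#' cannot drop back below the acceptance bound; the cutoff never changes the
#' result.
#'
#' @param adapter An [adapter_spec()].
#' @param read A [read_record()] or a plain nucleotide string.
#' @param use_cutoff Enable the column cost cutoff (default `TRUE`;
#'   exposed so that equivalence with the plain DP can be demonstrated).
#' @return An `alignment_location` (fields `read_start`, `read_stop`,
#'   `adapter_start`, `adapter_stop`, `matches`, `errors`, `origin`; 0-based
#'   half-open spans) or `NULL` when no acceptable alignment exists.
#' @examples
#' sp <- adapter_spec("AGATCGGAA")
#' semiglobal_align(sp, "CCCCCAGATCGGAA")  # span [5,14), 9 matches
#' @export
semiglobal_align <- function(adapter, read, use_cutoff = TRUE) {
  stopifnot(inherits(adapter, "adapter_spec"))
  bases <- if (inherits(read, "read_record")) read$bases else read
  if (!nchar(bases)) return(NULL)
  if (adapter$where == "back") {
    res <- cpp_semiglobal_back(adapter$sequence, bases,
                               adapter$max_error_rate, adapter$min_overlap,
                               adapter$allow_indels, adapter$anchored,
                               use_cutoff)
    return(as_location(res))
  }
  # 5' adapter: mirror image of the 3' case via reversal
  m <- nchar(adapter$sequence)
  n <- nchar(bases)
  res <- cpp_semiglobal_back(cpp_reverse_str(adapter$sequence),
                             cpp_reverse_str(bases),
                             adapter$max_error_rate, adapter$min_overlap,
                             adapter$allow_indels, adapter$anchored,
                             use_cutoff)
  if (is.null(res)) return(NULL)
  as_location(list(
    read_start = n - res$read_stop,
    read_stop = n - res$read_start,
    adapter_start = m - res$adapter_stop,
    adapter_stop = m,
    matches = res$matches,
    errors = res$errors,
    origin = if (res$adapter_stop < m) -(m - res$adapter_stop)
             else n - res$read_stop
  ))
}

# Accepted-candidate table (read span, aligned adapter length, errors,
# matches per shift) for a 3' adapter; used by equivalence tests.
semiglobal_candidates <- function(adapter, read, use_cutoff = TRUE) {
  bases <- if (inherits(read, "read_record")) read$bases else read
  cpp_semiglobal_back(adapter$sequence, bases, adapter$max_error_rate,
                      adapter$min_overlap, adapter$allow_indels,
                      adapter$anchored, use_cutoff,
                      all_candidates = TRUE)$candidates
}

#' Align an anchored adapter by Hamming distance
#'
#' Fast path for anchored adapters with indels disabled: the adapter is
#' compared position-wise against the read prefix (5' adapter) or suffix
#' (3' adapter), with the same error-rate acceptance rule as
#' [semiglobal_align()], with which it agrees under the same constraints.
#'
#' @inheritParams semiglobal_align
#' @return An `alignment_location` or `NULL`.
#' @export
hamming_align <- function(adapter, read) {
  stopifnot(inherits(adapter, "adapter_spec"))
  if (!adapter$anchored || adapter$allow_indels) {
    stop("hamming_align() requires an anchored adapter with indels disabled",
         call. = FALSE)
  }
  bases <- if (inherits(read, "read_record")) read$bases else read
  m <- nchar(adapter$sequence)
  n <- nchar(bases)
  if (m > n || !n) return(NULL)
  if (adapter$where == "back") {
    h <- cpp_hamming_prefix(adapter$sequence, substr(bases, n - m + 1L, n))
    span <- c(n - m, n)
  } else {
    h <- cpp_hamming_prefix(adapter$sequence, substr(bases, 1L, m))
    span <- c(0L, m)
  }
  if (h[["mismatches"]] > adapter$max_error_rate * m + 1e-9) return(NULL)
  if (m < adapter$min_overlap) return(NULL)
  as_location(list(read_start = span[1], read_stop = span[2],
                   adapter_start = 0L, adapter_stop = m,
                   matches = h[["matches"]], errors = h[["mismatches"]],
                   origin = span[1]))
}

#' Remove an aligned adapter from a read
#'
#' For a 3' (`"back"`) adapter the bases from the alignment start to the
#' read end are removed; for a 5' (`"front"`) adapter everything up to the
#' alignment end is removed. Qualities are trimmed in lockstep. With
#' `loc = NULL` the read is returned unchanged.
#'
#' @param read A [read_record()].
#' @param where `"back"` or `"front"`.
#' @param loc An `alignment_location` produced for this read, or `NULL`.
#' @return The trimmed [read_record()].
#' @export
trim_by_location <- function(read, where = c("back", "front"), loc) {
  where <- match.arg(where)
  stopifnot(inherits(read, "read_record"))
  if (is.null(loc)) return(read)
  n <- nchar(read$bases)
  if (loc$read_start < 0 || loc$read_stop > n) {
    stop("alignment span lies outside the read", call. = FALSE)
  }
  if (where == "back") {
    keep <- c(1L, loc$read_start)   # keep [0, read_start)
  } else {
    keep <- c(loc$read_stop + 1L, n)  # keep [read_stop, n)
  }
  read_record(read$name, substr(read$bases, keep[1], keep[2]),
              read$qualities[seq_len(n) >= keep[1] &
                             seq_len(n) <= keep[2]],
              mate = read$mate)
}
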
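# Insert-match trimming for read pairs.
#
# A read pair sequences the same insert from both ends, so when the insert
# is shorter than the read length, read 1 and the reverse complement of
# read 2 overlap over the full insert and the adapters occupy the
# overhangs.  Detecting that overlap locates the adapters far more
# specifically than matching the adapter sequence alone.

#' Parameters for insert-match trimming
#'
#' Specificity is controlled by three thresholds: a minimum number of
#' overlapping bases, a maximum number of mismatching bases (expressed as a
#' fraction of the overlap length), and a maximum probability that the
#' observed number of matches would arise between unrelated sequences
#' (binomial, base match probability `base_match_prob`).
#'
#' @param adapter1,adapter2 3' adapter for read 1 / read 2, as an
#'   [adapter_spec()] or a plain IUPAC string.
#' @param min_insert_overlap Minimum overlap between read 1 and the reverse
#'   complement of read 2. Default 10.
#' @param max_mismatch_frac Maximum mismatches as a fraction of the overlap
#'   length; the allowed count is `floor(frac * overlap)`. Default 0.2.
#' @param max_random_match_prob Maximum random-match probability. Default
#'   1e-6.
#' @param base_match_prob Probability that two random bases match. Default
#'   0.25.
#' @param overhang_error_rate Maximum mismatch fraction when confirming an
#'   adapter against an overhang. Overhangs can be as short as one base and
#'   3' quality is poor, so this is deliberately more permissive than the
#'   insert thresholds. Default 0.2.
#' @return An object of class `insert_match_params`.
#' @export
insert_match_params <- function(adapter1, adapter2,
                                min_insert_overlap = 10L,
                                max_mismatch_frac = 0.2,
                                max_random_match_prob = 1e-6,
                                base_match_prob = 0.25,
                                overhang_error_rate = 0.2) {
  if (is.character(adapter1)) adapter1 <- adapter_spec(adapter1)
  if (is.character(adapter2)) adapter2 <- adapter_spec(adapter2)
  stopifnot(inherits(adapter1, "adapter_spec"),
            inherits(adapter2, "adapter_spec"),
            min_insert_overlap >= 1,
            max_mismatch_frac >= 0, max_mismatch_frac <= 1,
            max_random_match_prob >= 0, max_random_match_prob <= 1,
            base_match_prob >= 0, base_match_prob <= 1)
  structure(list(adapter1 = adapter1, adapter2 = adapter2,
                 min_insert_overlap = as.integer(min_insert_overlap),
                 max_mismatch_frac = max_mismatch_frac,
                 max_random_match_prob = max_random_match_prob,
                 base_match_prob = base_match_prob,
                 overhang_error_rate = overhang_error_rate),
            class = "insert_match_params")
}

#' Policy for mutual error correction of overlapping read pairs
#'
#' At each mismatching overlap column the base with the higher Phred
#' quality becomes the consensus. `mode` selects what happens on quality
#' ties: `"keep"` leaves both bases, `"N"` converts both to N, `"best"`
#' takes the base from the read with the higher mean quality. `"none"`
#' disables correction entirely.
#'
#' @param mode Tie mode; one of `"best"`, `"keep"`, `"N"`, `"none"`.
#' @param overwrite_poor_read If `TRUE`, when one mate's mean error
#'   probability exceeds `overwrite_quality_ratio` times the other's, the
#'   better mate's reverse complement replaces the worse mate over the
#'   overlap before correction.
#' @param overwrite_quality_ratio Mean-error-probability ratio that triggers
#'   the overwrite. Default 3.
#' @param merge_pairs If `TRUE`, matched pairs are merged into a single
#'   consensus read covering the full insert.
#' @return An object of class `correction_policy`.
#' @export
correction_policy <- function(mode = c("best", "keep", "N", "none"),
                              overwrite_poor_read = FALSE,
                              overwrite_quality_ratio = 3,
                              merge_pairs = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, overwrite_poor_read = overwrite_poor_read,
                 overwrite_quality_ratio = overwrite_quality_ratio,
                 merge_pairs = merge_pairs),
            class = "correction_policy")
}

#' Probability of a random match between unrelated sequences
#'
#' Upper-tail binomial probability of observing at least `k` matching bases
#' out of `n` compared bases when each base matches independently with
#' probability `p`:
#' \deqn{P = \sum_{i=k}^{n} \binom{n}{i} p^i (1-p)^{n-i}}
#' Computed with the binomial survival function, which is stable for `n` up
#' to read length and beyond.
#'
#' @param k Number of matches (`0 <= k <= n`).
#' @param n Number of compared bases.
#' @param p Base match probability. Default 0.25.
#' @return The probability, a number in `[0, 1]`.
#' @examples
#' random_match_prob(4, 4)        # 0.25^4
#' random_match_prob(0, 10)       # 1
#' @export
random_match_prob <- function(k, n, p = 0.25) {
  if (any(k > n)) stop("k must not exceed n", call. = FALSE)
  if (any(k < 0) || any(n < 0)) stop("k and n must be non-negative",
                                     call. = FALSE)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Find candidate insert-overlap alignments for a read pair
#'
#' Enumerates, without indels, every relative shift in which the 3' ends of
#' read 1 and the reverse complement of read 2 overlap by at least
#' `params$min_insert_overlap`, counts matches and mismatches over the
#' overlap, and retains shifts that satisfy all three specificity
#' thresholds. Two geometries arise: when the implied insert is at most the
#' read length the reads overlap over the whole insert and adapters occupy
#' the overhangs; when it is longer, only the 3' ends overlap and there is
#' nothing to trim.
#'
#' @param read1,read2 [read_record()]s (read 2 in its stored orientation).
#' @param params An [insert_match_params()].
#' @return A data frame with columns `insert_length`, `overlap_len`,
#'   `matches`, `mismatches`, `prob`, sorted by decreasing overlap length.
#' @export
find_insert_candidates <- function(read1, read2, params) {
  stopifnot(inherits(params, "insert_match_params"))
  r1 <- if (inherits(read1, "read_record")) read1$bases else read1
  r2 <- if (inherits(read2, "read_record")) read2$bases else read2
  stopifnot(nchar(r1) > 0, nchar(r2) > 0)
  m <- cpp_insert_candidates(r1, cpp_revcomp(r2),
                             params$min_insert_overlap,
                             params$max_mismatch_frac,
                             params$max_random_match_prob,
                             params$base_match_prob)
  as.data.frame(m)
}

#' Confirm adapters in the overhangs of an insert-match candidate
#'
#' For a candidate whose insert length is below the read length, the
#' configured adapters are compared position-wise against the overhangs
#' `read1[insert_length:]` and `read2[insert_length:]`, starting at the end
#' of the insert overlap. An adapter is confirmed when its mismatch
#' fraction over the compared bases does not exceed
#' `params$overhang_error_rate`. If at least one adapter is confirmed, both
#' reads receive trim point `insert_length` — the adapter location must be
#' symmetric across the pair — and an `insert_match_result` is returned;
#' otherwise `NULL`, so the next candidate can be tried.
#'
#' @param candidate One row of [find_insert_candidates()] output (or a list
#'   with the same fields).
#' @inheritParams find_insert_candidates
#' @return An object of class `insert_match_result` or `NULL`.
#' @export
confirm_adapters <- function(candidate, read1, read2, params) {
  L <- as.integer(candidate$insert_length)
  r1 <- if (inherits(read1, "read_record")) read1$bases else read1
  r2 <- if (inherits(read2, "read_record")) read2$bases else read2
  n1 <- nchar(r1); n2 <- nchar(r2)
  if (L >= max(n1, n2)) {
    stop("candidate implies no overhangs; nothing to confirm", call. = FALSE)
  }
  conf <- function(adapter, bases, n) {
    if (L >= n) return(FALSE)
    over <- substr(bases, L + 1L, n)
    h <- cpp_hamming_prefix(adapter$sequence, over)
    h[["len"]] >= 1L &&
      h[["mismatches"]] <= params$overhang_error_rate * h[["len"]] + 1e-9
  }
  a1 <- conf(params$adapter1, r1, n1)
  a2 <- conf(params$adapter2, r2, n2)
  if (!a1 && !a2) return(NULL)
  structure(list(insert_length = L,
                 overlap_len = as.integer(candidate$overlap_len),
                 matches = as.integer(candidate$matches),
                 mismatches = as.integer(candidate$mismatches),
                 prob = as.numeric(candidate$prob),
                 adapter1_confirmed = a1, adapter2_confirmed = a2,
                 corrected_positions = 0L),
            class = "insert_match_result")
}

# Overlap coordinates implied by an insert-match result:
# list(o1, o2, ov) with 0-based starts of the overlap window in read1 and
# in rc(read2).
overlap_window <- function(L, n1, n2) {
  ov <- min(n1, n2, L, n1 + n2 - L)
  list(o1 = max(0L, L - n2), o2 = max(0L, n2 - L), ov = as.integer(ov))
}

#' Mutual error correction over the insert overlap
#'
#' At each mismatching column of the overlap between read 1 and the reverse
#' complement of read 2, the base with the higher Phred quality replaces the
#' other (read 2 stores the complement of the consensus). Quality ties are
#' resolved by `policy$mode`; the consensus position's quality becomes the
#' maximum of the two qualities. With `policy$mode == "none"` the reads are
#' returned untouched.
#'
#' @inheritParams find_insert_candidates
#' @param result An `insert_match_result` (or any list with
#'   `insert_length`).
#' @param policy A [correction_policy()].
#' @return A list with elements `read1`, `read2` (corrected records) and
#'   `corrections` (number of changed bases across both reads).
#' @export
error_correct <- function(read1, read2, result, policy) {
  stopifnot(inherits(read1, "read_record"), inherits(read2, "read_record"),
            inherits(policy, "correction_policy"))
  if (policy$mode == "none") {
    return(list(read1 = read1, read2 = read2, corrections = 0L))
  }
  n1 <- nchar(read1$bases); n2 <- nchar(read2$bases)
  w <- overlap_window(result$insert_length, n1, n2)
  if (w$ov < 1L) return(list(read1 = read1, read2 = read2, corrections = 0L))

  b1 <- charToRaw(read1$bases)
  b2 <- charToRaw(cpp_revcomp(read2$bases))   # rc(read2)
  q1 <- read1$qualities
  q2 <- rev(read2$qualities)                  # aligned with rc(read2)
  i1 <- w$o1 + seq_len(w$ov)                  # 1-based window in read1
  i2 <- w$o2 + seq_len(w$ov)                  # 1-based window in rc(read2)
  mis <- which(b1[i1] != b2[i2])
  changed <- 0L
  if (length(mis)) {
    p1 <- i1[mis]; p2 <- i2[mis]
    hi1 <- q1[p1] > q2[p2]
    hi2 <- q2[p2] > q1[p1]
    tie <- !hi1 & !hi2
    if (any(tie)) {
      if (policy$mode == "N") {
        b1[p1[tie]] <- charToRaw("N")
        b2[p2[tie]] <- charToRaw("N")
        changed <- changed + 2L * sum(tie)
      } else if (policy$mode == "best") {
        best1 <- mean_error_prob(read1$qualities) <=
          mean_error_prob(read2$qualities)
        if (best1) hi1 <- hi1 | tie else hi2 <- hi2 | tie
      }                                        # "keep": leave both
    }
    qmax <- pmax(q1[p1], q2[p2])
    if (any(hi1)) {                            # read1 wins: copy into read2
      b2[p2[hi1]] <- b1[p1[hi1]]
      changed <- changed + sum(hi1)
    }
    if (any(hi2)) {                            # read2 wins: copy into read1
      b1[p1[hi2]] <- b2[p2[hi2]]
      changed <- changed + sum(hi2)
    }
    res <- hi1 | hi2
    q1[p1[res]] <- qmax[res]
    q2[p2[res]] <- qmax[res]
  }
  r1 <- read_record(read1$name, rawToChar(b1), q1, mate = read1$mate)
  r2 <- read_record(read2$name, cpp_revcomp(rawToChar(b2)), rev(q2),
                    mate = read2$mate)
  list(read1 = r1, read2 = r2, corrections = changed)
}

#' Merge an overlapping read pair into a single read
#'
#' Returns one read covering the full insert: the non-overlap prefix of
#' read 1, the quality-consensus overlap, and — when the insert is longer
#' than the read length — the non-overlap suffix of the reverse complement
#' of read 2. Disagreeing overlap columns are resolved by [error_correct()]
#' under `policy` (with `mode == "none"` the consensus falls back to the
#' `"best"` tie rule).
#'
#' @inheritParams error_correct
#' @return A single merged [read_record()].
#' @export
merge_pair <- function(read1, read2, result, policy = correction_policy()) {
  stopifnot(inherits(result, "insert_match_result") ||
              !is.null(result$insert_length))
  eff <- if (policy$mode == "none") {
    correction_policy("best", merge_pairs = TRUE)
  } else policy
  ec <- error_correct(read1, read2, result, eff)
  r1 <- ec$read1; r2 <- ec$read2
  n1 <- nchar(r1$bases); n2 <- nchar(r2$bases)
  L <- result$insert_length
  w <- overlap_window(L, n1, n2)
  rc2 <- cpp_revcomp(r2$bases)
  q2 <- rev(r2$qualities)
  # consensus overlap taken from corrected read1 (identical to corrected
  # rc(read2) except at unresolved ties, where read1 is reported)
  prefix_end <- w$o1                     # read1[0, o1)
  suffix_from <- w$o2 + w$ov             # rc2[o2+ov, n2)
  bases <- paste0(substr(r1$bases, 1L, prefix_end + w$ov),
                  substr(rc2, suffix_from + 1L, n2))
  quals <- c(r1$qualities[seq_len(prefix_end + w$ov)],
             if (suffix_from < n2) q2[(suffix_from + 1L):n2])
  read_record(r1$name, bases, quals)
}

# Unconstrained adapter match used when the insert path fails; the match
# must additionally satisfy the binomial random-match probability bound, the
# same specificity device the insert thresholds use.
fallback_adapter_trim <- function(read, adapter, params) {
  loc <- semiglobal_align(adapter, read)
  if (is.null(loc)) return(NULL)
  alen <- loc$adapter_stop - loc$adapter_start
  pr <- random_match_prob(loc$matches, alen, params$base_match_prob)
  if (pr > params$max_random_match_prob) return(NULL)
  loc
}

#' Trim a read pair by insert matching, with adapter-match fallback
#'
#' Runs [find_insert_candidates()] and tests the candidates in order of
#' decreasing overlap length. A candidate without overhangs (implied insert
#' at least the read length) is accepted as-is: the reads overlap only at
#' their 3' ends and nothing is trimmed. A candidate with overhangs must
#' have an adapter confirmed by [confirm_adapters()]; on success, mutual
#' error correction is applied per `policy`, both reads are trimmed at the
#' insert length, and, if requested, the pair is merged. If no candidate
#' yields confirmed adapters (or none exists), an unconstrained adapter
#' match is attempted separately in each read.
#'
#' @inheritParams error_correct
#' @param params An [insert_match_params()].
#' @return A list with elements `read1`, `read2` (trimmed records),
#'   `merged` (merged record or `NULL`), `outcome` (one of `"insert"`,
#'   `"insert_untrimmed"`, `"adapter_fallback"`, `"untrimmed"`) and
#'   `result` (the `insert_match_result` or `NULL`).
#' @export
insert_trim_pair <- function(read1, read2, params,
                             policy = correction_policy("none")) {
  stopifnot(inherits(read1, "read_record"), inherits(read2, "read_record"),
            inherits(params, "insert_match_params"))
  n1 <- nchar(read1$bases); n2 <- nchar(read2$bases)
  cands <- if (n1 && n2) {
    cpp_insert_candidates(read1$bases, cpp_revcomp(read2$bases),
                          params$min_insert_overlap,
                          params$max_mismatch_frac,
                          params$max_random_match_prob,
                          params$base_match_prob)
  } else matrix(numeric(0), 0, 5)
  result <- NULL
  if (nrow(cands)) {
    if (cands[1, 1] >= max(n1, n2)) {
      # best candidate: pure 3' overlap, no adapter present
      return(list(read1 = read1, read2 = read2, merged = NULL,
                  outcome = "insert_untrimmed", result = NULL))
    }
    for (i in seq_len(nrow(cands))) {
      if (cands[i, 1] >= max(n1, n2)) next
      cand <- list(insert_length = cands[i, 1], overlap_len = cands[i, 2],
                   matches = cands[i, 3], mismatches = cands[i, 4],
                   prob = cands[i, 5])
      result <- confirm_adapters(cand, read1, read2, params)
      if (!is.null(result)) break
    }
  }
  if (!is.null(result)) {
    if (isTRUE(policy$overwrite_poor_read)) {
      ow <- overwrite_poor_mate(read1, read2, result, policy)
      read1 <- ow$read1; read2 <- ow$read2
    }
    ec <- error_correct(read1, read2, result, policy)
    result$corrected_positions <- ec$corrections
    L <- result$insert_length
    t1 <- shorten_record(ec$read1, min(L, n1))
    t2 <- shorten_record(ec$read2, min(L, n2))
    merged <- if (isTRUE(policy$merge_pairs)) {
      merge_pair(ec$read1, ec$read2, result, policy)
    }
    return(list(read1 = t1, read2 = t2, merged = merged,
                outcome = "insert", result = result))
  }
  # fallback: unconstrained adapter match, each read independently
  loc1 <- fallback_adapter_trim(read1, params$adapter1, params)
  loc2 <- fallback_adapter_trim(read2, params$adapter2, params)
  if (is.null(loc1) && is.null(loc2)) {
    return(list(read1 = read1, read2 = read2, merged = NULL,
                outcome = "untrimmed", result = NULL))
  }
  t1 <- trim_by_location(read1, "back", loc1)
  t2 <- trim_by_location(read2, "back", loc2)
  list(read1 = t1, read2 = t2, merged = NULL,
       outcome = "adapter_fallback", result = NULL)
}

# keep the first `len` bases of a record
shorten_record <- function(read, len) {
  len <- max(0L, as.integer(len))
  n <- nchar(read$bases)
  if (len >= n) return(read)
  read_record(read$name, substr(read$bases, 1L, len),
              read$qualities[seq_len(len)], mate = read$mate)
}

# replace the overlap of the poor-quality mate by the reverse complement of
# the better mate when quality is lopsided
overwrite_poor_mate <- function(read1, read2, result, policy) {
  e1 <- mean_error_prob(read1$qualities)
  e2 <- mean_error_prob(read2$qualities)
  ratio <- policy$overwrite_quality_ratio
  n1 <- nchar(read1$bases); n2 <- nchar(read2$bases)
  w <- overlap_window(result$insert_length, n1, n2)
  if (w$ov < 1L) return(list(read1 = read1, read2 = read2))
  if (e2 > ratio * e1) {
    # read2 is poor: copy rc(read1 overlap) into read2
    rc2 <- charToRaw(cpp_revcomp(read2$bases))
    q2 <- rev(read2$qualities)
    src <- charToRaw(read1$bases)
    idx2 <- w$o2 + seq_len(w$ov)
    idx1 <- w$o1 + seq_len(w$ov)
    rc2[idx2] <- src[idx1]
    q2[idx2] <- read1$qualities[idx1]
    read2 <- read_record(read2$name, cpp_revcomp(rawToChar(rc2)), rev(q2),
                         mate = read2$mate)
  } else if (e1 > ratio * e2) {
    rc2 <- charToRaw(cpp_revcomp(read2$bases))
    q2 <- rev(read2$qualities)
    b1 <- charToRaw(read1$bases)
    q1 <- read1$qualities
    idx2 <- w$o2 + seq_len(w$ov)
    idx1 <- w$o1 + seq_len(w$ov)
    b1[idx1] <- rc2[idx2]
    q1[idx1] <- q2[idx2]
    read1 <- read_record(read1$name, rawToChar(b1), q1, mate = read1$mate)
  }
  list(read1 = read1, read2 = read2)
}
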
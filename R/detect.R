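# De novo adapter/contaminant detection by iterative k-mer profiling.
#
# Adapters are designed not to match natural sequence, so a k-mer that is
# massively over-represented in a read sample — far beyond what a random
# genome position could produce — is very likely adapter or another library
# contaminant.

#' Parameters for adapter detection
#'
#' @param k0 Initial k-mer length. Default 12.
#' @param sample_size Number of reads sampled from the input (the first
#'   `sample_size` reads). Default 10000.
#' @param overrepresentation Over-representation factor `O`: a k-mer
#'   qualifies when its count strictly exceeds `N (l - k + 1) O / 4^k`.
#'   Default 100.
#' @param polyA_min_run Minimum run of A bases that triggers poly-A
#'   pre-trimming. Default 8.
#' @param complexity_threshold Shannon-entropy threshold in bits below
#'   which a sequence counts as low-complexity. Default 1.0.
#' @param max_report Maximum number of reported contaminants. Default 20.
#' @param known_contaminants Optional named character vector
#'   (name -> sequence) of known adapters, or a path to a FASTA file; see
#'   [default_contaminants()].
#' @return An object of class `detect_params`.
#' @export
detect_params <- function(k0 = 12L, sample_size = 10000L,
                          overrepresentation = 100,
                          polyA_min_run = 8L, complexity_threshold = 1.0,
                          max_report = 20L, known_contaminants = NULL) {
  stopifnot(k0 >= 1, sample_size >= 1, overrepresentation > 0,
            polyA_min_run >= 1, complexity_threshold > 0, max_report >= 1)
  if (is.character(known_contaminants) && length(known_contaminants) == 1L &&
      file.exists(known_contaminants) && is.null(names(known_contaminants))) {
    known_contaminants <- read_contaminants(known_contaminants)
  }
  structure(list(k0 = as.integer(k0), sample_size = as.integer(sample_size),
                 overrepresentation = overrepresentation,
                 polyA_min_run = as.integer(polyA_min_run),
                 complexity_threshold = complexity_threshold,
                 max_report = as.integer(max_report),
                 known_contaminants = known_contaminants),
            class = "detect_params")
}

#' Read a name -> sequence contaminant table from FASTA
#'
#' @param path FASTA file of known adapter/contaminant sequences.
#' @return Named character vector.
#' @export
read_contaminants <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Bundled list of common adapter sequences
#'
#' @return Named character vector of widely used TruSeq/Nextera adapter
#'   sequences shipped with the package.
#' @export
default_contaminants <- function() {
  read_contaminants(system.file("extdata", "contaminants.fasta",
                                package = "readtrim"))
}

#' Remove poly-A tails and everything 3' of them
#'
#' A run of at least `min_run` consecutive A bases is a strong indicator
#' that the sequencer scanned past the end of the template; the run and all
#' subsequent bases are removed.
#'
#' @param seq Character vector of read sequences.
#' @param min_run Minimum A-run length. Default 8.
#' @return Character vector of pre-trimmed sequences.
#' @export
polyA_pretrim <- function(seq, min_run = 8L) {
  pat <- paste0("A{", min_run, ",}")
  pos <- regexpr(pat, seq)
  ifelse(pos > 0L, substr(seq, 1L, pos - 1L), seq)
}

#' Sequence complexity in bits
#'
#' Shannon entropy over the nucleotide frequencies of the sequence:
#' `X(S) = -sum_i f_i log2(f_i)` with `f_i = C(i, S) / |S|` over
#' `i in {A, C, G, T}` and `0 log 0 := 0`. Values below 1.0 bit are
#' conventionally called low-complexity.
#'
#' @param seq Character vector of non-empty sequences.
#' @return Numeric vector of entropies in `[0, 2]`.
#' @examples
#' complexity("AAAAAA")    # 0
#' complexity("ACGTACGT")  # 2
#' complexity("AACC")      # 1
#' @export
complexity <- function(seq) {
  if (any(!nchar(seq))) stop("complexity of an empty sequence is undefined",
                             call. = FALSE)
  n <- nchar(seq)
  ent <- rep(0, length(seq))
  for (b in c("A", "C", "G", "T")) {
    f <- (n - nchar(gsub(b, "", seq, fixed = TRUE))) / n
    term <- ifelse(f > 0, -f * log2(f), 0)
    ent <- ent + term
  }
  ent
}

#' Minimum count for a k-mer to be called high-abundance
#'
#' A k-mer of length `k` drawn from `N` reads of length `l` is expected
#' `N (l - k + 1) / 4^k` times by chance; the qualification threshold
#' multiplies this by the over-representation factor `O`. A k-mer is
#' high-abundance iff its count strictly exceeds the threshold.
#'
#' @param params A [detect_params()].
#' @param l Read length.
#' @param k k-mer length (`k <= l`).
#' @return The (real-valued) threshold.
#' @examples
#' # defaults: N = 10000, l = 125, k = 12, O = 100 -> about 6.8,
#' # so counts of 7 and above qualify
#' abundance_threshold(detect_params(), l = 125, k = 12)
#' @export
abundance_threshold <- function(params, l, k) {
  stopifnot(inherits(params, "detect_params"))
  if (k > l) stop("k must not exceed the read length", call. = FALSE)
  params$sample_size * (l - k + 1) * params$overrepresentation / 4^k
}

#' Detect likely adapter/contaminant sequences in a read sample
#'
#' Samples reads, pre-trims poly-A tails, drops low-complexity reads, and
#' profiles k-mers starting at `params$k0`: k-mers whose count strictly
#' exceeds the abundance threshold are kept together with back-links to
#' their source reads, and profiling repeats with doubled k on the linked
#' reads only, until no k-mer qualifies or k exceeds half the read length.
#' Qualifying k-mers of all lengths are merged by containment (a sequence
#' fully contained in a longer one is dropped) and optionally matched
#' against known contaminants (90% identity to label).
#'
#' @param reads Character vector of read sequences, a data frame with a
#'   `seq` column, or a FASTQ path.
#' @param params A [detect_params()].
#' @return A data frame with columns `rank`, `sequence`, `kmer_len`,
#'   `count`, `abundance_ratio`, `known_name`, `known_identity` — up to
#'   `params$max_report` rows, most likely contaminants first.
#' @export
detect_adapters <- function(reads, params = detect_params()) {
  stopifnot(inherits(params, "detect_params"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.data.frame(reads)) reads <- reads$seq
  reads <- head(reads, params$sample_size)
  empty <- data.frame(rank = integer(0), sequence = character(0),
                      kmer_len = integer(0), count = integer(0),
                      abundance_ratio = numeric(0),
                      known_name = character(0),
                      known_identity = numeric(0))
  if (!length(reads)) {
    warning("empty read sample; nothing to detect")
    return(empty)
  }
  reads <- polyA_pretrim(reads, params$polyA_min_run)
  reads <- reads[nchar(reads) >= params$k0]
  reads <- reads[complexity(reads) >= params$complexity_threshold]
  if (!length(reads)) {
    warning("no reads left after poly-A/complexity filtering")
    return(empty)
  }
  l <- mean(nchar(reads))
  kmax <- floor(l / 2)

  hits <- list()
  active <- seq_along(reads)
  k <- params$k0
  while (k <= kmax && length(active)) {
    sub <- reads[active]
    lens <- nchar(sub)
    nk <- pmax(0L, lens - k + 1L)
    use <- nk > 0L
    if (!any(use)) break
    i_vec <- rep(active[use], nk[use])
    s_vec <- sequence(nk[use])
    dt <- data.table::data.table(
      read = i_vec,
      kmer = substring(reads[i_vec], s_vec, s_vec + k - 1L))
    counts <- dt[, list(count = .N), by = "kmer"]
    thr <- max(abundance_threshold(params, l, k), 1)
    counts <- counts[counts$count > thr, ]
    if (nrow(counts)) {
      keep <- counts$kmer[complexity(counts$kmer) >=
                            params$complexity_threshold]
      counts <- counts[counts$kmer %in% keep, ]
    }
    if (!nrow(counts)) break
    hits[[as.character(k)]] <-
      data.frame(sequence = counts$kmer, count = counts$count,
                 kmer_len = k,
                 threshold = thr,
                 expected = params$sample_size * (l - k + 1) / 4^k)
    active <- unique(dt$read[dt$kmer %in% counts$kmer])
    k <- k * 2L
  }
  if (!length(hits)) return(empty)
  all_hits <- do.call(rbind, hits)
  # rank by support x length and work with the strongest candidates only;
  # flanks of a true contaminant spawn large numbers of weakly supported
  # k-mer variants that can never reach the report
  ord <- order(-all_hits$count * nchar(all_hits$sequence))
  all_hits <- all_hits[head(ord, max(3L * params$max_report, 60L)), ,
                       drop = FALSE]
  # merge: assemble qualifying k-mers that overlap by at least k0 - 1 into
  # longer contigs (so a contaminant longer than the largest profiled k is
  # reported in full), then drop any sequence contained in a longer one
  asm <- assemble_overlaps(all_hits$sequence, all_hits$count,
                           min_ov = params$k0 - 1L)
  all_hits <- data.frame(sequence = asm$sequence, count = asm$count,
                         expected = params$sample_size *
                           pmax(l - nchar(asm$sequence) + 1, 1) /
                           4^nchar(asm$sequence))
  ord <- order(-nchar(all_hits$sequence), -all_hits$count)
  all_hits <- all_hits[ord, , drop = FALSE]
  kept <- logical(nrow(all_hits))
  for (i in seq_len(nrow(all_hits))) {
    longer <- all_hits$sequence[seq_len(i - 1L)][kept[seq_len(i - 1L)]]
    contained <- any(vapply(longer, function(long) {
      grepl(all_hits$sequence[i], long, fixed = TRUE)
    }, logical(1)))
    kept[i] <- !isTRUE(contained)
  }
  all_hits <- all_hits[kept, , drop = FALSE]

  all_hits$known_name <- NA_character_
  all_hits$known_identity <- NA_real_
  known <- params$known_contaminants
  if (!is.null(known) && length(known)) {
    for (i in seq_len(nrow(all_hits))) {
      best <- match_known(all_hits$sequence[i], known)
      if (!is.null(best)) {
        all_hits$known_name[i] <- best$name
        all_hits$known_identity[i] <- best$identity
      }
    }
  }
  score <- all_hits$count * nchar(all_hits$sequence)
  ord <- order(!is.na(all_hits$known_name), score, decreasing = TRUE)
  all_hits <- all_hits[ord, , drop = FALSE]
  all_hits <- head(all_hits, params$max_report)
  data.frame(rank = seq_len(nrow(all_hits)),
             sequence = all_hits$sequence,
             kmer_len = nchar(all_hits$sequence),
             count = all_hits$count,
             abundance_ratio = all_hits$count / all_hits$expected,
             known_name = all_hits$known_name,
             known_identity = all_hits$known_identity,
             row.names = NULL)
}

# Greedy assembly of qualifying k-mers: while any pair overlaps
# (suffix-to-prefix) by at least min_ov bases, join them; the joined contig
# keeps the larger support count.  Adjacent k-mers of one contaminant
# overlap by k - 1, so its full sequence is reconstructed.
assemble_overlaps <- function(seqs, counts, min_ov) {
  seqs <- as.character(seqs)
  repeat {
    n <- length(seqs)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i == j) next
        a <- seqs[i]; b <- seqs[j]
        na <- nchar(a); nb <- nchar(b)
        ov_hi <- min(na, nb) - 1L
        if (ov_hi < min_ov) next
        for (ov in ov_hi:min_ov) {
          if (substr(a, na - ov + 1L, na) == substr(b, 1L, ov)) {
            seqs[i] <- paste0(a, substr(b, ov + 1L, nb))
            counts[i] <- max(counts[i], counts[j])
            seqs <- seqs[-j]; counts <- counts[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  list(sequence = seqs, count = counts)
}

# label a candidate with the best-matching known contaminant at >= 90%
# identity over the candidate's length
match_known <- function(candidate, known) {
  spec <- adapter_spec(candidate, max_error_rate = 0.2, min_overlap = 3L)
  best <- NULL
  for (j in seq_along(known)) {
    loc <- semiglobal_align(spec, known[[j]])
    if (is.null(loc)) next
    identity <- loc$matches / nchar(candidate)
    if (identity >= 0.9 && (is.null(best) || identity > best$identity)) {
      best <- list(name = names(known)[j], identity = identity)
    }
  }
  best
}
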
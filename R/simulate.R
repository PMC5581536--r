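# Paired-end read simulation with ground truth.
#
# Geometry: each pair draws an insert; read 1 is the insert prefix, read 2
# the reverse-complement insert prefix.  When the insert is shorter than
# the read length, the 3' adapter (then random filler) is appended so each
# read reaches full length — exactly the situation an adapter trimmer must
# recognise.  Base-call errors are substitutions drawn per base with
# probability 10^(-q/10) from the base's Phred quality.

.TRUSEQ_R1 <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
.TRUSEQ_R2 <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA"

#' Create a per-position quality-score profile
#'
#' A profile gives, for each read position, a distribution over Phred bins
#' expressed as read counts (the way empirical sequencer profiles are
#' published). Bin `i` carries error probability `e_i = 10^(-q_i/10)`.
#'
#' @param phred Integer vector of Phred bin values (shared by all
#'   positions).
#' @param counts Numeric matrix of read counts, positions x bins, or a
#'   vector for a single position.
#' @return An object of class `quality_profile`.
#' @export
quality_profile <- function(phred, counts) {
  phred <- as.integer(phred)
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  stopifnot(ncol(counts) == length(phred), all(counts >= 0),
            all(phred >= 0), all(phred <= 93))
  if (any(rowSums(counts) <= 0)) {
    stop("every position needs at least one positive count", call. = FALSE)
  }
  structure(list(phred = phred, counts = counts),
            class = "quality_profile")
}

#' Overall error rate of a quality profile
#'
#' With bins `e_1..e_n` (error probabilities) and read counts `r_1..r_n`,
#' aggregated over all positions:
#' \deqn{E = \sum_i e_i r_i / \sum_i r_i}
#'
#' @param profile A [quality_profile()].
#' @return The overall error rate.
#' @export
profile_error_rate <- function(profile) {
  stopifnot(inherits(profile, "quality_profile"))
  e <- 10^(-profile$phred / 10)
  tot <- sum(profile$counts)
  if (tot <= 0) stop("profile has no counts", call. = FALSE)
  sum(sweep(profile$counts, 2, e, `*`)) / tot
}

#' Inflate a quality profile to a target error rate
#'
#' Adds an equal number of counts `C` to every Phred bin of the profile so
#' that the overall error rate becomes `target`; i.e. solves
#' \deqn{f(C, E') = \sum_i e_i (r_i + C) / \sum_i (r_i + C) - E' = 0.}
#' `f` is monotone in `C` from the current rate `E` toward the unweighted
#' mean of the `e_i`, which bounds the reachable targets; `f` is a ratio of
#' two linear functions of `C`, so the root is solved exactly (and is
#' checked to satisfy `|f| < 1e-9`).
#'
#' @param profile A [quality_profile()].
#' @param target Desired overall error rate `E'`, between the profile's
#'   current rate and the unweighted mean of its bin error probabilities.
#' @return The inflated `quality_profile` (counts become non-integer).
#' @export
inflate_profile <- function(profile, target) {
  stopifnot(inherits(profile, "quality_profile"))
  e <- 10^(-profile$phred / 10)
  npos <- nrow(profile$counts)
  S1 <- sum(sweep(profile$counts, 2, e, `*`))
  S0 <- sum(profile$counts)
  Se <- npos * sum(e)              # added error mass per unit C
  B <- npos * length(e)            # number of bins receiving C
  E0 <- S1 / S0
  Einf <- Se / B                   # limit as C -> infinity: mean(e_i)
  lo <- min(E0, Einf); hi <- max(E0, Einf)
  if (target < lo - 1e-12 || target > hi + 1e-12) {
    stop(sprintf(
      "target error rate %.6g is unreachable; reachable range is [%.6g, %.6g]",
      target, lo, hi), call. = FALSE)
  }
  C <- if (abs(target - E0) < 1e-15) 0 else (S1 - target * S0) /
    (target * B - Se)
  C <- max(0, C)
  out <- quality_profile(profile$phred, profile$counts + C)
  stopifnot(abs(profile_error_rate(out) - target) < 1e-9)
  attr(out, "added_count") <- C
  out
}

#' Configuration for the read-pair simulator
#'
#' @param n_pairs Number of read pairs.
#' @param read_length Read length in bases. Default 125.
#' @param insert_mean,insert_sd,insert_min,insert_max Insert-length
#'   distribution: normal(mean, sd) truncated to `[insert_min,
#'   insert_max]` and rounded. Defaults 200 / 60 / 1 / 400.
#' @param adapter1,adapter2 3' adapter appended to read 1 / read 2 when the
#'   insert is shorter than the read. Defaults: TruSeq indexed/universal
#'   sequences.
#' @param error_rate Target overall base-call error rate; realised as the
#'   flat integer Phred quality `round(-10 log10(rate))`, so the realised
#'   rate is `10^(-q/10)`. 0 disables errors (quality 40). Ignored when a
#'   `profile` is given.
#' @param profile Optional [quality_profile()] with one row per read
#'   position.
#' @param seed Mandatory random seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pairs, read_length = 125L, insert_mean = 200,
                       insert_sd = 60, insert_min = 1L, insert_max = 400L,
                       adapter1 = .TRUSEQ_R1, adapter2 = .TRUSEQ_R2,
                       error_rate = 0.002, profile = NULL, seed) {
  stopifnot(n_pairs >= 1, read_length >= 1, insert_min >= 1,
            insert_max >= insert_min, error_rate >= 0, error_rate < 1)
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (nchar(adapter1) > read_length || nchar(adapter2) > read_length) {
    stop("adapter longer than the read length", call. = FALSE)
  }
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "quality_profile"),
              nrow(profile$counts) == read_length)
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 adapter1 = adapter1, adapter2 = adapter2,
                 error_rate = error_rate, profile = profile,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_bases <- function(total) {
  if (total <= 0) return("")
  paste(c("A", "C", "G", "T")[sample.int(4L, total, replace = TRUE)],
        collapse = "")
}

# substitute bases according to a per-read x per-position error mask
apply_errors <- function(seqs, mask) {
  acgt <- charToRaw("ACGT")
  idx <- which(mask)
  if (!length(idx)) return(seqs)
  nr <- nrow(mask)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  shift <- sample.int(3L, length(idx), replace = TRUE)
  byrow <- split(seq_along(idx), row)
  for (rn in names(byrow)) {
    j <- as.integer(rn)
    sel <- byrow[[rn]]
    r <- charToRaw(seqs[j])
    pos <- col[sel]
    cur <- match(r[pos], acgt)
    cur[is.na(cur)] <- 1L          # defensive: N bases rotate from A
    r[pos] <- acgt[(cur - 1L + shift[sel]) %% 4L + 1L]
    seqs[j] <- rawToChar(r)
  }
  seqs
}

#' Simulate paired-end reads with ground truth
#'
#' Draws an insert length per pair, builds error-free reads (insert prefix
#' plus adapter and random filler when the insert is shorter than the
#' read), draws per-base qualities (flat quality matching
#' `config$error_rate`, or from `config$profile`) and substitutes each base
#' with probability `10^(-q/10)`, choosing uniformly among the three other
#' nucleotides. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_prefix If given, writes `<prefix>_1.fq.gz`,
#'   `<prefix>_2.fq.gz` and `<prefix>_truth.tsv`.
#' @return A list with data frames `r1`, `r2` (FASTQ records) and `truth`
#'   (columns `name`, `insert_length`, `adapter_start` — `NA` when the
#'   read contains no adapter — and `insert_seq`), plus
#'   `realized_error_rate`. The truth table carries the read length and
#'   insert distribution as attributes (and header comments on disk).
#' @export
simulate_pairs <- function(config, out_prefix = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  rl <- config$read_length

  u <- runif(n, pnorm(config$insert_min - 0.5, config$insert_mean,
                      config$insert_sd),
             pnorm(config$insert_max + 0.5, config$insert_mean,
                   config$insert_sd))
  L <- as.integer(pmin(config$insert_max,
                       pmax(config$insert_min,
                            round(qnorm(u, config$insert_mean,
                                        config$insert_sd)))))

  ends <- cumsum(L)
  starts <- ends - L + 1L
  big <- random_bases(sum(L))
  inserts <- substring(big, starts, ends)
  rc_inserts <- cpp_revcomp(inserts)

  build_reads <- function(core_src, adapter) {
    core <- substring(core_src, 1L, pmin(L, rl))
    need <- pmax(0L, rl - L)
    short <- which(need > 0L)
    out <- core
    if (length(short)) {
      fill_len <- pmax(0L, need[short] - nchar(adapter))
      fends <- cumsum(fill_len)
      fstarts <- fends - fill_len + 1L
      fill_big <- random_bases(sum(fill_len))
      fills <- substring(fill_big, fstarts, fends)
      out[short] <- paste0(core[short],
                           substr(paste0(adapter, fills), 1L,
                                  need[short]))
    }
    out
  }
  r1 <- build_reads(inserts, config$adapter1)
  r2 <- build_reads(rc_inserts, config$adapter2)

  if (is.null(config$profile)) {
    q <- if (config$error_rate > 0) {
      as.integer(round(-10 * log10(config$error_rate)))
    } else 40L
    e <- if (config$error_rate > 0) 10^(-q / 10) else 0
    qmat1 <- qmat2 <- NULL
    qual1 <- rep(strrep(intToUtf8(q + 33L), rl), n)
    qual2 <- qual1
    if (e > 0) {
      r1 <- apply_errors(r1, matrix(runif(n * rl) < e, nrow = n))
      r2 <- apply_errors(r2, matrix(runif(n * rl) < e, nrow = n))
    }
    realized <- e
  } else {
    ph <- config$profile$phred
    cnt <- config$profile$counts
    draw_q <- function() {
      m <- matrix(0L, nrow = n, ncol = rl)
      for (p in seq_len(rl)) {
        m[, p] <- ph[sample.int(length(ph), n, replace = TRUE,
                                prob = cnt[p, ])]
      }
      m
    }
    qmat1 <- draw_q(); qmat2 <- draw_q()
    r1 <- apply_errors(r1, matrix(runif(n * rl), nrow = n) <
                         10^(-qmat1 / 10))
    r2 <- apply_errors(r2, matrix(runif(n * rl), nrow = n) <
                         10^(-qmat2 / 10))
    qual1 <- vapply(seq_len(n),
                    function(i) intToUtf8(qmat1[i, ] + 33L), character(1))
    qual2 <- vapply(seq_len(n),
                    function(i) intToUtf8(qmat2[i, ] + 33L), character(1))
    realized <- profile_error_rate(config$profile)
  }

  name <- sprintf("sim%07d", seq_len(n))
  r1df <- data.frame(name = name, seq = r1, qual = qual1)
  r2df <- data.frame(name = name, seq = r2, qual = qual2)
  truth <- data.frame(name = name, insert_length = L,
                      adapter_start = ifelse(L < rl, L, NA_integer_),
                      insert_seq = inserts)
  attr(truth, "read_length") <- rl
  attr(truth, "insert_distribution") <-
    sprintf("truncnorm(mean=%g, sd=%g, min=%d, max=%d)",
            config$insert_mean, config$insert_sd, config$insert_min,
            config$insert_max)

  if (!is.null(out_prefix)) {
    write_fastq(r1df, paste0(out_prefix, "_1.fq.gz"))
    write_fastq(r2df, paste0(out_prefix, "_2.fq.gz"))
    write_truth(truth, paste0(out_prefix, "_truth.tsv"))
  }
  list(r1 = r1df, r2 = r2df, truth = truth, realized_error_rate = realized)
}

#' Write / read a simulator truth table
#'
#' Tab-separated with `#`-prefixed header comments recording the read
#' length and insert-length distribution.
#'
#' @param truth Truth data frame from [simulate_pairs()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# read_length: %d", attr(truth, "read_length")),
               sprintf("# insert_distribution: %s",
                       attr(truth, "insert_distribution"))), con)
  suppressWarnings(write.table(truth, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  hdr <- readLines(path, n = 5L)
  hdr <- hdr[startsWith(hdr, "#")]
  truth <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  rlm <- regmatches(hdr, regexec("read_length: ([0-9]+)", hdr))
  rl <- as.integer(unlist(lapply(rlm, `[`, 2)))
  if (length(rl)) attr(truth, "read_length") <- rl[!is.na(rl)][1]
  truth
}
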
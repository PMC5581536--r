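# Independent reference implementations used as oracles.  These are
# deliberately naive: full-matrix dynamic programming and exhaustive
# enumeration, sharing no code with the package internals.

ORACLE_MASKS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L,
                  S = 6L, W = 9L, K = 12L, M = 3L, B = 14L, D = 13L,
                  H = 11L, V = 7L, N = 15L)

oracle_pat_mask <- function(ch) {
  m <- ORACLE_MASKS[[ch]]
  if (ch == "N") m <- bitwOr(m, 16L)
  m
}
oracle_sub_mask <- function(ch) {
  if (ch %in% c("A", "C", "G", "T", "U")) return(ORACLE_MASKS[[ch]])
  if (ch == "N") return(16L)
  ORACLE_MASKS[[ch]]
}

# Full-matrix semi-global DP for a 3' adapter: D(0,j) = 0 (free read-prefix
# skip), D(i,0) = i.  Each cell carries (edits, matches, start) optimised
# lexicographically: min edits, then max matches, then leftmost start.
# Candidates: bottom row (full adapter ending at j) plus the last column
# (partial adapter at the 3' read end).
oracle_semiglobal_back <- function(adapter, read, max_error_rate,
                                   min_overlap, allow_indels = TRUE) {
  a <- strsplit(adapter, "")[[1]]
  r <- strsplit(read, "")[[1]]
  m <- length(a); n <- length(r)
  am <- vapply(a, oracle_pat_mask, integer(1))
  rm_ <- vapply(r, oracle_sub_mask, integer(1))

  cands <- list()
  if (!allow_indels) {
    for (s in 0:(n - 1)) {
      alen <- min(m, n - s)
      mat <- sum(bitwAnd(am[seq_len(alen)],
                         rm_[s + seq_len(alen)]) != 0L)
      cands[[length(cands) + 1L]] <-
        data.frame(read_start = s, read_stop = s + alen, alen = alen,
                   errors = alen - mat, matches = mat)
    }
  } else {
    D <- matrix(0L, m + 1, n + 1)
    M <- matrix(0L, m + 1, n + 1)
    S <- matrix(0L, m + 1, n + 1)
    D[, 1] <- 0:m
    S[1, ] <- 0:n
    for (j in 2:(n + 1)) {
      for (i in 2:(m + 1)) {
        hit <- bitwAnd(am[i - 1], rm_[j - 1]) != 0L
        opts <- rbind(
          c(D[i - 1, j - 1] + !hit, M[i - 1, j - 1] + hit, S[i - 1, j - 1]),
          c(D[i, j - 1] + 1L, M[i, j - 1], S[i, j - 1]),
          c(D[i - 1, j] + 1L, M[i - 1, j], S[i - 1, j]))
        best <- opts[order(opts[, 1], -opts[, 2], opts[, 3])[1], ]
        D[i, j] <- best[1]; M[i, j] <- best[2]; S[i, j] <- best[3]
      }
    }
    for (j in 0:n) {                         # bottom row
      cands[[length(cands) + 1L]] <-
        data.frame(read_start = S[m + 1, j + 1], read_stop = j, alen = m,
                   errors = D[m + 1, j + 1], matches = M[m + 1, j + 1])
    }
    if (m > 1) {
      for (i in 1:(m - 1)) {                 # last column, partial adapter
        cands[[length(cands) + 1L]] <-
          data.frame(read_start = S[i + 1, n + 1], read_stop = n, alen = i,
                     errors = D[i + 1, n + 1], matches = M[i + 1, n + 1])
      }
    }
  }
  all <- do.call(rbind, cands)
  acc <- all[all$alen >= min_overlap &
               all$errors <= max_error_rate * all$alen + 1e-9, ,
             drop = FALSE]
  best <- NULL
  if (nrow(acc)) {
    ord <- order(-acc$matches, acc$errors, -acc$alen, acc$read_start)
    best <- acc[ord[1], ]
  }
  list(accepted = acc[order(acc$read_start, acc$read_stop, acc$alen), ,
                      drop = FALSE],
       best = best)
}

# Exhaustive 3'-quality-trim oracle: evaluate every cut point, keep the one
# maximising the suffix sum of (cutoff - q); ties keep the longest read.
oracle_quality_cut <- function(q, cutoff) {
  n <- length(q)
  sums <- vapply(0:(n - 1), function(cut) sum(cutoff - q[(cut + 1):n]),
                 numeric(1))
  best <- max(sums)
  if (best <= 0) return(n)
  max(which(sums == best)) - 1L            # kept length, rightmost maximum
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# n uniform-random reads of equal length, built in one draw
random_reads <- function(n, len) {
  big <- paste(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
               collapse = "")
  substring(big, seq(1L, n * len, by = len), seq(len, n * len, by = len))
}

# reads carrying `planted` at a random interior position, 3' of a genomic
# prefix, followed by random filler — the geometry of read-through into a
# 3' adapter
planted_reads <- function(n, planted, len = 125L, pre_range = 30:90) {
  pre <- random_reads(n, len)
  fill <- random_reads(n, len)
  plen <- sample(pre_range, n, replace = TRUE)
  substr(paste0(substr(pre, 1, plen), planted, fill), 1, len)
}

# Build one synthetic pair with a known insert (error-free unless edits are
# applied by the caller).
build_pair <- function(insert_len, read_len = 125,
                       a1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                       a2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA",
                       q = 40L, name = "pair") {
  ins <- random_seq(insert_len)
  pad <- function(core, adapter) {
    s <- paste0(core, adapter)
    if (nchar(s) < read_len) {
      s <- paste0(s, random_seq(read_len - nchar(s)))
    }
    substr(s, 1, read_len)
  }
  r1 <- pad(substr(ins, 1, min(insert_len, read_len)), a1)
  r2 <- pad(substr(reverse_complement(ins), 1, min(insert_len, read_len)),
            a2)
  list(read1 = read_record(name, r1, rep(q, read_len), mate = 1L),
       read2 = read_record(name, r2, rep(q, read_len), mate = 2L),
       insert = ins)
}

default_params <- function() {
  insert_match_params("AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                      "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTA")
}

expect_same_alignment <- function(adapter, read, max_error_rate = 0.1,
                                  min_overlap = 3L, allow_indels = TRUE) {
  spec <- adapter_spec(adapter, max_error_rate = max_error_rate,
                       min_overlap = min_overlap,
                       allow_indels = allow_indels)
  ora <- oracle_semiglobal_back(adapter, read, max_error_rate, min_overlap,
                                allow_indels)
  got <- readtrim:::semiglobal_candidates(spec, read)
  gdf <- as.data.frame(got)
  gdf <- gdf[order(gdf$read_start, gdf$read_stop, gdf$alen), , drop = FALSE]
  rownames(gdf) <- rownames(ora$accepted) <- NULL
  expect_equal(gdf, ora$accepted,
               info = paste("candidates for", adapter, "vs", read))
  res <- semiglobal_align(spec, read)
  if (is.null(ora$best)) {
    expect_null(res, info = paste(adapter, "vs", read))
  } else {
    expect_false(is.null(res), info = paste(adapter, "vs", read))
    expect_equal(res$read_start, ora$best$read_start,
                 info = paste(adapter, "vs", read))
    expect_equal(res$read_stop, ora$best$read_stop)
    expect_equal(res$adapter_stop - res$adapter_start, ora$best$alen)
    expect_equal(res$errors, ora$best$errors)
    expect_equal(res$matches, ora$best$matches)
  }
}
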
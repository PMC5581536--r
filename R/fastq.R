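# FASTQ input/output.  Records are held as plain data frames with columns
# name / seq / qual (qualities as Phred+33 strings), the lightest container
# for whole-file streaming.  Parsing goes through Biostrings; writing is
# 4-line formatting onto a (gz)file connection so that output remains
# gzip-member-concatenable.

#' Read a FASTQ file
#'
#' Plain or gzip-compressed FASTQ with Phred+33 qualities.
#'
#' @param path Path to the FASTQ file.
#' @return A data frame with character columns `name`, `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("input not readable: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(name = if (is.null(names(x))) character(length(x)) else names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL)
}

#' Read paired-end FASTQ input
#'
#' Accepts two files (`in1`, `in2`), a single interleaved file
#' (`interleaved = TRUE`), or a single-end file. Mates are checked to stay
#' in sync: equal counts and matching record names (ignoring a trailing
#' `/1` / `/2` or comment).
#'
#' @param in1 First (or only) FASTQ file.
#' @param in2 Second FASTQ file, or `NULL`.
#' @param interleaved Treat `in1` as interleaved paired-end data.
#' @return A list with data-frame elements `r1` and `r2` (`r2` is `NULL`
#'   for single-end input).
#' @export
read_fastq_pair <- function(in1, in2 = NULL, interleaved = FALSE) {
  r1 <- read_fastq(in1)
  if (interleaved) {
    if (nrow(r1) %% 2L != 0L) {
      stop("interleaved input has an odd number of records", call. = FALSE)
    }
    odd <- seq(1L, nrow(r1), by = 2L)
    out <- list(r1 = r1[odd, , drop = FALSE],
                r2 = r1[odd + 1L, , drop = FALSE])
  } else if (!is.null(in2)) {
    out <- list(r1 = r1, r2 = read_fastq(in2))
  } else {
    return(list(r1 = r1, r2 = NULL))
  }
  rownames(out$r1) <- rownames(out$r2) <- NULL
  if (nrow(out$r1) != nrow(out$r2)) {
    n <- min(nrow(out$r1), nrow(out$r2))
    offending <- if (nrow(out$r1) > n) out$r1$name[n + 1L]
                 else out$r2$name[n + 1L]
    stop("mate files out of sync: unpaired record '", offending, "'",
         call. = FALSE)
  }
  b1 <- base_read_name(out$r1$name)
  b2 <- base_read_name(out$r2$name)
  bad <- which(b1 != b2)
  if (length(bad)) {
    stop("mate files out of sync at record '", out$r1$name[bad[1]], "'",
         call. = FALSE)
  }
  out
}

# strip a mate suffix (/1, /2) and any comment after whitespace
base_read_name <- function(x) {
  x <- sub("[ \t].*$", "", x)
  sub("/[12]$", "", x)
}

fastq_lines <- function(df) {
  if (!nrow(df)) return(character(0))
  paste0("@", df$name, "\n", df$seq, "\n+\n", df$qual)
}

#' Write records to a FASTQ file
#'
#' @param df Data frame with columns `name`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix selects gzip compression.
#' @param append Append to an existing file.
#' @return The path, invisibly.
#' @export
write_fastq <- function(df, path, append = FALSE) {
  con <- open_out(path, append)
  on.exit(close(con))
  writeLines(fastq_lines(df), con)
  invisible(path)
}

open_out <- function(path, append = FALSE) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("output not writable: ", path, call. = FALSE)
  }
  mode <- if (append) "ab" else "wb"
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# interleave two record data frames
interleave_records <- function(r1, r2) {
  n <- nrow(r1)
  idx <- rep(seq_len(n), each = 2L) + rep(c(0L, n), times = n)
  rbind(r1, r2)[idx, , drop = FALSE]
}
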
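# Read records: the unit flowing through every trimming stage.

#' Create a sequencing read record
#'
#' A read record bundles a name, a nucleotide string over `{A,C,G,T,N}` and
#' the per-base Phred qualities (integer scale; `Phred+33` on disk).
#'
#' @param name Text identifier.
#' @param bases Nucleotide string.
#' @param qualities Integer vector of Phred scores in `[0, 93]`, one per
#'   base, or a single Phred+33-encoded character string of the same length.
#' @param mate Optional mate number (1 or 2) for paired-end reads.
#' @return An object of class `read_record` with fields `name`, `bases`,
#'   `qualities` and `mate`.
#' @examples
#' read_record("r1", "ACGT", c(30L, 30L, 30L, 2L))
#' @export
read_record <- function(name, bases, qualities, mate = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(bases), length(bases) == 1L)
  if (is.character(qualities)) qualities <- phred_from_string(qualities)
  qualities <- as.integer(qualities)
  if (length(qualities) != nchar(bases)) {
    stop("bases and qualities must have equal length", call. = FALSE)
  }
  if (length(qualities) && (min(qualities) < 0L || max(qualities) > 93L)) {
    stop("qualities must lie in [0, 93]", call. = FALSE)
  }
  if (!is.null(mate)) stopifnot(mate %in% c(1L, 2L))
  structure(list(name = name, bases = bases, qualities = qualities,
                 mate = mate),
            class = "read_record")
}

#' @export
print.read_record <- function(x, ...) {
  cat("<read_record> ", x$name, "\n  ", x$bases, "\n  ",
      phred_to_string(x$qualities), "\n", sep = "")
  invisible(x)
}

#' @export
length.read_record <- function(x) nchar(x$bases)

#' Convert between integer Phred scores and Phred+33 strings
#'
#' @param qualities Integer vector of Phred scores.
#' @return `phred_to_string()` returns a single character string;
#'   `phred_from_string()` returns an integer vector.
#' @examples
#' phred_to_string(c(0L, 40L))   # "!I"
#' phred_from_string("!I")       # c(0L, 40L)
#' @export
phred_to_string <- function(qualities) {
  if (!length(qualities)) return("")
  intToUtf8(as.integer(qualities) + 33L)
}

#' @rdname phred_to_string
#' @param x A Phred+33-encoded character string.
#' @export
phred_from_string <- function(x) {
  if (!nchar(x)) return(integer(0))
  utf8ToInt(x) - 33L
}

# Mean base-call error probability of a record (used for the poor-read
# overwrite rule and BEST_READ tie-breaking).
mean_error_prob <- function(qualities) {
  if (!length(qualities)) return(1)
  mean(10^(-qualities / 10))
}
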
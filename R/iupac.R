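# IUPAC nucleotide codes as 4-bit masks (A = 1, C = 2, G = 4, T = 8).
# Two characters are compatible iff their masks share a set bit.

.IUPAC_MASKS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.IUPAC_COMP <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Encode an IUPAC nucleotide code as a 4-bit mask
#'
#' Each of the 15 IUPAC ambiguity codes denotes a set of nucleotides; the
#' mask has one bit per nucleotide (A = 1, C = 2, G = 4, T = 8). Two symbols
#' are compatible exactly when their masks share a set bit, so degenerate
#' adapter characters can be compared with a single bitwise AND.
#'
#' @param symbol A single IUPAC character (case-insensitive; `U` is treated
#'   as `T`).
#' @return An integer in `[1, 15]`.
#' @examples
#' encode_iupac("A")  # 1
#' encode_iupac("N")  # 15: matches any nucleotide
#' encode_iupac("Y")  # 10: C or T
#' @seealso [iupac_compatible()]
#' @export
encode_iupac <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nchar(symbol) == 1L)
  m <- .IUPAC_MASKS[toupper(symbol)]
  if (is.na(m)) {
    stop("invalid IUPAC character '", symbol, "' at position 1",
         call. = FALSE)
  }
  unname(m)
}

#' Test whether two IUPAC codes are compatible
#'
#' @param a,b Single IUPAC characters.
#' @return `TRUE` when the nucleotide sets denoted by `a` and `b` intersect.
#' @examples
#' iupac_compatible("Y", "H")  # TRUE: both contain C and T
#' iupac_compatible("A", "Y")  # FALSE
#' @export
iupac_compatible <- function(a, b) {
  bitwAnd(encode_iupac(a), encode_iupac(b)) != 0L
}

#' Reverse-complement a nucleotide sequence
#'
#' Vectorised over `x`; all IUPAC ambiguity codes are complemented correctly
#' (Y to R, H to D, N to N, ...) and case is preserved.
#'
#' @param x Character vector of nucleotide/IUPAC strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")  # "ACGT" (self-complementary)
#' reverse_complement("AAYC")  # "GRTT"
#' @export
reverse_complement <- function(x) {
  cpp_revcomp(as.character(x))
}
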
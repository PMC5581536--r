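# Error-rate estimation from base qualities.

#' Estimate the sequencing error rate from base qualities
#'
#' Converts each Phred quality `q` to its base-call error probability
#' `10^(-q/10)` and averages over all bases of a read sample. Fast, but
#' tends to overestimate the true error rate because base-callers are
#' conservative. The alternative shadow-regression estimator is exposed as
#' a named method but not implemented here.
#'
#' @param input A FASTQ path, a data frame with a `qual` column, or a
#'   character vector of Phred+33 quality strings.
#' @param sample_size Number of reads sampled (the first `sample_size`).
#'   Default 10000.
#' @param method `"quality"` (implemented) or `"shadow"` (fails fast).
#' @return An object of class `error_estimate` with fields
#'   `per_file_error`, `sample_size` (reads actually used) and
#'   `per_position_error`.
#' @examples
#' estimate_error(c("IIII", "IIII"))  # all q40 -> 1e-4
#' @export
estimate_error <- function(input, sample_size = 10000L,
                           method = c("quality", "shadow")) {
  method <- match.arg(method)
  if (method == "shadow") {
    stop("shadow-regression estimation is not implemented here; see the ",
         "shadow-regression literature for its definition — use ",
         'method = "quality"', call. = FALSE)
  }
  if (is.character(input) && length(input) == 1L && file.exists(input)) {
    input <- read_fastq(input)
  }
  quals <- if (is.data.frame(input)) input$qual else input
  if (!length(quals)) stop("no reads to estimate from", call. = FALSE)
  quals <- head(quals, sample_size)
  q <- utf8ToInt(paste(quals, collapse = "")) - 33L
  if (!length(q)) stop("no bases to estimate from", call. = FALSE)
  err <- 10^(-q / 10)

  maxlen <- max(nchar(quals))
  per_pos <- rep(NA_real_, maxlen)
  for (p in seq_len(maxlen)) {
    ch <- substr(quals, p, p)
    ch <- ch[nchar(ch) > 0]
    if (!length(ch)) next
    qp <- utf8ToInt(paste(ch, collapse = "")) - 33L
    per_pos[p] <- mean(10^(-qp / 10))
  }
  structure(list(per_file_error = mean(err),
                 sample_size = length(quals),
                 per_position_error = per_pos),
            class = "error_estimate")
}

#' @export
print.error_estimate <- function(x, ...) {
  cat(sprintf("<error_estimate> %.4g%% over %d reads\n",
              100 * x$per_file_error, x$sample_size))
  invisible(x)
}
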
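#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  revcomp_cpp(toupper(as.character(x)))
}

#' Convert a 0-based half-open interval to 1-based inclusive (and back)
#'
#' TEloci stores coordinates 1-based inclusive throughout (the R/Bioconductor
#' convention); these helpers convert to and from the 0-based half-open
#' convention used by BED-style interchange.
#'
#' @param start,end interval bounds.
#' @return a list with `start` and `end` in the other convention.
#' @export
interval_0h_to_1i <- function(start, end) {
  stopifnot(all(start < end), all(start >= 0))
  list(start = start + 1L, end = end)
}

#' @rdname interval_0h_to_1i
#' @export
interval_1i_to_0h <- function(start, end) {
  stopifnot(all(start <= end), all(start >= 1))
  list(start = start - 1L, end = end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_df <- function(...) {
  cols <- list(...)
  structure(as.data.frame(cols, stringsAsFactors = FALSE),
            row.names = integer(0))
}
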
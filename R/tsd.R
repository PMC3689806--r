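#' Parse a target-site-duplication (TSD) specification
#'
#' A TE's TSD is declared on the description line of its FASTA record as a
#' `TSD=<value>` token.  Three forms are accepted:
#'
#' * an exact DNA sequence, e.g. `TSD=TAA`;
#' * an integer length, e.g. `TSD=3` (any sequence of that length matches);
#' * a fixed-width pattern over the IUPAC / character-class alphabet, e.g.
#'   `TSD=T[AT]A` or `TSD=TNA`.  Each plain letter, IUPAC ambiguity code or
#'   `[...]` class matches exactly one base, so the pattern implies a fixed
#'   width.  Variable-width regular-expression constructs (`*`, `+`, `?`,
#'   `{}`, `|`, groups) are rejected: TSD-overlap calling needs a fixed
#'   overlap width.
#'
#' @param raw the specification, with or without the leading `TSD=`.
#' @return a `tsd_matcher` object with fields `kind` (`"exact"`, `"length"`
#'   or `"pattern"`), `value`, `width` and a compiled anchored `regex`.
#' @examples
#' m <- parse_tsd_spec("TSD=TAA")
#' tsd_matches(m, "TAA")
#' tsd_matches(m, "TAG")
#' @export
parse_tsd_spec <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || !nzchar(raw))
    stop("TSD specification must be a single non-empty string")
  tok <- sub("^TSD=", "", trimws(raw), ignore.case = TRUE)
  if (!nzchar(tok))
    stop("malformed TSD specification: ", sQuote(raw))

  if (grepl("^[0-9]+$", tok)) {
    width <- as.integer(tok)
    if (width < 1)
      stop("malformed TSD specification (zero width): ", sQuote(raw))
    m <- list(kind = "length", value = width, width = width,
              regex = paste0("^[ACGT]{", width, "}$"))
  } else if (grepl("^[ACGT]+$", tok)) {
    m <- list(kind = "exact", value = tok, width = nchar(tok),
              regex = paste0("^", tok, "$"))
  } else {
    m <- parse_tsd_pattern(tok, raw)
  }
  structure(m, class = "tsd_matcher")
}

# IUPAC single-base ambiguity codes as character classes
iupac_classes <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

parse_tsd_pattern <- function(tok, raw) {
  chars <- strsplit(tok, "")[[1]]
  out <- character(0)
  width <- 0L
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars))
        stop("malformed TSD specification (unclosed '['): ", sQuote(raw))
      cls <- chars[(i + 1L):(j - 1L)]
      if (length(cls) == 0 || !all(cls %in% c("A", "C", "G", "T")))
        stop("malformed TSD specification (illegal class): ", sQuote(raw))
      out <- c(out, paste0("[", paste(cls, collapse = ""), "]"))
      width <- width + 1L
      i <- j + 1L
    } else if (ch == ".") {
      out <- c(out, "[ACGT]")
      width <- width + 1L
      i <- i + 1L
    } else if (toupper(ch) %in% names(iupac_classes)) {
      out <- c(out, iupac_classes[[toupper(ch)]])
      width <- width + 1L
      i <- i + 1L
    } else if (ch %in% c("*", "+", "?", "{", "}", "|", "(", ")")) {
      stop("malformed TSD specification (variable-width construct ",
           sQuote(ch), "): ", sQuote(raw))
    } else {
      stop("malformed TSD specification (illegal character ",
           sQuote(ch), "): ", sQuote(raw))
    }
  }
  if (width < 1)
    stop("malformed TSD specification (zero width): ", sQuote(raw))
  list(kind = "pattern", value = tok, width = width,
       regex = paste0("^", paste(out, collapse = ""), "$"))
}

#' Test sequences against a TSD matcher
#'
#' @param matcher a `tsd_matcher` from [parse_tsd_spec()].
#' @param x character vector of candidate sequences (must have the matcher's
#'   width to be able to match).
#' @param both_strands if `TRUE`, a sequence whose reverse complement
#'   satisfies the matcher also matches (the TSD may be read on either
#'   strand when flanks are mapped).
#' @return logical vector.
#' @export
tsd_matches <- function(matcher, x, both_strands = FALSE) {
  stopifnot(inherits(matcher, "tsd_matcher"))
  x <- toupper(as.character(x))
  hit <- grepl(matcher$regex, x)
  if (both_strands && matcher$kind != "length")
    hit <- hit | grepl(matcher$regex, revcomp(x))
  hit
}

#' @export
print.tsd_matcher <- function(x, ...) {
  cat(sprintf("TSD matcher: kind=%s value=%s width=%d\n",
              x$kind, as.character(x$value), x$width))
  invisible(x)
}

#' Construct a TE model
#'
#' @param name element name.
#' @param sequence element sequence (A/C/G/T/N).
#' @param tsd_spec TSD specification string (see [parse_tsd_spec()]).
#' @return a `te_model` object with fields `name`, `sequence`, `tsd`
#'   (a `tsd_matcher`) and `length`.
#' @export
te_model <- function(name, sequence, tsd_spec) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence) || grepl("[^ACGTN]", sequence))
    stop("TE sequence must be a non-empty A/C/G/T/N string")
  structure(list(name = as.character(name), sequence = sequence,
                 tsd = parse_tsd_spec(tsd_spec),
                 length = nchar(sequence)),
            class = "te_model")
}

#' @export
print.te_model <- function(x, ...) {
  cat(sprintf("TE model '%s': %d bp, TSD %s (%s, width %d)\n",
              x$name, x$length, as.character(x$tsd$value), x$tsd$kind,
              x$tsd$width))
  invisible(x)
}

#' Read a TE model from a FASTA file
#'
#' The TSD specification is taken from a `TSD=<value>` token on the
#' description line, e.g. `>mping TSD=TAA`.
#'
#' @param path FASTA file with one TE record.
#' @param tsd optional override for the TSD specification.
#' @return a [te_model()].
#' @export
read_te_fasta <- function(path, tsd = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1) stop("no records in TE FASTA ", path)
  if (length(set) > 1)
    warning("multiple records in TE FASTA; using the first")
  desc <- names(set)[1]
  name <- sub("\\s.*$", "", desc)
  if (is.null(tsd)) {
    m <- regmatches(desc, regexpr("TSD=\\S+", desc, ignore.case = TRUE))
    if (length(m) == 0)
      stop("no TSD=<spec> token on the description line of ", path,
           " and no override supplied")
    tsd <- m[1]
  }
  te_model(name, as.character(set[[1]]), tsd)
}
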
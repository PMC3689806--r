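#' Count spanner reads at an insertion site
#'
#' Spanners are whole (untrimmed) reads that support the allele without the
#' insertion: their alignment must contiguously cover the target-site
#' interval padded by `pad` bp on each side, with no alignment gap across
#' the padded window (no deletion overlapping it and no insertion opening
#' inside it or at the target-site boundaries) and -- when the alignment
#' records distinguish matches from mismatches (`=`/`X` CIGAR ops, as the
#' internal aligner emits) -- no mismatch inside the padded window.  The
#' padding matters: a read ending inside the target site matches the
#' insertion allele equally well (the TSD is duplicated at the junction),
#' and a read from the insertion allele carrying a few terminal TE bases
#' aligns across the site with mismatches; neither is evidence for an empty
#' site.  Reads flagged ambiguous (multiple best placements) are not
#' counted.
#'
#' @param site a one-row insertion call (needs `chrom`, `tsd_start`,
#'   `tsd_end`).
#' @param alignments whole-read alignment data frame from
#'   [align_whole_reads()] or [read_alignments()].
#' @param chroms chromosome names known to the alignments (defaults to
#'   those present); a site on an unknown chromosome is an error.
#' @param pad exact-match margin around the target site (default: the
#'   target-site width plus 5 bp).  The margin must be wide enough that a
#'   junction read whose terminal TE bases happen to coincide with the
#'   reference flank cannot slip through: both the TE ends and the flank
#'   are fixed sequences, so at an unlucky site a short margin leaks every
#'   junction read on that side, not just a random few.
#' @return integer spanner count.
#' @export
count_spanners <- function(site, alignments, chroms = NULL, pad = NULL) {
  chroms <- chroms %||% unique(alignments$chrom)
  if (!(site$chrom %in% chroms))
    stop("site chromosome ", site$chrom, " absent from alignments")
  t1 <- site$tsd_start
  t2 <- site$tsd_end
  pad <- pad %||% (t2 - t1 + 1L + 5L)
  w1 <- t1 - pad
  w2 <- t2 + pad
  a <- alignments[alignments$chrom == site$chrom & !alignments$ambiguous &
                    alignments$pos <= w1 & alignments$end >= w2, ,
                  drop = FALSE]
  if (nrow(a) == 0) return(0L)
  ok <- vapply(seq_len(nrow(a)), function(i) {
    ops <- cigar_ref_ops(a$cigar[i], a$pos[i])
    gap <- (ops$type == "D" & ops$start <= w2 & ops$end >= w1) |
      (ops$type == "I" & ops$start >= t1 - 1L & ops$start <= t2 + 1L) |
      (ops$type == "I" & ops$start > w1 & ops$start <= w2) |
      (ops$type == "X" & ops$start <= w2 & ops$end >= w1)
    !any(gap)
  }, TRUE)
  sum(ok)
}

# indel and mismatch operations of one CIGAR in reference coordinates; an
# insertion of length k between ref positions p-1 and p is reported as type
# "I", start = end = p, length k
cigar_ref_ops <- function(cigar, pos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  ref_pos <- pos
  type <- character(0)
  start <- integer(0)
  end <- integer(0)
  length_ <- integer(0)
  for (k in seq_along(ops)) {
    op <- ops[k]
    len <- lens[k]
    if (op == "I") {
      type <- c(type, "I"); start <- c(start, ref_pos)
      end <- c(end, ref_pos); length_ <- c(length_, len)
    } else if (op == "D") {
      type <- c(type, "D"); start <- c(start, ref_pos)
      end <- c(end, ref_pos + len - 1L); length_ <- c(length_, len)
      ref_pos <- ref_pos + len
    } else if (op == "X") {
      type <- c(type, "X"); start <- c(start, ref_pos)
      end <- c(end, ref_pos + len - 1L); length_ <- c(length_, len)
      ref_pos <- ref_pos + len
    } else if (op %in% c("M", "=", "N")) {
      ref_pos <- ref_pos + len
    }
  }
  data.frame(type = type, start = start, end = end, length = length_,
             stringsAsFactors = FALSE)
}

cigar_indels <- function(cigar, pos) {
  ops <- cigar_ref_ops(cigar, pos)
  ops[ops$type %in% c("I", "D"), , drop = FALSE]
}

#' Detect an excision footprint near an insertion site
#'
#' Imprecise excision leaves a few residual bases at the emptied site, seen
#' as a consistent small insertion or deletion in whole-read alignments
#' within one TSD width of the target site.  The most-supported indel with
#' at least `min_support` supporting reads is reported; precise excisions
#' leave no footprint and return nothing.
#'
#' A read only lends footprint support if its alignment is clean around the
#' site: exactly one indel and (when `=`/`X` CIGAR ops are available) no
#' mismatches within the window.  Junction reads of the insertion allele
#' that carry a few terminal TE bases can otherwise be squeezed into the
#' reference with a recurring indel-plus-mismatch pattern and masquerade as
#' footprint evidence.
#'
#' @param site a one-row insertion call (`chrom`, `tsd_start`, `tsd_end`).
#' @param alignments whole-read alignment data frame.
#' @param tsd_width TSD width in bp; the search window is the target site
#'   padded by this on both sides.
#' @param min_support minimum reads carrying the identical indel
#'   (default 2).
#' @return one-row data frame (`indel_type`, `offset`, `ref_start`,
#'   `length`, `supporting_reads`) or `NULL`.
#' @export
detect_footprint <- function(site, alignments, tsd_width, min_support = 2) {
  t1 <- site$tsd_start
  t2 <- site$tsd_end
  w <- tsd_width
  a <- alignments[alignments$chrom == site$chrom &
                    alignments$pos <= t2 + w & alignments$end >= t1 - w, ,
                  drop = FALSE]
  if (nrow(a) == 0) return(NULL)
  ind <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    ops <- cigar_ref_ops(a$cigar[i], a$pos[i])
    in_win <- ops$end >= t1 - w & ops$start <= t2 + w
    if (any(ops$type == "X" & in_win)) return(NULL)
    ii <- ops[ops$type %in% c("I", "D") & in_win, , drop = FALSE]
    if (nrow(ii) != 1) return(NULL)
    ii
  }))
  if (is.null(ind) || nrow(ind) == 0) return(NULL)
  # offset of an indel from the target-site span (0 when overlapping it)
  ind$offset <- ifelse(ind$end < t1, ind$end - t1,
                       ifelse(ind$start > t2, ind$start - t2, 0L))
  ind <- ind[abs(ind$offset) <= w, , drop = FALSE]
  if (nrow(ind) == 0) return(NULL)
  key <- paste(ind$type, ind$start, ind$length)
  support <- table(key)
  best <- names(support)[support == max(support)]
  if (max(support) < min_support) return(NULL)
  cand <- unique(ind[key %in% best, , drop = FALSE])
  cand <- cand[order(abs(cand$offset), cand$start, cand$type), ,
               drop = FALSE]
  top <- cand[1, , drop = FALSE]
  data.frame(indel_type = ifelse(top$type == "I", "insertion", "deletion"),
             offset = top$offset, ref_start = top$start,
             length = top$length,
             supporting_reads = as.integer(max(support)),
             stringsAsFactors = FALSE)
}

#' Genotype all non-reference insertion sites
#'
#' For each called site, computes the average flanker count F from the
#' call's left/right counts, counts spanners in the whole-read alignments,
#' classifies the genotype through the rule cascade, and scans for an
#' excision footprint.
#'
#' @param calls insertion calls ([call_insertions()] output or a report
#'   re-read with [read_insertion_table()]).
#' @param alignments whole-read alignment data frame ([align_whole_reads()]
#'   or [read_alignments()]).
#' @param tsd_width TSD width used for the footprint window; defaults to
#'   the width of the calls' TSD spans.
#' @param min_footprint_support minimum reads for a footprint (default 2).
#' @param chroms chromosome names known to the alignments; sites on other
#'   chromosomes raise an error listing them.
#' @return data frame with one row per site: coordinates, `avg_flankers`,
#'   `spanners`, `genotype`, `rule`, and footprint columns.
#' @export
characterize_all <- function(calls, alignments, tsd_width = NULL,
                             min_footprint_support = 2, chroms = NULL) {
  empty <- empty_df(te_name = character(0), chrom = character(0),
                    tsd_start = integer(0), tsd_end = integer(0),
                    avg_flankers = numeric(0), spanners = integer(0),
                    genotype = character(0), rule = character(0),
                    footprint = logical(0), footprint_type = character(0),
                    footprint_offset = integer(0),
                    footprint_support = integer(0))
  if (nrow(calls) == 0) return(empty)
  chroms <- chroms %||% unique(alignments$chrom)
  bad <- !(calls$chrom %in% chroms)
  if (any(bad))
    stop("sites on chromosomes absent from the alignments: ",
         paste0(calls$chrom[bad], ":", calls$tsd_start[bad], collapse = ", "))
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    site <- calls[i, , drop = FALSE]
    F <- (site$left_count + site$right_count) / 2
    S <- count_spanners(site, alignments, chroms = chroms)
    g <- classify_genotype(F, S)
    w <- tsd_width %||% (site$tsd_end - site$tsd_start + 1L)
    fp <- detect_footprint(site, alignments, tsd_width = w,
                           min_support = min_footprint_support)
    data.frame(te_name = site$te_name %||% "TE", chrom = site$chrom,
               tsd_start = site$tsd_start, tsd_end = site$tsd_end,
               avg_flankers = F, spanners = S,
               genotype = g$genotype, rule = g$rule,
               footprint = !is.null(fp),
               footprint_type = if (is.null(fp)) NA_character_ else
                 fp$indel_type,
               footprint_offset = if (is.null(fp)) NA_integer_ else
                 fp$offset,
               footprint_support = if (is.null(fp)) NA_integer_ else
                 fp$supporting_reads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the genotype report
#'
#' @param genotypes output of [characterize_all()].
#' @param path output tab-delimited file.
#' @export
write_genotype_report <- function(genotypes, path) {
  write.table(genotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
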
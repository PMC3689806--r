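#' Discover non-reference TE insertions from short reads
#'
#' Runs the full discovery pipeline: scan reads for end-anchored TE
#' matches, trim the TE-matching portions, map the remaining genomic flanks
#' uniquely to the reference, cluster them, and call insertions at perfect
#' TSD overlaps between left and right flankers.  Optionally also scans the
#' reference for full-length copies of the element and classifies them as
#' shared or reference-only.
#'
#' @param te a [te_model()] (or path to a TE FASTA with a `TSD=` token).
#' @param reference named character vector of reference sequences (or path
#'   to a FASTA).
#' @param reads read data frame from [read_fastq()].
#' @param seed_len,min_aligned,allowance,min_trimmed_len TE-scan
#'   parameters, see [te_scan()].
#' @param max_genome_mismatch maximum mismatches for a flank placement
#'   (default 3).
#' @param reference_scan also classify reference TE copies (default FALSE).
#' @param mate_anchor optional mate placements for paired rescue, see
#'   [align_trimmed_reads()].
#' @param verbose log per-stage counts (default FALSE).
#' @return a list of class `relocate_result`: `calls`, `flankers`
#'   (clustered flanker alignments), `trimmed`, `ref_copies` (when
#'   scanned), `stats`.
#' @export
relocate <- function(te, reference, reads, seed_len = 7, min_aligned = 10,
                     allowance = 0, min_trimmed_len = 10,
                     max_genome_mismatch = 3, reference_scan = FALSE,
                     mate_anchor = NULL, verbose = FALSE) {
  if (is.character(te) && length(te) == 1 && file.exists(te))
    te <- read_te_fasta(te)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference) && is.null(names(reference)))
    reference <- read_fasta(reference)
  stopifnot(inherits(te, "te_model"))

  trimmed <- te_scan(reads, te, seed_len = seed_len,
                     min_aligned = min_aligned, allowance = allowance,
                     min_trimmed_len = min_trimmed_len)
  flankers <- align_trimmed_reads(trimmed, reference,
                                  max_mismatch = max_genome_mismatch,
                                  mate_anchor = mate_anchor)
  clusters <- cluster_flankers(flankers)
  calls <- call_insertions(clusters, te$tsd, reference, te_name = te$name)
  ref_copies <- NULL
  if (reference_scan) {
    copies <- scan_reference_for_te(reference, te)
    ref_copies <- classify_reference_sites(copies, flankers)
  }
  stats <- c(attr(trimmed, "stats"),
             aligned_unique = nrow(flankers),
             clusters = if (nrow(clusters)) max(clusters$cluster) else 0L,
             calls = nrow(calls))
  if (verbose) {
    for (nm in names(stats))
      message(sprintf("relocate: %s=%d", nm, stats[[nm]]))
  }
  structure(list(calls = calls, flankers = clusters, trimmed = trimmed,
                 ref_copies = ref_copies, stats = stats, te = te),
            class = "relocate_result")
}

#' @export
print.relocate_result <- function(x, ...) {
  cat(sprintf("TE insertion discovery: %d non-reference call(s) for '%s'\n",
              nrow(x$calls), x$te$name))
  if (!is.null(x$ref_copies))
    cat(sprintf("  reference copies: %d (%d shared, %d reference-only)\n",
                nrow(x$ref_copies),
                sum(x$ref_copies$class == "shared"),
                sum(x$ref_copies$class == "reference-only")))
  invisible(x)
}

#' Write the outputs of a discovery run
#'
#' Writes the tab-delimited non-reference insertion report and, when
#' reference copies were scanned, a GFF3 of reference/shared/reference-only
#' copies plus the non-reference calls.
#'
#' @param result a `relocate_result` from [relocate()].
#' @param reference named character vector of reference sequences.
#' @param outdir output directory.
#' @param flank_len flanking sequence length for the report (default 100).
#' @return named vector of written paths.
#' @export
write_relocate_results <- function(result, reference, outdir,
                                   flank_len = 100) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- file.path(outdir, paste0(result$te$name, "_insertions.tsv"))
  write_insertion_table(result$calls, reference, report,
                        flank_len = flank_len)
  paths <- c(report = report)
  feats <- if (nrow(result$calls)) {
    data.frame(chrom = result$calls$chrom, start = result$calls$tsd_start,
               end = result$calls$tsd_end,
               strand = result$calls$te_strand, class = "non-reference",
               te_name = result$te$name, stringsAsFactors = FALSE)
  } else {
    empty_df(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), class = character(0),
             te_name = character(0))
  }
  if (!is.null(result$ref_copies) && nrow(result$ref_copies)) {
    rc <- result$ref_copies
    feats <- rbind(feats, data.frame(
      chrom = rc$chrom, start = rc$start, end = rc$end, strand = rc$strand,
      class = rc$class, te_name = result$te$name, stringsAsFactors = FALSE))
  }
  gff <- file.path(outdir, paste0(result$te$name, "_sites.gff3"))
  write_gff3(feats, gff)
  paths["gff3"] <- gff
  paths
}
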
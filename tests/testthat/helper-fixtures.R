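# shared fixture builders (everything generated in code; no data files)

fixture_te <- function() demo_te(seed = 42)

# a reference plus the haplotype carrying one TSD-duplicating insertion,
# and hand-cut junction reads with given flank / TE-overlap geometry
fixture_junction <- function(te, seed = 7, genome_length = 6000,
                             tsd_start = NULL) {
  ref <- generate_reference(seed, lengths = genome_length)
  sites <- find_tsd_sites(ref, te$tsd, min_gap = 200)
  if (is.null(tsd_start)) tsd_start <- sites$tsd_start[ceiling(nrow(sites) / 2)]
  hap <- plant_insertion(ref, te, "chr1", tsd_start)
  w <- te$tsd$width
  list(ref = ref, hap = hap, tsd_start = tsd_start,
       tsd_end = tsd_start + w - 1L, w = w,
       te_start_hap = tsd_start + w,            # first TE base in hap coords
       te_end_hap = tsd_start + w + te$length - 1L)
}

# read crossing the left junction: `flank` genomic bases (ending with the
# TSD) followed by `te_part` bases of the TE 5' end
left_junction_read <- function(fx, flank = 40, te_part = 30, id = "L1") {
  s <- fx$tsd_end - flank + 1L
  data.frame(id = id, mate = 0L,
             seq = substr(fx$hap[["chr1"]], s, fx$tsd_end + te_part),
             qual = strrep("I", flank + te_part), stringsAsFactors = FALSE)
}

# read crossing the right junction: `te_part` bases of the TE 3' end, then
# the second TSD copy and `flank - w` genomic bases
right_junction_read <- function(fx, flank = 40, te_part = 30, id = "R1") {
  s <- fx$te_end_hap - te_part + 1L
  data.frame(id = id, mate = 0L,
             seq = substr(fx$hap[["chr1"]], s, fx$te_end_hap + flank),
             qual = strrep("I", te_part + flank), stringsAsFactors = FALSE)
}

# minimal spanner-alignment row covering [t1-pad, t2+pad] exactly
spanner_row <- function(id, chrom, t1, t2, pad = NULL, readlen = 100) {
  pad <- if (is.null(pad)) t2 - t1 + 1L else pad
  pos <- t1 - pad - 5L
  data.frame(id = id, chrom = chrom, pos = pos,
             end = pos + readlen - 1L, strand = "+",
             cigar = paste0(readlen, "="), edit = 0L, ambiguous = FALSE,
             stringsAsFactors = FALSE)
}

qual_string <- function(phreds) intToUtf8(phreds + 33L, multiple = FALSE)
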
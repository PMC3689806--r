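# Independent brute-force oracles used to validate the fast implementations.
# These deliberately share no code with the package internals.

# all maximal exact ungapped matches between a read and a TE (both strands),
# found by enumerating every diagonal and extracting runs of equality
oracle_te_matches <- function(read, te, min_aligned = 10) {
  out <- list()
  L <- nchar(read)
  Tn <- nchar(te)
  tb <- strsplit(te, "")[[1]]
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else revcomp(read)
    rb <- strsplit(r, "")[[1]]
    for (d in (-(L - 1)):(Tn - 1)) {
      i_lo <- max(1L, 1L - d)
      i_hi <- min(L, Tn - d)
      if (i_lo > i_hi) next
      idx <- i_lo:i_hi
      eq <- rb[idx] == tb[idx + d] & rb[idx] != "N"
      rl <- rle(eq)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (j in seq_along(rl$values)) {
        if (rl$values[j] && rl$lengths[j] >= min_aligned) {
          s <- idx[starts[j]]
          e <- idx[ends[j]]
          if (strand == "+") { frs <- s; fre <- e }
          else { frs <- L - e + 1L; fre <- L - s + 1L }
          out[[length(out) + 1]] <- data.frame(
            r_start = frs, r_end = fre, t_start = s + d, t_end = e + d,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(r_start = integer(0), r_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  m <- unique(do.call(rbind, out))
  m[order(m$strand, m$r_start, m$t_start), , drop = FALSE]
}

# exhaustive ungapped placement: best mismatch count, its position(s)
oracle_place <- function(seq, reference, max_mismatch = 3) {
  best <- max_mismatch + 1L
  hits <- list()
  sb_f <- strsplit(seq, "")[[1]]
  sb_r <- strsplit(revcomp(seq), "")[[1]]
  L <- length(sb_f)
  for (chrom in names(reference)) {
    gb <- strsplit(reference[[chrom]], "")[[1]]
    G <- length(gb)
    if (G < L) next
    for (strand in c("+", "-")) {
      sb <- if (strand == "+") sb_f else sb_r
      for (p in 1:(G - L + 1L)) {
        win <- gb[p:(p + L - 1L)]
        mm <- sum(win != sb | win == "N" | sb == "N")
        if (mm < best) {
          best <- mm
          hits <- list(list(chrom = chrom, pos = p, strand = strand, mm = mm))
        } else if (mm == best && best <= max_mismatch) {
          hits[[length(hits) + 1]] <- list(chrom = chrom, pos = p,
                                           strand = strand, mm = mm)
        }
      }
    }
  }
  if (best > max_mismatch) return(NULL)
  list(best = best, n_best = length(hits), hits = hits)
}

# transitive closure clustering of intervals by repeated merging
oracle_clusters <- function(chrom, start, end) {
  n <- length(start)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && chrom[i] == chrom[j] &&
          start[i] <= end[j] && start[j] <= end[i] && lab[i] != lab[j]) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# independent interpreter of a TSD specification over one candidate string
oracle_tsd_accepts <- function(token, s) {
  tok <- sub("^TSD=", "", token)
  if (grepl("^[0-9]+$", tok))
    return(nchar(s) == as.integer(tok) && !grepl("[^ACGT]", s))
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  chars <- strsplit(tok, "")[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      cls <- character(0)
      while (chars[j] != "]") { cls <- c(cls, chars[j]); j <- j + 1L }
      sets[[length(sets) + 1]] <- cls
      i <- j + 1L
    } else if (ch == ".") {
      sets[[length(sets) + 1]] <- c("A", "C", "G", "T")
      i <- i + 1L
    } else {
      sets[[length(sets) + 1]] <- iupac[[toupper(ch)]]
      i <- i + 1L
    }
  }
  if (nchar(s) != length(sets)) return(FALSE)
  sb <- strsplit(s, "")[[1]]
  all(vapply(seq_along(sb), function(k) sb[k] %in% sets[[k]], TRUE))
}

# all strings over ACGT of width w
all_kmers <- function(w) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), w),
                              stringsAsFactors = FALSE))
}

# independent rule-by-rule evaluator of the genotype cascade, written as
# plain nested conditionals (no shared code with genotype_rules())
oracle_genotype <- function(F, S) {
  if (S == 0) return("homozygous")
  if (F >= 5 && S < 5) return("homozygous_somatic_excision")
  if (S <= 10 && S <= 0.2 * F) return("homozygous_somatic_excision")
  if (F <= 2 && S > 10) return("somatic_insertion")
  if (abs(F - S) <= (F + S) / 2 + 10) return("heterozygous")
  if (F > 10 && S > 10) return("heterozygous")
  if (F <= 10 && abs(S - F) > (F + S) / 2) return("somatic_insertion")
  "other"
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
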
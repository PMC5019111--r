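# Internal helpers shared across modules.

# Reverse complement of plain character DNA (vectorized).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, strict = TRUE, arg = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    if (strict) {
      abort(sprintf(
        "%s contains non-ACGT symbols (e.g. %s); use strict = FALSE to mark such windows unscorable",
        arg, sub(".*?([^ACGT]).*", "\\1", x[which(bad)[1]])
      ))
    }
  }
  bad
}

# Window geometry ------------------------------------------------------------
#
# Relative coordinates around an intron boundary skip 0: ..., -2, -1, +1, +2,
# ... For donors, +1 is the first intronic base (the boundary); the scoring
# window covers [-2..-1, +1..+7] (9 nt, GT at +1,+2).  For acceptors, -1 is
# the last intronic base (the boundary); the window covers [-24..-1, +1..+3]
# (27 nt, AG at -2,-1).

window_rel_positions <- function(kind) {
  if (kind == "donor") c(-2:-1, 1:7) else c(-24:-1, 1:3)
}

site_window_length <- function(kind) if (kind == "donor") 9L else 27L

# Genomic coordinate of a relative position given boundary, strand, kind.
rel_to_genomic <- function(rel, boundary, strand, kind) {
  stopifnot(all(rel != 0))
  n <- max(length(rel), length(boundary), length(strand))
  rel <- rep_len(rel, n)
  boundary <- rep_len(as.integer(boundary), n)
  strand <- rep_len(strand, n)
  if (kind == "donor") {
    # +1 maps onto the boundary base
    off <- ifelse(rel > 0, rel - 1L, rel)
  } else {
    # -1 maps onto the boundary base
    off <- ifelse(rel < 0, rel + 1L, rel)
  }
  ifelse(strand == "+", boundary + off, boundary - off)
}

# Inverse mapping: genomic position -> relative position (NA outside the
# window).  Vectorized over all arguments, including `kind`.
genomic_to_rel <- function(pos, boundary, strand, kind) {
  n <- max(length(pos), length(boundary), length(strand), length(kind))
  pos <- rep_len(pos, n); boundary <- rep_len(boundary, n)
  strand <- rep_len(strand, n); kind <- rep_len(kind, n)
  off <- ifelse(strand == "+", pos - boundary, boundary - pos)
  rel <- ifelse(kind == "donor",
                ifelse(off >= 0, off + 1L, off),
                ifelse(off <= 0, off - 1L, off))
  ok <- (kind == "donor" & rel %in% window_rel_positions("donor")) |
    (kind == "acceptor" & rel %in% window_rel_positions("acceptor"))
  rel[!ok] <- NA_integer_
  as.integer(rel)
}

# Genomic interval [start, end] of the scoring window.
window_interval <- function(boundary, strand, kind) {
  rel <- window_rel_positions(kind)
  g <- vapply(seq_along(boundary), function(i) {
    range(rel_to_genomic(rel, boundary[i], strand[i], kind))
  }, numeric(2))
  tibble(window_start = g[1, ], window_end = g[2, ])
}

# Substring extraction from a named character genome (list or named vector).
genome_seq <- function(genome, chrom, start, end) {
  if (inherits(genome, "DNAStringSet")) {
    contig <- genome[[chrom]]
    if (start < 1 || end > length(contig)) {
      abort(sprintf("window [%d, %d] outside contig '%s' (length %d)",
                    start, end, chrom, length(contig)))
    }
    return(as.character(Biostrings::subseq(contig, start, end)))
  }
  contig <- genome[[chrom]]
  if (is.null(contig)) abort(sprintf("unknown contig '%s'", chrom))
  if (start < 1 || end > nchar(contig)) {
    abort(sprintf("window [%d, %d] outside contig '%s' (length %d)",
                  start, end, chrom, nchar(contig)))
  }
  substr(contig, start, end)
}
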
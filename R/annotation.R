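# Annotation handling: transcripts -> introns -> deduplicated splice sites
# with strand-aware scoring windows.

#' Read transcript exon structures from a GTF file
#'
#' Parses exon features of a Gencode-dialect GTF into the flat exon table
#' the rest of the package consumes (one row per exon).  Other feature
#' types are ignored.
#'
#' @param path GTF file path.
#' @return Tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `exon_start`, `exon_end` (1-based inclusive).
#' @export
read_transcripts_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read GTF files")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_start = GenomicRanges::start(gr),
    exon_end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$transcript_id, .data$exon_start)
}

#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return A `Biostrings::DNAStringSet` named by contig.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*", "", names(g))
  g
}

validate_exons <- function(transcripts) {
  bad <- transcripts |>
    group_by(.data$transcript_id) |>
    summarise(ok = all(diff(.data$exon_start) > 0) &&
                all(head(.data$exon_end, -1) < tail(.data$exon_start, -1)),
              .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("unsorted or overlapping exons in transcript(s): %s",
                  paste(head(bad$transcript_id, 3), collapse = ", ")))
  }
}

#' Derive introns and deduplicated splice sites from transcript models
#'
#' One intron per adjacent exon pair per transcript; splice sites are
#' deduplicated on (chrom, strand, kind, boundary).  The boundary is the
#' 1-based genomic coordinate of the first intronic base for donors and the
#' last intronic base for acceptors.  A site is flagged `constitutive` when
#' every transcript of the same gene whose genomic span covers the boundary
#' actually uses the site, and `alternative` otherwise.
#'
#' @param transcripts Exon table as returned by [read_transcripts_gtf()]
#'   (columns `gene_id`, `transcript_id`, `chrom`, `strand`, `exon_start`,
#'   `exon_end`; exons sorted and non-overlapping within a transcript).
#' @return A list with two tibbles: `introns` (chrom, strand, intron_start,
#'   intron_end, donor_boundary, acceptor_boundary, length, transcript_id,
#'   gene_id) and `sites` (site_id, chrom, strand, kind, boundary,
#'   window_start, window_end, usage, n_transcripts).
#' @export
derive_introns <- function(transcripts) {
  validate_exons(transcripts)
  tx <- transcripts |> arrange(.data$transcript_id, .data$exon_start)
  introns <- tx |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) |>
    dplyr::reframe(
      intron_start = head(.data$exon_end, -1) + 1L,
      intron_end = tail(.data$exon_start, -1) - 1L
    )
  if (nrow(introns) > 0) {
    introns <- introns |>
      mutate(
        donor_boundary = if_else(.data$strand == "+",
                                 .data$intron_start, .data$intron_end),
        acceptor_boundary = if_else(.data$strand == "+",
                                    .data$intron_end, .data$intron_start),
        length = .data$intron_end - .data$intron_start + 1L
      )
  } else {
    introns <- tibble(gene_id = character(), transcript_id = character(),
                      chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      donor_boundary = integer(),
                      acceptor_boundary = integer(), length = integer())
  }

  long <- bind_rows(
    introns |> mutate(kind = "donor", boundary = .data$donor_boundary),
    introns |> mutate(kind = "acceptor", boundary = .data$acceptor_boundary)
  )

  spans <- tx |>
    group_by(.data$gene_id, .data$transcript_id, .data$chrom) |>
    summarise(tx_start = min(.data$exon_start), tx_end = max(.data$exon_end),
              .groups = "drop")

  sites <- long |>
    group_by(.data$chrom, .data$strand, .data$kind, .data$boundary,
             .data$gene_id) |>
    summarise(n_transcripts = dplyr::n_distinct(.data$transcript_id),
              .groups = "drop")
  if (nrow(sites) > 0) {
    # a site is alternative if any same-gene transcript spanning the
    # boundary does not use it
    spanning <- sites |>
      left_join(spans, by = c("chrom", "gene_id"),
                relationship = "many-to-many") |>
      filter(.data$tx_start <= .data$boundary,
             .data$boundary <= .data$tx_end) |>
      group_by(.data$chrom, .data$strand, .data$kind, .data$boundary,
               .data$gene_id) |>
      summarise(n_spanning = dplyr::n(), .groups = "drop")
    sites <- sites |>
      left_join(spanning,
                by = c("chrom", "strand", "kind", "boundary", "gene_id")) |>
      mutate(n_spanning = dplyr::coalesce(.data$n_spanning, .data$n_transcripts),
             usage = if_else(.data$n_transcripts >= .data$n_spanning,
                             "constitutive", "alternative")) |>
      select(-"n_spanning")
    sites <- sites |>
      group_by(.data$kind) |>
      dplyr::group_modify(function(df, key) {
        w <- window_interval(df$boundary, df$strand, key$kind)
        bind_cols(df, w)
      }) |>
      ungroup() |>
      mutate(site_id = paste(.data$chrom, .data$strand, .data$kind,
                             .data$boundary, sep = ":")) |>
      select("site_id", "chrom", "strand", "kind", "boundary",
             "window_start", "window_end", "usage", "n_transcripts",
             "gene_id") |>
      arrange(.data$chrom, .data$boundary, .data$kind)
  } else {
    sites <- tibble(site_id = character(), chrom = character(),
                    strand = character(), kind = character(),
                    boundary = integer(), window_start = integer(),
                    window_end = integer(), usage = character(),
                    n_transcripts = integer(), gene_id = character())
  }
  list(introns = introns, sites = sites)
}

#' Extract strand-aware scoring windows for splice sites
#'
#' Returns the transcribed-strand window sequence of each site (9 nt for
#' donors spanning relative positions \[-2..-1, +1..+7\]; 27 nt for
#' acceptors spanning \[-24..-1, +1..+3\]; relative coordinates skip 0).
#' Minus-strand windows are reverse-complemented.
#'
#' @param genome A `DNAStringSet` (or named character vector) of contigs.
#' @param sites Site tibble from [derive_introns()] (needs `chrom`,
#'   `strand`, `kind`, `boundary`).
#' @param min_intron Introns shorter than the acceptor window would let
#'   windows overlap the opposite site; sites whose window leaves the
#'   contig raise an error.
#' @return `sites` with a `ref_window` column added.
#' @export
extract_window <- function(genome, sites, min_intron = 27L) {
  w <- sites |>
    group_by(.data$kind) |>
    dplyr::group_modify(function(df, key) {
      iv <- window_interval(df$boundary, df$strand, key$kind)
      seqs <- vapply(seq_len(nrow(df)), function(i) {
        s <- genome_seq(genome, df$chrom[i], iv$window_start[i],
                        iv$window_end[i])
        if (df$strand[i] == "-") revcomp(s) else s
      }, character(1))
      df$window_start <- iv$window_start
      df$window_end <- iv$window_end
      df$ref_window <- seqs
      df
    }) |>
    ungroup()
  w[match(paste(sites$chrom, sites$strand, sites$kind, sites$boundary),
          paste(w$chrom, w$strand, w$kind, w$boundary)), , drop = FALSE]
}

#' Per-position variant diversity profile around splice sites
#'
#' For every relative window position, the fraction of sites that carry at
#' least one variant at that position, mapped strand-awareley into the
#' relative coordinate frame (no position 0).
#'
#' @param sites Site tibble (`chrom`, `strand`, `kind`, `boundary`).
#' @param variants Variant tibble (`chrom`, `pos`, 1-based).
#' @return Tibble with `kind`, `rel_pos`, `n_sites`, `n_hit`, `frac`.
#' @export
site_diversity_profile <- function(sites, variants) {
  out <- lapply(c("donor", "acceptor"), function(kind) {
    ss <- sites |> filter(.data$kind == !!kind)
    rel <- window_rel_positions(kind)
    base <- tibble(kind = kind, rel_pos = rel,
                   n_sites = nrow(ss), n_hit = 0L)
    if (nrow(ss) == 0 || is.null(variants) || nrow(variants) == 0) {
      return(base |> mutate(frac = ifelse(.data$n_sites > 0, 0, NA_real_)))
    }
    hits <- ss |>
      inner_join(variants |> select("chrom", "pos") |> distinct(),
                 by = "chrom", relationship = "many-to-many") |>
      mutate(rel_pos = genomic_to_rel(.data$pos, .data$boundary,
                                      .data$strand, !!kind)) |>
      filter(!is.na(.data$rel_pos)) |>
      distinct(.data$chrom, .data$strand, .data$boundary, .data$rel_pos) |>
      count(.data$rel_pos, name = "n_hit")
    base |>
      select(-"n_hit") |>
      left_join(hits, by = "rel_pos") |>
      mutate(n_hit = dplyr::coalesce(.data$n_hit, 0L),
             frac = .data$n_hit / .data$n_sites)
  })
  bind_rows(out)
}

#' Export splice sites as BED6
#'
#' Writes half-open BED intervals of the scoring windows, named by site id
#' and scored by transcript support.
#'
#' @param sites Site tibble with `chrom`, `window_start`, `window_end`,
#'   `site_id`, `n_transcripts`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble(chrom = sites$chrom,
                start = sites$window_start - 1L,
                end = sites$window_end,
                name = sites$site_id,
                score = sites$n_transcripts %||% 0L,
                strand = sites$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
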
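# Putative novel introns (PNIs) from split-read junction evidence.

#' Rescue putative novel introns from split-read junctions
#'
#' Filters split mappings (properly paired, mapping quality, edit
#' distance, insert size), removes junctions identical to annotated
#' introns, and groups the rest into PNIs with read / individual /
#' population support.  Each junction side is flagged novel when its
#' boundary is not an annotated splice site of the matching kind; a PNI is
#' kept when every novel side (or, for doubly novel junctions, at least
#' one side) lies within `proximity` nt of an annotated exon boundary.
#'
#' @param split_mappings Tibble: `read_id`, `sample_id`, `population_id`,
#'   `chrom`, `strand`, `donor_boundary`, `acceptor_boundary`, `mapq`,
#'   `edit_distance`, `properly_paired`, `insert_size`.
#' @param annotation List from [derive_introns()] (`introns` and `sites`).
#' @param min_mapq Minimum mapping quality (default 150; scale is
#'   mapper-dependent).
#' @param max_edit_distance Maximum edit distance (default 6).
#' @param max_insert_size Maximum insert size in nt (default 1e6).
#' @param proximity Maximum distance of a novel side to an annotated exon
#'   boundary (default 30 nt).
#' @param transcripts Optional exon table; when given, the annotated exon
#'   boundary set used for the proximity rule includes transcript start
#'   and end exons (otherwise only internal boundaries derived from
#'   introns are available).
#' @param genome Optional contigs; when given, junction dinucleotides are
#'   checked and non-GT/AG PNIs flagged (`canonical` column).
#' @return Tibble of PNIs: junction coordinates, `donor_novel`,
#'   `acceptor_novel`, `donor_nearest`, `acceptor_nearest` (distance to
#'   the nearest annotated exon boundary), `n_reads`, `n_individuals`,
#'   `n_populations`, `length`, and `canonical` when a genome is supplied.
#' @export
rescue_pni <- function(split_mappings, annotation, min_mapq = 150,
                       max_edit_distance = 6, max_insert_size = 1e6,
                       proximity = 30, transcripts = NULL, genome = NULL) {
  if (any(split_mappings$donor_boundary >= split_mappings$acceptor_boundary &
            split_mappings$strand == "+") ||
      any(split_mappings$acceptor_boundary >= split_mappings$donor_boundary &
            split_mappings$strand == "-")) {
    abort("malformed junction: donor must precede acceptor along the transcript")
  }
  sm <- split_mappings |>
    filter(.data$properly_paired, .data$mapq >= min_mapq,
           .data$edit_distance <= max_edit_distance,
           .data$insert_size <= max_insert_size)

  ann_introns <- annotation$introns |>
    distinct(.data$chrom, .data$strand, .data$donor_boundary,
             .data$acceptor_boundary)
  sm <- sm |>
    anti_join(ann_introns,
              by = c("chrom", "strand", "donor_boundary",
                     "acceptor_boundary"))
  if (nrow(sm) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  donor_boundary = integer(), acceptor_boundary = integer(),
                  donor_novel = logical(), acceptor_novel = logical(),
                  donor_nearest = integer(), acceptor_nearest = integer(),
                  n_reads = integer(), n_individuals = integer(),
                  n_populations = integer(), length = integer()))
  }

  pni <- sm |>
    group_by(.data$chrom, .data$strand, .data$donor_boundary,
             .data$acceptor_boundary) |>
    summarise(n_reads = dplyr::n(),
              n_individuals = dplyr::n_distinct(.data$sample_id),
              n_populations = dplyr::n_distinct(.data$population_id),
              .groups = "drop") |>
    mutate(length = abs(.data$acceptor_boundary - .data$donor_boundary) + 1L)

  sites <- annotation$sites
  don_set <- sites |> filter(.data$kind == "donor")
  acc_set <- sites |> filter(.data$kind == "acceptor")
  key <- function(chrom, strand, boundary) paste(chrom, strand, boundary)
  pni <- pni |>
    mutate(
      donor_novel = !key(.data$chrom, .data$strand, .data$donor_boundary) %in%
        key(don_set$chrom, don_set$strand, don_set$boundary),
      acceptor_novel = !key(.data$chrom, .data$strand,
                            .data$acceptor_boundary) %in%
        key(acc_set$chrom, acc_set$strand, acc_set$boundary)
    )

  # nearest annotated exon boundary (exon table when given, else the exon
  # edges implied by annotated introns)
  bounds <- if (!is.null(transcripts)) {
    transcripts |>
      dplyr::reframe(chrom = rep(.data$chrom, 2),
                     b = c(.data$exon_start, .data$exon_end))
  } else {
    annotation$introns |>
      dplyr::reframe(chrom = rep(.data$chrom, 2),
                     b = c(.data$intron_start - 1L, .data$intron_end + 1L))
  }
  nearest <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      b <- bounds$b[bounds$chrom == chrom[i]]
      if (length(b) == 0) NA_integer_ else as.integer(min(abs(b - pos[i])))
    }, integer(1))
  }
  pni <- pni |>
    mutate(donor_nearest = nearest(.data$chrom, .data$donor_boundary),
           acceptor_nearest = nearest(.data$chrom, .data$acceptor_boundary))

  near_ok <- function(novel, nearest) !novel | (!is.na(nearest) &
                                                  nearest <= proximity)
  both_novel <- pni$donor_novel & pni$acceptor_novel
  keep <- ifelse(
    both_novel,
    near_ok(TRUE, pni$donor_nearest) | near_ok(TRUE, pni$acceptor_nearest),
    near_ok(pni$donor_novel, pni$donor_nearest) &
      near_ok(pni$acceptor_novel, pni$acceptor_nearest)
  )
  pni <- pni |> filter(keep)

  if (!is.null(genome) && nrow(pni) > 0) {
    din <- vapply(seq_len(nrow(pni)), function(i) {
      d <- genome_seq(genome, pni$chrom[i],
                      min(pni$donor_boundary[i], pni$donor_boundary[i] +
                            ifelse(pni$strand[i] == "+", 1L, -1L)),
                      max(pni$donor_boundary[i], pni$donor_boundary[i] +
                            ifelse(pni$strand[i] == "+", 1L, -1L)))
      a <- genome_seq(genome, pni$chrom[i],
                      min(pni$acceptor_boundary[i], pni$acceptor_boundary[i] +
                            ifelse(pni$strand[i] == "+", -1L, 1L)),
                      max(pni$acceptor_boundary[i], pni$acceptor_boundary[i] +
                            ifelse(pni$strand[i] == "+", -1L, 1L)))
      if (pni$strand[i] == "-") { d <- revcomp(d); a <- revcomp(a) }
      paste0(d, "..", a)
    }, character(1))
    pni$dinucleotides <- din
    pni$canonical <- din == "GT..AG"
  }
  pni
}

#' Classify the alternative-splicing event implied by a PNI
#'
#' A PNI is `internal` when its junction lies fully inside the genomic
#' span of an annotated transcript of the same chromosome and strand;
#' junctions extending beyond (or lying wholly just outside) the nearest
#' transcript's extremities within `flank` nt are `extension` events,
#' sub-labelled `upstream_of_tss` / `downstream_of_cleavage` by transcript
#' orientation.  PNIs farther than `flank` from every transcript are
#' `intergenic` (excluded from event tabulations).  The site-novelty
#' pattern is one of `novel-combination` (no novel site),
#' `one-novel-donor`, `one-novel-acceptor`, `two-novel`.
#'
#' @param pnis PNI tibble from [rescue_pni()].
#' @param transcripts Exon table (as for [derive_introns()]).
#' @param flank Maximum distance (nt) from a transcript span for a
#'   junction to count as an extension of that transcript (default 1000).
#' @return `pnis` with `category`, `subcategory` and `pattern` columns.
#' @export
classify_pni_event <- function(pnis, transcripts, flank = 1000) {
  spans <- transcripts |>
    group_by(.data$chrom, .data$strand, .data$transcript_id) |>
    summarise(tx_start = min(.data$exon_start), tx_end = max(.data$exon_end),
              .groups = "drop")
  res <- lapply(seq_len(nrow(pnis)), function(i) {
    lo <- min(pnis$donor_boundary[i], pnis$acceptor_boundary[i])
    hi <- max(pnis$donor_boundary[i], pnis$acceptor_boundary[i])
    sp <- spans |> filter(.data$chrom == pnis$chrom[i],
                          .data$strand == pnis$strand[i])
    if (nrow(sp) == 0) {
      return(tibble(category = "intergenic", subcategory = NA_character_))
    }
    inside <- any(sp$tx_start <= lo & hi <= sp$tx_end)
    if (inside) {
      return(tibble(category = "internal", subcategory = NA_character_))
    }
    gap <- pmax(sp$tx_start - hi, lo - sp$tx_end, 0)
    j <- which.min(gap)
    if (gap[j] > flank) {
      return(tibble(category = "intergenic", subcategory = NA_character_))
    }
    # beyond an extremity of the nearest transcript: orient by strand
    before_start <- lo < sp$tx_start[j]
    upstream <- if (pnis$strand[i] == "+") before_start else !before_start
    tibble(category = "extension",
           subcategory = if (upstream) "upstream_of_tss" else
             "downstream_of_cleavage")
  })
  pattern <- dplyr::case_when(
    pnis$donor_novel & pnis$acceptor_novel ~ "two-novel",
    pnis$donor_novel ~ "one-novel-donor",
    pnis$acceptor_novel ~ "one-novel-acceptor",
    TRUE ~ "novel-combination"
  )
  bind_cols(pnis, bind_rows(res)) |> mutate(pattern = pattern)
}

#' Tabulate PNI support levels
#'
#' Counts of PNIs at the standard support levels: seen in all populations,
#' and supported by more than each individual threshold.  Counts are
#' monotone non-increasing with the threshold.
#'
#' @param pnis PNI tibble (`n_individuals`, `n_populations`).
#' @param individual_thresholds Strict lower bounds on supporting
#'   individuals (default `c(150, 300, 450)`).
#' @param n_populations_total Number of populations in the study; default
#'   the maximum label count observed.
#' @return Tibble with `level` and `n_pnis`.
#' @export
support_summary <- function(pnis, individual_thresholds = c(150, 300, 450),
                            n_populations_total = NULL) {
  if (is.null(n_populations_total)) {
    n_populations_total <- if (nrow(pnis) > 0) max(pnis$n_populations) else 0L
  }
  lv <- c("all", ">0 in all populations",
          sprintf(">%d individuals", individual_thresholds))
  n <- c(nrow(pnis),
         sum(pnis$n_populations >= n_populations_total & nrow(pnis) > 0),
         vapply(individual_thresholds,
                function(t) sum(pnis$n_individuals > t), numeric(1)))
  tibble(level = lv, n_pnis = as.integer(n))
}

#' Cross-dataset confirmation of PNIs
#'
#' Exact junction-coordinate match (chrom, strand, both boundaries).
#'
#' @param set_a,set_b PNI tibbles.
#' @return `set_a` with a `confirmed` column; confirmation fraction in
#'   attribute `"fraction"`.
#' @export
confirm_pni <- function(set_a, set_b) {
  k <- function(x) paste(x$chrom, x$strand, x$donor_boundary,
                         x$acceptor_boundary)
  out <- set_a |> mutate(confirmed = k(set_a) %in% k(set_b))
  attr(out, "fraction") <- if (nrow(out) > 0) mean(out$confirmed) else 0
  out
}
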
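# ADAR-consistent A-to-G editing candidates from RNA-side variant calls.

#' Filter RNA-side variant calls to A-to-G editing candidates
#'
#' Keeps RNA-seq variant calls that are consistent with ADAR A-to-I
#' editing: not present among genomic (genotype) variants, reading A>G on
#' the transcribed strand (plus-strand A>G or minus-strand T>C), and
#' passing the three evidence thresholds - median coverage across samples
#' carrying the site, number of samples showing the non-reference base, and
#' call quality.  The boundary semantics are strict on the low side:
#' median coverage 10, 10 supporting samples and quality 100 all pass.
#'
#' @param rna_variants Tibble of RNA-side calls: `chrom`, `pos`, `ref`,
#'   `alt`, `qual`, `median_coverage`, `n_alt_samples`, optionally
#'   `ref_count` / `alt_count` pooled depths (see [read_rna_variants_vcf()]).
#' @param genomic_variants Tibble of genomic variants (`chrom`, `pos`);
#'   matching positions are removed as genotype polymorphisms, not editing.
#' @param genes Tibble assigning strands: `chrom`, `start`, `end`,
#'   `strand`.  Calls in no gene, or in genes of both strands, are dropped
#'   with a warning.
#' @param min_median_coverage,min_alt_samples,min_qual The three evidence
#'   thresholds (defaults 10, 10, 100).
#' @param sites Optional site tibble; when given, candidates are annotated
#'   with the id of the splice-site window they overlap (`site_id`, `NA`
#'   otherwise).
#' @return Tibble of candidates with `gene_strand`, `efficiency` (when
#'   depth columns are present) and `exhaustive` (efficiency > 0.9).
#' @export
filter_editing_candidates <- function(rna_variants, genomic_variants, genes,
                                      min_median_coverage = 10,
                                      min_alt_samples = 10, min_qual = 100,
                                      sites = NULL) {
  v <- rna_variants |>
    anti_join(genomic_variants |> select("chrom", "pos") |> distinct(),
              by = c("chrom", "pos"))

  # strand assignment by containing gene
  g <- genes |> select("chrom", "start", "end", "strand")
  v <- v |>
    left_join(g, by = "chrom", relationship = "many-to-many") |>
    mutate(in_gene = !is.na(.data$start) & .data$pos >= .data$start &
             .data$pos <= .data$end) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(across(dplyr::any_of(c("qual", "median_coverage",
                                     "n_alt_samples", "ref_count",
                                     "alt_count")), dplyr::first),
              strands = list(unique(.data$strand[.data$in_gene])),
              .groups = "drop")
  n_strand <- lengths(v$strands)
  if (any(n_strand == 0)) {
    warn(sprintf("%d call(s) outside any gene dropped", sum(n_strand == 0)))
  }
  if (any(n_strand > 1)) {
    warn(sprintf("%d call(s) in overlapping antisense genes dropped",
                 sum(n_strand > 1)))
  }
  v <- v |> filter(n_strand == 1) |>
    mutate(gene_strand = map_chr(.data$strands, 1)) |>
    select(-"strands")

  v <- v |>
    filter((.data$gene_strand == "+" & .data$ref == "A" & .data$alt == "G") |
             (.data$gene_strand == "-" & .data$ref == "T" & .data$alt == "C")) |>
    filter(.data$median_coverage >= min_median_coverage,
           .data$n_alt_samples >= min_alt_samples,
           .data$qual >= min_qual)

  if (all(c("ref_count", "alt_count") %in% names(v)) && nrow(v) > 0) {
    eff <- editing_efficiency(v$ref_count, v$alt_count)
    v$efficiency <- eff$efficiency
    v$exhaustive <- eff$exhaustive
  }
  if (!is.null(sites) && nrow(v) > 0) {
    hit <- sites |>
      inner_join(v |> select("chrom", "pos") |> distinct(), by = "chrom",
                 relationship = "many-to-many") |>
      filter(.data$pos >= .data$window_start,
             .data$pos <= .data$window_end) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      select("chrom", "pos", "site_id")
    v <- v |> left_join(hit, by = c("chrom", "pos"))
  }
  v
}

#' Editing efficiency from pooled base counts
#'
#' Fraction of non-reference bases observed at an edited position;
#' positions with efficiency strictly above 0.9 are flagged as
#' exhaustively edited.
#'
#' @param ref_count,alt_count Non-negative pooled read counts; the total
#'   must be positive.
#' @return Tibble with `efficiency` and `exhaustive`.
#' @export
#' @examples
#' editing_efficiency(1, 9)  # 0.9, not exhaustive (strict inequality)
editing_efficiency <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0)) {
    abort("counts must be non-negative")
  }
  total <- ref_count + alt_count
  if (any(total == 0)) abort("zero total coverage")
  eff <- alt_count / total
  tibble(efficiency = eff, exhaustive = eff > 0.9)
}

#' Intron retention vs editing completeness
#'
#' Compares normalized intron read coverage between introns flanked by
#' exhaustively edited disrupted sites and those with partial editing
#' (two-group Mann-Whitney/Wilcoxon rank-sum test).  A positive direction
#' means the exhaustive group shows higher intron coverage, i.e. more
#' retained introns.
#'
#' @param coverage Numeric vector of per-intron normalized read coverage.
#' @param exhaustive Logical vector (same length) splitting the introns.
#' @return Tibble with group sizes, medians, `p_value` and `direction`
#'   (`"exhaustive_higher"`, `"partial_higher"` or `"none"`).
#' @export
intron_retention_association <- function(coverage, exhaustive) {
  stopifnot(length(coverage) == length(exhaustive))
  x <- coverage[exhaustive]; y <- coverage[!exhaustive]
  if (length(x) < 2 || length(y) < 2) {
    abort("each group needs >= 2 introns")
  }
  wt <- suppressWarnings(wilcox.test(x, y))
  mx <- median(x); my <- median(y)
  tibble(n_exhaustive = length(x), n_partial = length(y),
         median_exhaustive = mx, median_partial = my,
         p_value = wt$p.value,
         direction = if (mx > my) "exhaustive_higher" else
           if (mx < my) "partial_higher" else "none")
}
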
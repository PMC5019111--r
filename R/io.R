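# Readers and writers for the standard formats the pipeline consumes and
# emits.  All fixture writers are deterministic (no timestamps).

#' Read variants from a VCF file
#'
#' Parses a VCF into the flat variant tibble used throughout the package.
#' Multi-allelic records are split into one row per ALT allele.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param daf_tag INFO tag carrying the derived allele frequency
#'   (default `"DAF"`; set `NULL` to skip).
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `qual`, `type` and
#'   (when present) `daf`.
#' @export
read_variants_vcf <- function(path, daf_tag = "DAF") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("vcfR is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT,
                qual = suppressWarnings(as.numeric(fix$QUAL)),
                info = fix$INFO)
  out <- out |>
    mutate(alt = str_split(.data$alt, ",")) |>
    unnest("alt")
  if (!is.null(daf_tag)) {
    pat <- paste0("(?:^|;)", daf_tag, "=([^;]+)")
    m <- regmatches(out$info, regexec(pat, out$info))
    out$daf <- suppressWarnings(as.numeric(vapply(
      m, function(x) if (length(x) == 2) x[2] else NA_character_,
      character(1))))
  }
  out |>
    mutate(type = variant_type(.data$ref, .data$alt)) |>
    select(-"info")
}

#' Read RNA-side variant calls with per-sample depths from a VCF
#'
#' Extracts, per call, the call quality, the median coverage across
#' samples carrying the site, the number of samples showing the
#' non-reference base, and pooled ref/alt depths - the evidence fields
#' used by [filter_editing_candidates()].  Depth fields default to the
#' conventional `AD` (allelic depths) and `DP` tags; tag names are
#' configurable.
#'
#' @param path VCF path.
#' @param ad_tag,dp_tag FORMAT tag names for allelic depths and total
#'   depth.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `median_coverage`, `n_alt_samples`, `ref_count`, `alt_count`.
#' @export
read_rna_variants_vcf <- function(path, ad_tag = "AD", dp_tag = "DP") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("vcfR is required to read VCF files")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = ad_tag)
  dp <- suppressWarnings(
    apply(vcfR::extract.gt(v, element = dp_tag), 2, as.numeric))
  dp <- matrix(dp, nrow = nrow(fix))
  split_ad <- function(x, which) {
    suppressWarnings(as.numeric(vapply(strsplit(x %||% "", ","), function(p) {
      if (length(p) >= which) p[which] else NA_character_
    }, character(1))))
  }
  ref_mat <- apply(ad, 2, split_ad, which = 1)
  alt_mat <- apply(ad, 2, split_ad, which = 2)
  ref_mat <- matrix(ref_mat, nrow = nrow(fix))
  alt_mat <- matrix(alt_mat, nrow = nrow(fix))
  tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    median_coverage = apply(dp, 1, function(x) {
      x <- x[!is.na(x) & x > 0]
      if (length(x) == 0) 0 else median(x)
    }),
    n_alt_samples = rowSums(alt_mat > 0, na.rm = TRUE),
    ref_count = rowSums(ref_mat, na.rm = TRUE),
    alt_count = rowSums(alt_mat, na.rm = TRUE)
  )
}

#' Write a genome as FASTA
#'
#' @param genome `DNAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(unlist(genome))
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write transcript models as a Gencode-dialect GTF
#'
#' @param transcripts Exon table (`gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `exon_start`, `exon_end`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_gtf <- function(transcripts, path) {
  tx <- transcripts |> arrange(.data$transcript_id, .data$exon_start)
  lines <- sprintf(
    '%s\tsplicevar\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tx$chrom, tx$exon_start, tx$exon_end, tx$strand, tx$gene_id,
    tx$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Write a variant tibble as a minimal VCF
#'
#' Emits a site-only VCFv4.2 with DAF (and, for fixtures, the planted
#' truth class) in INFO.
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`, optional
#'   `daf`, `true_class`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  info <- rep(".", nrow(variants))
  parts <- list()
  if ("daf" %in% names(variants)) {
    parts$daf <- sprintf("DAF=%.6g", variants$daf)
  }
  if ("true_class" %in% names(variants)) {
    parts$cls <- sprintf("TRUECLASS=%s", variants$true_class)
  }
  if (length(parts) > 0) {
    info <- do.call(paste, c(parts, sep = ";"))
  }
  qual <- if ("qual" %in% names(variants)) variants$qual else "."
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=DAF,Number=1,Type=Float,Description="Derived allele frequency">',
           '##INFO=<ID=TRUECLASS,Number=1,Type=String,Description="Planted effect class">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s", variants$chrom,
                  variants$pos, variants$ref, variants$alt,
                  as.character(qual), info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+",
                           strrep("I", nchar(reads$seq))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a split-read junction table
#'
#' The documented TSV alternative to BAM input for junction evidence:
#' columns `read_id`, `sample_id`, `population_id`, `chrom`, `strand`,
#' `donor_boundary`, `acceptor_boundary`, `mapq`, `edit_distance`,
#' `properly_paired`, `insert_size`.
#'
#' @param path TSV path.
#' @return Tibble of split mappings.
#' @export
read_junctions_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname read_junctions_tsv
#' @param junctions Junction tibble.
#' @export
write_junctions_tsv <- function(junctions, path) {
  readr::write_tsv(junctions, path)
  invisible(path)
}

#' Write cleavage sites as BED6
#'
#' @param pcs Cleavage-site tibble (`chrom`, `strand`, `position`,
#'   `read_support`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pcs_bed <- function(pcs, path) {
  bed <- tibble(chrom = pcs$chrom, start = pcs$position - 1L,
                end = pcs$position,
                name = paste0("PCS_", seq_len(nrow(pcs))),
                score = pcs$read_support, strand = pcs$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
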
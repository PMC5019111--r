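# Poly-A rescue: tailed-read selection, tail trimming, informative-read
# filtering, cleavage-site calling, hexamer signal scanning and
# motif-variant classification.

#' Select candidate poly-A reads
#'
#' Keeps unmapped reads that end in `AAAA` (A-tail) or begin with `TTTT`
#' (T-head: minus-strand evidence, the reverse-complement of a tail).
#'
#' @param reads Tibble with `read_id` and `seq` columns.
#' @return Input rows that pass, with a `tail_side` column (`"A3"` or
#'   `"T5"`; reads matching both are kept once as `"A3"`).
#' @export
select_polya_reads <- function(reads) {
  a3 <- str_detect(reads$seq, "AAAA$")
  t5 <- str_detect(reads$seq, "^TTTT")
  reads |>
    filter(a3 | t5) |>
    mutate(tail_side = if_else(a3[a3 | t5], "A3", "T5"))
}

trim_one <- function(seq, side, max_mismatches, min_tail) {
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  if (side == "A3") {
    idx <- rev(seq_len(n)); target <- "A"
  } else {
    idx <- seq_len(n); target <- "T"
  }
  mism <- 0L
  run_len <- 0L          # length of trimmable run (ends at last matching base)
  i <- 0L
  for (k in seq_along(idx)) {
    b <- bases[idx[k]]
    if (b == target) {
      run_len <- k
    } else {
      mism <- mism + 1L
      if (mism > max_mismatches) break
    }
  }
  if (run_len < min_tail) {
    return(list(trimmed = seq, tail_length = 0L))
  }
  if (side == "A3") {
    list(trimmed = substr(seq, 1L, n - run_len), tail_length = run_len)
  } else {
    list(trimmed = substr(seq, run_len + 1L, n), tail_length = run_len)
  }
}

#' Trim a poly-A tail (or poly-T head)
#'
#' Removes the longest terminal run of A (3' side) or leading run of T
#' (5' side) that contains at most `max_mismatches` interrupting bases;
#' the innermost trimmed base is always a matching base, so a mismatch is
#' never terminal on the read-internal side.  Runs shorter than `min_tail`
#' are left untouched.
#'
#' @param reads Tibble with `seq` and `tail_side` (from
#'   [select_polya_reads()]).
#' @param max_mismatches Maximum non-matching bases inside the trimmed run
#'   (default 1).
#' @param min_tail Minimum run length to trim (default 5).
#' @return Input with `trimmed_seq` and `tail_length` columns added
#'   (`tail_length` 0 when nothing was trimmed).
#' @export
trim_tail <- function(reads, max_mismatches = 1, min_tail = 5) {
  res <- map2(reads$seq, reads$tail_side, trim_one,
              max_mismatches = max_mismatches, min_tail = min_tail)
  reads |>
    mutate(trimmed_seq = map_chr(res, "trimmed"),
           tail_length = map_int(res, function(x) as.integer(x$tail_length)))
}

#' Filter trimmed reads for informativeness
#'
#' A trimmed read is kept when it is longer than `min_length` nucleotides
#' (strict) and its combined A+T content is below `max_at` (reads at or
#' above the bound are low-complexity and dropped).
#'
#' @param reads Tibble with a `trimmed_seq` column.
#' @param min_length Minimum informative length (default 25; kept iff
#'   length > 25).
#' @param max_at Maximum A+T fraction (default 0.8; kept iff A+T < 0.8).
#' @return Input with `keep` (logical) and `drop_reason` (`NA`,
#'   `"too_short"` or `"low_complexity"`).
#' @export
filter_informative <- function(reads, min_length = 25, max_at = 0.8) {
  len <- nchar(reads$trimmed_seq)
  nA <- str_length(reads$trimmed_seq) -
    str_length(gsub("A", "", reads$trimmed_seq))
  nT <- str_length(reads$trimmed_seq) -
    str_length(gsub("T", "", reads$trimmed_seq))
  at <- ifelse(len > 0, (nA + nT) / len, 1)
  too_short <- len <= min_length
  low_cx <- !too_short & at >= max_at
  reads |>
    mutate(keep = !too_short & !low_cx,
           drop_reason = dplyr::case_when(too_short ~ "too_short",
                                          low_cx ~ "low_complexity",
                                          TRUE ~ NA_character_))
}

#' Call putative cleavage sites from anchored alignments
#'
#' Each uniquely anchored, trimmed read pinpoints the last templated base
#' before the removed tail: for A-tail evidence on the plus strand this is
#' the 3' end of the alignment; T-head reads represent minus-strand
#' cleavage (their evidence is the reverse complement of a tail), so the
#' symmetric coordinate is used.  Identical (chrom, strand, position)
#' collapse with summed read support; sites with support >= 2 form the
#' conservative subset.
#'
#' @param alignments Tibble of unique alignments: `read_id`, `chrom`,
#'   `strand` (cleavage strand), `start`, `end` (1-based alignment span of
#'   the templated part), optionally `unique` (logical).
#' @param merge_radius Collapse radius in nt (default 0: exact-position
#'   keying).
#' @param strict Error on alignments flagged non-unique (default TRUE).
#' @return Tibble of cleavage sites: `chrom`, `strand`, `position`,
#'   `read_support`, `conservative`.
#' @export
call_pcs <- function(alignments, merge_radius = 0, strict = TRUE) {
  if ("unique" %in% names(alignments)) {
    if (strict && any(!alignments$unique)) {
      abort("non-unique alignment passed in strict mode")
    }
    alignments <- alignments |> filter(.data$unique)
  }
  pcs <- alignments |>
    mutate(position = if_else(.data$strand == "+", .data$end, .data$start)) |>
    count(.data$chrom, .data$strand, .data$position, name = "read_support") |>
    arrange(.data$chrom, .data$strand, .data$position)
  if (merge_radius > 0 && nrow(pcs) > 1) {
    pcs <- pcs |>
      group_by(.data$chrom, .data$strand) |>
      mutate(cluster = cumsum(c(TRUE, diff(.data$position) > merge_radius))) |>
      group_by(.data$chrom, .data$strand, .data$cluster) |>
      summarise(position = .data$position[which.max(.data$read_support)],
                read_support = sum(.data$read_support), .groups = "drop") |>
      select(-dplyr::any_of("cluster"))
  }
  pcs |> mutate(conservative = .data$read_support >= 2)
}

#' Cross-dataset confirmation of cleavage sites
#'
#' A site in `set_a` is confirmed when any `set_b` site lies within
#' `+/-window` nt on the same chromosome (and same strand unless
#' `ignore_strand`).
#'
#' @param set_a,set_b Cleavage-site tibbles (`chrom`, `strand`,
#'   `position`).
#' @param window Maximum distance in nt (default 50; distance exactly
#'   `window` confirms).
#' @param ignore_strand Match across strands (default FALSE).
#' @return `set_a` with a `confirmed` column; the confirmation fraction is
#'   in attribute `"fraction"` and printed by `summary()`-style use.
#' @export
confirm_pcs <- function(set_a, set_b, window = 50, ignore_strand = FALSE) {
  conf <- vapply(seq_len(nrow(set_a)), function(i) {
    b <- set_b[set_b$chrom == set_a$chrom[i], , drop = FALSE]
    if (!ignore_strand) b <- b[b$strand == set_a$strand[i], , drop = FALSE]
    any(abs(b$position - set_a$position[i]) <= window)
  }, logical(1))
  out <- set_a |> mutate(confirmed = conf)
  attr(out, "fraction") <- if (nrow(out) > 0) mean(conf) else 0
  out
}

#' Scan for a ranked poly-A hexamer around a cleavage site
#'
#' Top-down scan of the 13 CPSF hexamers in rank order over the
#' transcribed-strand sequence around a PCS: the first (most frequent)
#' hexamer present is reported, and among its occurrences the one closest
#' to the PCS (ties favour the upstream occurrence).
#'
#' @param window_seq Transcribed-strand sequence centred on the PCS
#'   (default geometry: `+/-scan_window` nt, so `2*scan_window + 1` bases
#'   with the PCS at position `scan_window + 1`).
#' @param pcs_offset 1-based position of the PCS base inside `window_seq`
#'   (default centre).
#' @param upstream_only Scan only the upstream half (default FALSE:
#'   scan around the site).
#' @return One-row tibble (`hexamer`, `rank`, `offset`, `distance`) or a
#'   zero-row tibble when no listed hexamer occurs.  `offset` is the
#'   signed position of the hexamer start relative to the PCS (negative =
#'   upstream); `distance` its absolute value.
#' @export
scan_polya_motif <- function(window_seq, pcs_offset = NULL,
                             upstream_only = FALSE) {
  window_seq <- toupper(window_seq)
  n <- nchar(window_seq)
  if (is.null(pcs_offset)) pcs_offset <- (n + 1L) %/% 2L
  empty <- tibble(hexamer = character(), rank = integer(),
                  offset = integer(), distance = integer())
  for (r in seq_along(POLYA_HEXAMERS)) {
    hex <- POLYA_HEXAMERS[r]
    locs <- str_locate_all(window_seq, stringr::fixed(hex))[[1]]
    if (nrow(locs) == 0) next
    starts <- locs[, 1]
    offs <- as.integer(starts - pcs_offset)
    if (upstream_only) {
      keep <- offs < 0
      if (!any(keep)) next
      offs <- offs[keep]
    }
    d <- abs(offs)
    # closest occurrence; upstream (negative offset) wins ties
    best <- order(d, offs)[1]
    return(tibble(hexamer = hex, rank = r, offset = offs[best],
                  distance = d[best]))
  }
  empty
}

#' Classify a variant inside a poly-A motif
#'
#' Membership test of the variant hexamer against the 13-motif list:
#' both listed and different is `altered` (the variant reproduces a known
#' poly-A signal), reference listed but variant not is `degraded` (the
#' variant sequence is unknown to function as a poly-A signal), identical
#' hexamers are `unchanged`.
#'
#' @param ref_hexamer,var_hexamer Six-base sequences; `ref_hexamer` must
#'   be in the motif list.
#' @return Tibble with `ref_hexamer`, `var_hexamer`, `status`.
#' @export
classify_motif_variant <- function(ref_hexamer, var_hexamer) {
  ref_hexamer <- toupper(ref_hexamer); var_hexamer <- toupper(var_hexamer)
  if (!all(ref_hexamer %in% POLYA_HEXAMERS)) {
    abort("ref_hexamer must be one of the 13 listed poly-A hexamers")
  }
  status <- dplyr::case_when(
    ref_hexamer == var_hexamer ~ "unchanged",
    var_hexamer %in% POLYA_HEXAMERS ~ "altered",
    TRUE ~ "degraded"
  )
  tibble(ref_hexamer = ref_hexamer, var_hexamer = var_hexamer,
         status = status)
}

#' Compare motif-to-PCS distances between altered and degraded motifs
#'
#' Two-group Mann-Whitney/Wilcoxon rank-sum test on the distances between
#' the poly-A motif and its cleavage site.
#'
#' @param altered_distances,degraded_distances Numeric distance vectors.
#' @return Tibble with group sizes, medians, `p_value` and `direction`.
#' @export
motif_distance_comparison <- function(altered_distances,
                                      degraded_distances) {
  if (length(altered_distances) < 1 || length(degraded_distances) < 1) {
    abort("both groups must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(altered_distances, degraded_distances))
  ma <- median(altered_distances); md <- median(degraded_distances)
  tibble(n_altered = length(altered_distances),
         n_degraded = length(degraded_distances),
         median_altered = ma, median_degraded = md,
         p_value = wt$p.value,
         direction = if (md > ma) "degraded_farther" else
           if (md < ma) "altered_farther" else "none")
}
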
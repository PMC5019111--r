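# Deterministic synthetic fixtures with planted ground truth: genome,
# annotation, variants, split reads, poly-A reads and editing evidence.
# Every generator takes an explicit seed (via the spec); identical specs
# give identical output.

#' True generating probabilities of the synthetic site models
#'
#' Position-specific base probabilities used to sample splice-site windows
#' for the synthetic genome.  The canonical dinucleotides (donor GT at
#' +1,+2; acceptor AG at -2,-1) are deterministic; the remaining positions
#' mix a major base, a secondary base and two minor bases so that
#' single-base substitutions with large, small or negligible log-odds
#' effects all exist.  Acceptor positions -24..-5 emulate the
#' polypyrimidine tract.
#'
#' @param site_kind `"donor"` or `"acceptor"`.
#' @return A 4 x window-length probability matrix (rows A, C, G, T).
#' @export
site_truth_probs <- function(site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  p <- function(A, C, G, T) c(A = A, C = C, G = G, T = T)
  cols <- if (site_kind == "donor") {
    list(
      p(.62, .08, .26, .04),   # -2
      p(.26, .08, .62, .04),   # -1
      p(0, 0, 1, 0),           # +1 G
      p(0, 0, 0, 1),           # +2 T
      p(.62, .08, .26, .04),   # +3
      p(.40, .12, .38, .10),   # +4
      p(.26, .04, .62, .08),   # +5
      p(.38, .10, .12, .40),   # +6
      p(.30, .22, .28, .20)    # +7
    )
  } else {
    tract <- p(.09, .40, .05, .46)
    c(rep(list(tract), 20),                    # -24..-5
      list(p(.12, .40, .08, .40),              # -4
           p(.08, .62, .04, .26),              # -3
           p(1, 0, 0, 0),                      # -2 A
           p(0, 0, 1, 0),                      # -1 G
           p(.25, .12, .45, .18),              # +1
           p(.22, .25, .18, .35),              # +2
           p(.30, .26, .24, .20)))             # +3
  }
  m <- do.call(cbind, cols)
  rownames(m) <- DNA_BASES
  colnames(m) <- as.character(window_rel_positions(site_kind))
  m
}

sample_windows <- function(probs, n) {
  L <- ncol(probs)
  cols <- lapply(seq_len(L), function(i) {
    sample(DNA_BASES, n, replace = TRUE, prob = probs[, i])
  })
  do.call(paste0, cols)
}

random_dna <- function(n, probs = c(A = .28, C = .22, G = .22, T = .28)) {
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

#' Fixture specification
#'
#' Bundles all knobs of the synthetic-data generators.  Identical specs
#' produce identical fixtures.
#'
#' @param seed Integer seed driving every random choice.
#' @param n_genes Number of genes (strands alternate).
#' @param exons_per_gene Exons per gene.
#' @param exon_length,intron_length Length ranges (min, max).
#' @param intergenic Intergenic gap length between genes.
#' @param alt_fraction Fraction of genes with a second, exon-skipping
#'   transcript (creates alternative splice sites).
#' @param n_train Training windows sampled per site kind (default 4000:
#'   large enough that the order-2 functional sequence space of the true
#'   models is essentially fully covered, emulating a genome-wide site
#'   catalogue).
#' @param n_per_class Named vector of planted variant counts per effect
#'   class.
#' @param n_pcs,pcs_read_support Planted cleavage sites and the support
#'   levels cycled over them.
#' @param n_novel_internal,n_novel_two,n_novel_combination,n_novel_extension
#'   Planted novel-junction counts by design.
#' @param n_samples,n_populations Individuals and population labels for
#'   read-level fixtures.
#' @param n_edit_exhaustive,n_edit_partial Planted editing sites by
#'   completeness.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_genes = 60, exons_per_gene = 4,
                         exon_length = c(90, 140),
                         intron_length = c(90, 160), intergenic = 150,
                         alt_fraction = 0.5, n_train = 4000,
                         n_per_class = c(disrupting = 40, weakening = 40,
                                         neutral = 60, enhancing = 30,
                                         activating = 20),
                         n_pcs = 20, pcs_read_support = c(1, 2, 3, 4),
                         n_novel_internal = 12, n_novel_two = 6,
                         n_novel_combination = 6, n_novel_extension = 6,
                         n_samples = 30, n_populations = 3,
                         n_edit_exhaustive = 8, n_edit_partial = 8) {
  structure(as.list(environment()), class = "fixture_spec")
}

# --- genome + annotation ----------------------------------------------------

build_genome <- function(spec) {
  don_p <- site_truth_probs("donor")
  acc_p <- site_truth_probs("acceptor")
  chars <- character(0)
  exons <- list()
  gaps <- list()   # intergenic intervals, used to place PCS fixtures
  cursor <- 1L
  for (g in seq_len(spec$n_genes)) {
    gap_len <- spec$intergenic
    chars <- c(chars, strsplit(random_dna(gap_len), "")[[1]])
    gaps[[g]] <- c(cursor, cursor + gap_len - 1L)
    cursor <- cursor + gap_len
    strand <- if (g %% 2 == 1) "+" else "-"
    ex_len <- sample(seq(spec$exon_length[1], spec$exon_length[2]),
                     spec$exons_per_gene, replace = TRUE)
    in_len <- sample(seq(spec$intron_length[1], spec$intron_length[2]),
                     spec$exons_per_gene - 1, replace = TRUE)
    gene_start <- cursor
    ex <- matrix(0L, nrow = spec$exons_per_gene, ncol = 2)
    pos <- gene_start
    pieces <- character(0)
    for (e in seq_len(spec$exons_per_gene)) {
      ex[e, ] <- c(pos, pos + ex_len[e] - 1L)
      pieces <- c(pieces, random_dna(ex_len[e]))
      pos <- pos + ex_len[e]
      if (e < spec$exons_per_gene) {
        pieces <- c(pieces, random_dna(in_len[e]))
        pos <- pos + in_len[e]
      }
    }
    gene_chars <- strsplit(paste0(pieces, collapse = ""), "")[[1]]
    # overwrite splice-site windows with draws from the true models
    for (e in seq_len(spec$exons_per_gene - 1)) {
      intron_start <- ex[e, 2] + 1L
      intron_end <- ex[e + 1, 1] - 1L
      don_b <- if (strand == "+") intron_start else intron_end
      acc_b <- if (strand == "+") intron_end else intron_start
      wd <- sample_windows(don_p, 1)
      wa <- sample_windows(acc_p, 1)
      for (w in list(list(win = wd, b = don_b, kind = "donor"),
                     list(win = wa, b = acc_b, kind = "acceptor"))) {
        gpos <- rel_to_genomic(window_rel_positions(w$kind), w$b, strand,
                               w$kind)
        seqc <- strsplit(if (strand == "-") revcomp(w$win) else w$win,
                         "")[[1]]
        gene_chars[sort(gpos) - gene_start + 1L] <- seqc
      }
    }
    chars <- c(chars, gene_chars)
    cursor <- cursor + length(gene_chars)
    exons[[g]] <- tibble(
      gene_id = sprintf("G%03d", g),
      transcript_id = sprintf("G%03d.t1", g),
      chrom = "chrS", strand = strand,
      exon_start = ex[, 1], exon_end = ex[, 2]
    )
  }
  # trailing gap
  chars <- c(chars, strsplit(random_dna(spec$intergenic), "")[[1]])
  gaps[[spec$n_genes + 1L]] <- c(cursor, cursor + spec$intergenic - 1L)

  transcripts <- bind_rows(exons)
  # exon-skipping second transcript for a deterministic subset of genes
  alt_genes <- unique(transcripts$gene_id)
  alt_genes <- alt_genes[seq_along(alt_genes) %%
                           round(1 / max(spec$alt_fraction, 1e-9)) == 0]
  if (spec$exons_per_gene >= 3 && length(alt_genes) > 0) {
    skip <- transcripts |>
      filter(.data$gene_id %in% alt_genes) |>
      group_by(.data$gene_id) |>
      mutate(rank = dplyr::row_number()) |>
      filter(.data$rank != 2L + (dplyr::cur_group_id() %% 2L)) |>
      ungroup() |>
      mutate(transcript_id = sub("t1$", "t2", .data$transcript_id)) |>
      select(-"rank")
    transcripts <- bind_rows(transcripts, skip) |>
      arrange(.data$transcript_id, .data$exon_start)
  }
  list(chars = chars, transcripts = transcripts,
       gaps = do.call(rbind, gaps))
}

# pick a substitution of the requested class at one site, or NULL
plant_substitution <- function(truth, kind, window, class, tau,
                               margin = 0.7) {
  rels <- window_rel_positions(kind)
  order_idx <- sample(seq_along(rels))
  for (i in order_idx) {
    pb <- truth[, i]
    if (max(pb) >= 0.999) next            # canonical dinucleotide
    b <- substr(window, i, i)
    p_ref <- pb[[b]]
    for (a in setdiff(DNA_BASES, b)) {
      p_alt <- pb[[a]]
      if (p_alt == 0 || p_ref == 0) next
      lr <- log(p_alt / p_ref)
      hit <- switch(class,
        weakening = lr <= -(tau + margin) && p_alt >= 0.03 && p_ref >= 0.2,
        enhancing = lr >= (tau + margin) && p_ref >= 0.03 && p_alt >= 0.2,
        neutral = abs(lr) <= 0.2 && p_alt >= 0.08 && p_ref >= 0.08,
        FALSE)
      if (hit) return(list(pos_idx = i, rel = rels[i], ref = b, alt = a))
    }
  }
  NULL
}

daf_for_class <- function(class, n) {
  switch(class,
         disrupting = stats::rbeta(n, 1, 9),
         weakening = stats::rbeta(n, 1, 6),
         neutral = runif(n),
         enhancing = stats::rbeta(n, 3, 2),
         activating = stats::rbeta(n, 5, 2))
}

# window base -> plus-strand genomic allele
to_plus <- function(base, strand) {
  ifelse(strand == "+", base, chartr("ACGT", "TGCA", base))
}

plant_variants <- function(genome_chars, sites, spec) {
  don_t <- site_truth_probs("donor")
  acc_t <- site_truth_probs("acceptor")
  taus <- c(donor = 1.5, acceptor = 1.0)
  avail <- sites |> mutate(used = FALSE)
  out <- list()
  genome1 <- paste0(genome_chars, collapse = "")
  win_of <- function(row) {
    s <- substr(genome1, row$window_start, row$window_end)
    if (row$strand == "-") revcomp(s) else s
  }

  # activating first: break the genome at the site, variant restores it
  n_act <- spec$n_per_class[["activating"]]
  act_rows <- which(!avail$used)
  act_pick <- head(act_rows[sample(length(act_rows))], n_act)
  for (ri in act_pick) {
    row <- avail[ri, ]
    # break the canonical dinucleotide base (+1 G for donors, -1 G for
    # acceptors): G -> A in window coordinates
    rel <- if (row$kind == "donor") 1L else -1L
    gpos <- rel_to_genomic(rel, row$boundary, row$strand, row$kind)
    broken <- to_plus("A", row$strand)
    restored <- genome_chars[gpos]          # the original (canonical) base
    genome_chars[gpos] <- broken
    out[[length(out) + 1]] <- tibble(
      chrom = row$chrom, pos = gpos, ref = broken, alt = restored,
      true_class = "activating", site_id = row$site_id)
    avail$used[ri] <- TRUE
  }
  genome1 <- paste0(genome_chars, collapse = "")

  for (class in c("disrupting", "weakening", "neutral", "enhancing")) {
    n_want <- spec$n_per_class[[class]]
    rows <- which(!avail$used)
    rows <- rows[sample(length(rows))]
    got <- 0L
    for (ri in rows) {
      if (got >= n_want) break
      row <- avail[ri, ]
      truth <- if (row$kind == "donor") don_t else acc_t
      win <- win_of(row)
      if (class == "disrupting") {
        rel <- if (row$kind == "donor") 2L else -2L   # T of GT / A of AG
        idx <- match(rel, window_rel_positions(row$kind))
        ref_w <- substr(win, idx, idx)
        alt_w <- if (ref_w == "A") "C" else "A"
        sub <- list(rel = rel, ref = ref_w, alt = alt_w)
      } else {
        sub <- plant_substitution(truth, row$kind, win, class,
                                  taus[[row$kind]])
        if (is.null(sub)) next
      }
      gpos <- rel_to_genomic(sub$rel, row$boundary, row$strand, row$kind)
      out[[length(out) + 1]] <- tibble(
        chrom = row$chrom, pos = gpos,
        ref = to_plus(sub$ref, row$strand),
        alt = to_plus(sub$alt, row$strand),
        true_class = class, site_id = row$site_id)
      avail$used[ri] <- TRUE
      got <- got + 1L
    }
  }
  v <- bind_rows(out)
  v$daf <- unlist(lapply(seq_len(nrow(v)), function(i) {
    daf_for_class(v$true_class[i], 1)
  }))
  list(genome_chars = genome_chars, variants = v |> arrange(.data$pos))
}

# --- read-level fixtures ----------------------------------------------------

sim_junction_reads <- function(annotation, transcripts, spec) {
  introns <- annotation$introns |>
    distinct(.data$chrom, .data$strand, .data$intron_start,
             .data$intron_end, .data$donor_boundary,
             .data$acceptor_boundary)
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  pops <- sprintf("P%d", seq_len(spec$n_populations))
  pop_of <- setNames(rep(pops, length.out = spec$n_samples), samples)
  mk <- function(chrom, strand, don, acc, n_reads, sample_pool,
                 truth = NA_character_) {
    smp <- sample(sample_pool, n_reads, replace = TRUE)
    tibble(read_id = paste0("r", seq_len(n_reads)), sample_id = smp,
           population_id = unname(pop_of[smp]), chrom = chrom,
           strand = strand, donor_boundary = don, acceptor_boundary = acc,
           mapq = 200L, edit_distance = sample(0:2, n_reads, TRUE),
           properly_paired = TRUE,
           insert_size = sample(150:400, n_reads, TRUE), truth = truth)
  }
  out <- list()
  # annotated junction support
  for (i in seq_len(nrow(introns))) {
    out[[length(out) + 1]] <- mk(introns$chrom[i], introns$strand[i],
                                 introns$donor_boundary[i],
                                 introns$acceptor_boundary[i],
                                 sample(3:8, 1), samples, "annotated")
  }
  shift_into <- function(b, strand, side) {
    # move a boundary 6 nt into the intron (novel but within 30 nt)
    if (side == "donor") b + ifelse(strand == "+", 6L, -6L) else
      b + ifelse(strand == "+", -6L, 6L)
  }
  pick <- introns[sample(nrow(introns)), ]
  k <- 1L
  plant <- function(don, acc, row, n_design, support, pool, label) {
    mk(row$chrom, row$strand, don, acc, support, pool, label)
  }
  for (j in seq_len(spec$n_novel_internal)) {
    row <- pick[k, ]; k <- k + 1L
    out[[length(out) + 1]] <- mk(row$chrom, row$strand,
                                 shift_into(row$donor_boundary, row$strand,
                                            "donor"),
                                 row$acceptor_boundary,
                                 sample(2:5, 1), samples, "novel_donor")
  }
  for (j in seq_len(spec$n_novel_two)) {
    row <- pick[k, ]; k <- k + 1L
    out[[length(out) + 1]] <- mk(row$chrom, row$strand,
                                 shift_into(row$donor_boundary, row$strand,
                                            "donor"),
                                 shift_into(row$acceptor_boundary,
                                            row$strand, "acceptor"),
                                 sample(2:5, 1), samples, "novel_two")
  }
  # novel combination: donor of one intron with the acceptor of the next
  combo <- annotation$introns |>
    group_by(.data$transcript_id) |>
    filter(dplyr::n() >= 2, grepl("t1$", .data$transcript_id[1])) |>
    slice(1:2) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              # exon-skipping junction: donor of the transcript-first
              # intron with the acceptor of the second (strand-aware,
              # introns being stored in genomic order)
              don = if_else(first(.data$strand) == "+",
                            .data$donor_boundary[1],
                            .data$donor_boundary[2]),
              acc = if_else(first(.data$strand) == "+",
                            .data$acceptor_boundary[2],
                            .data$acceptor_boundary[1]),
              .groups = "drop")
  # a skip junction can coincide with an annotated intron of the gene's
  # exon-skipping transcript; those are not novel combinations
  combo <- combo |>
    anti_join(introns,
              by = c(chrom = "chrom", strand = "strand",
                     don = "donor_boundary", acc = "acceptor_boundary"))
  combo <- combo[sample(nrow(combo)), ]
  for (j in seq_len(min(spec$n_novel_combination, nrow(combo)))) {
    out[[length(out) + 1]] <- mk(combo$chrom[j], combo$strand[j],
                                 combo$don[j], combo$acc[j],
                                 sample(2:5, 1), samples,
                                 "novel_combination")
  }
  # extension: junction just beyond the transcript 5' extremity
  spans <- transcripts |>
    group_by(.data$gene_id, .data$strand, .data$chrom) |>
    summarise(tx_start = min(.data$exon_start), tx_end = max(.data$exon_end),
              .groups = "drop")
  spans <- spans[sample(nrow(spans)), ]
  for (j in seq_len(min(spec$n_novel_extension, nrow(spans)))) {
    sp <- spans[j, ]
    if (sp$strand == "+") {
      don <- sp$tx_start - 60L; acc <- sp$tx_start - 25L
    } else {
      don <- sp$tx_end + 60L; acc <- sp$tx_end + 25L
    }
    out[[length(out) + 1]] <- mk(sp$chrom, sp$strand, don, acc,
                                 sample(2:5, 1), samples, "novel_extension")
  }
  # low-quality evidence that the filters must drop
  row <- pick[k, ]
  bad <- mk(row$chrom, row$strand,
            shift_into(row$donor_boundary, row$strand, "donor") + 3L,
            row$acceptor_boundary, 3, samples, "low_quality")
  bad$mapq <- 40L
  out[[length(out) + 1]] <- bad
  bind_rows(out) |> mutate(read_id = paste0("jr", dplyr::row_number()))
}

sim_polya_fixture <- function(genome_chars, gaps, spec) {
  n <- spec$n_pcs
  gap_rows <- rep(seq_len(nrow(gaps)), length.out = n)
  support <- rep(spec$pcs_read_support, length.out = n)
  strand <- rep(c("+", "-"), length.out = n)
  # motif design cycles: rank-1, rank-13, none
  motif_plan <- rep(c("AATAAA", "AATAGA", NA), length.out = n)
  pcs <- tibble(chrom = "chrS", strand = strand,
                position = gaps[gap_rows, 1] + 60L,
                read_support = as.integer(support),
                motif = motif_plan)
  reads <- list(); aligns <- list()
  for (i in seq_len(n)) {
    p <- pcs$position[i]
    # G/C-only neighbourhood: no poly-A hexamer can occur spontaneously
    # (all 13 contain A/T), so the planted motif is the unambiguous truth
    # and templated read segments always pass the A+T complexity filter
    genome_chars[(p - 55L):(p + 55L)] <- sample(c("C", "G"), 111L,
                                                replace = TRUE)
    if (!is.na(pcs$motif[i])) {
      hex <- pcs$motif[i]
      if (pcs$strand[i] == "+") {
        genome_chars[(p - 30L):(p - 25L)] <- strsplit(hex, "")[[1]]
      } else {
        genome_chars[(p + 25L):(p + 30L)] <- strsplit(revcomp(hex), "")[[1]]
      }
    }
    for (r in seq_len(pcs$read_support[i])) {
      if (pcs$strand[i] == "+") {
        templ <- paste0(genome_chars[(p - 29L):p], collapse = "")
        seq <- paste0(templ, strrep("A", 12L))
        aligns[[length(aligns) + 1]] <- tibble(
          read_id = sprintf("pa%d_%d", i, r), chrom = "chrS", strand = "+",
          start = p - 29L, end = p, unique = TRUE)
      } else {
        templ_fwd <- paste0(genome_chars[p:(p + 29L)], collapse = "")
        seq <- paste0(strrep("T", 12L), templ_fwd)
        aligns[[length(aligns) + 1]] <- tibble(
          read_id = sprintf("pa%d_%d", i, r), chrom = "chrS", strand = "-",
          start = p, end = p + 29L, unique = TRUE)
      }
      reads[[length(reads) + 1]] <- tibble(
        read_id = sprintf("pa%d_%d", i, r), seq = seq)
    }
  }
  # reads the selection / trimming / complexity filters must reject
  junk <- tibble(
    read_id = c("junk_short", "junk_lowcx", "junk_untailed"),
    seq = c(paste0(random_dna(12), strrep("A", 10L)),
            paste0(strrep("AT", 20L), strrep("A", 10L)),
            random_dna(40)))
  list(genome_chars = genome_chars, pcs_truth = pcs,
       reads = bind_rows(c(reads, list(junk))),
       alignments = bind_rows(aligns))
}

sim_editing_fixture <- function(genome_chars, annotation, transcripts,
                                spec) {
  acc <- annotation$sites |> filter(.data$kind == "acceptor")
  acc <- acc[sample(nrow(acc)), ]
  n_ex <- spec$n_edit_exhaustive; n_pa <- spec$n_edit_partial
  n_tot <- n_ex + n_pa
  stopifnot(nrow(acc) >= n_tot + 4)
  genes <- transcripts |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$exon_start), end = max(.data$exon_end),
              .groups = "drop")
  mk_site <- function(row, efficiency, qual = 200, med_cov = 30,
                      n_alt = 20) {
    # the edited base is the A of the acceptor AG (relative -2)
    gpos <- rel_to_genomic(-2L, row$boundary, row$strand, row$kind)
    ref_plus <- if (row$strand == "+") "A" else "T"
    alt_plus <- if (row$strand == "+") "G" else "C"
    depth <- 40L
    alt_n <- round(depth * efficiency)
    tibble(chrom = row$chrom, pos = gpos, ref = ref_plus, alt = alt_plus,
           qual = qual, median_coverage = med_cov, n_alt_samples = n_alt,
           ref_count = depth - alt_n, alt_count = alt_n,
           site_id = row$site_id, strand = row$strand)
  }
  eff_ex <- runif(n_ex, 0.92, 0.99)
  eff_pa <- runif(n_pa, 0.30, 0.70)
  calls <- bind_rows(
    lapply(seq_len(n_ex), function(i) mk_site(acc[i, ], eff_ex[i])),
    lapply(seq_len(n_pa), function(i) mk_site(acc[n_ex + i, ], eff_pa[i]))
  )
  calls$true_group <- rep(c("exhaustive", "partial"), c(n_ex, n_pa))
  # calls the filters must remove
  fail_rows <- acc[(n_tot + 1):(n_tot + 4), ]
  fails <- bind_rows(
    mk_site(fail_rows[1, ], 0.5, qual = 50),            # low quality
    mk_site(fail_rows[2, ], 0.5, med_cov = 9),          # median coverage < 10
    mk_site(fail_rows[3, ], 0.5, n_alt = 9),            # < 10 samples
    mk_site(fail_rows[4, ], 0.5)                        # genomic contaminant
  )
  fails$true_group <- c("fail_qual", "fail_cov", "fail_samples",
                        "fail_genomic")
  genomic <- fails |> filter(.data$true_group == "fail_genomic") |>
    select("chrom", "pos")
  # intron coverage: exhaustively edited disrupted sites retain introns
  cov <- c(stats::rlnorm(n_ex, log(4), 0.4), stats::rlnorm(n_pa, log(1.5),
                                                           0.4))
  list(rna_variants = bind_rows(calls, fails) |> select(-"strand"),
       genomic_variants = genomic, genes = genes,
       intron_coverage = tibble(site_id = calls$site_id,
                                exhaustive = calls$true_group ==
                                  "exhaustive", coverage = cov))
}

#' Simulate junction count matrices with a PSI response to score deltas
#'
#' Emulates the accumulation of positive / negative splice-score alleles
#' across individuals: each individual carries a net allele dosage per
#' exon; the per-individual inclusion level follows a logistic response to
#' the accumulated dosage, observed through binomial junction read counts.
#'
#' @param seed RNG seed.
#' @param n_individuals,n_exons Grid size.
#' @param coverage Junction read coverage per exon and individual.
#' @param effect Logit shift per unit of net positive dosage.
#' @param noise_sd Individual-by-exon logit noise.
#' @return Tibble with `individual`, `exon`, `net_dosage`, `inclusion_left`,
#'   `inclusion_right`, `exclusion`.
#' @export
sim_psi_fixture <- function(seed = 1, n_individuals = 100, n_exons = 40,
                            coverage = 60, effect = 0.9, noise_sd = 0.3) {
  withr::local_seed(seed)
  base_logit <- stats::qlogis(runif(n_exons, 0.35, 0.65))
  grid <- expand_grid(individual = seq_len(n_individuals),
                      exon = seq_len(n_exons))
  # net dosage in -2..2: two haplotypes each carrying -1/0/+1 effect alleles
  dos <- matrix(sample(-1:1, n_individuals * 2, replace = TRUE,
                       prob = c(.3, .4, .3)), ncol = 2)
  net <- rowSums(dos)
  grid$net_dosage <- net[grid$individual]
  lg <- base_logit[grid$exon] + effect * grid$net_dosage +
    rnorm(nrow(grid), 0, noise_sd)
  psi <- stats::plogis(lg)
  grid$inclusion_left <- rbinom(nrow(grid), coverage, psi)
  grid$inclusion_right <- rbinom(nrow(grid), coverage, psi)
  grid$exclusion <- rbinom(nrow(grid), coverage, 1 - psi)
  grid
}

# --- master fixture ---------------------------------------------------------

#' Generate the full synthetic fixture
#'
#' Builds, deterministically from the spec's seed, a synthetic genome with
#' canonical GT..AG introns whose windows are drawn from the true site
#' models, plus planted ground truth for every pipeline stage: variants of
#' each effect class (with class-specific derived-allele-frequency
#' distributions), split-read junction evidence with planted novel introns,
#' poly-A-tailed reads at planted cleavage sites with planted signal
#' hexamers, and RNA-editing calls with chosen efficiencies.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `genome` (DNAStringSet), `transcripts`, `annotation`
#'   (from [derive_introns()]), `sites` (with reference windows),
#'   `train_donor` / `train_acceptor` (training windows),
#'   `background` (background sequences), `variants` (with `true_class`
#'   and `daf`), `junction_reads`, `polya` (reads, alignments,
#'   `pcs_truth`), `editing` (rna_variants, genomic_variants, genes,
#'   intron_coverage), and `spec`.
#' @export
sim_fixture <- function(spec = fixture_spec()) {
  withr::local_seed(spec$seed)
  gb <- build_genome(spec)
  ann <- derive_introns(gb$transcripts)

  # training catalogue: an independent draw from the same true models
  train_donor <- sample_windows(site_truth_probs("donor"), spec$n_train)
  train_acceptor <- sample_windows(site_truth_probs("acceptor"),
                                   spec$n_train)
  background <- vapply(seq_len(50), function(i) random_dna(500),
                       character(1))

  # poly-A fixtures first: they write signal hexamers into intergenic DNA
  pa <- sim_polya_fixture(gb$chars, gb$gaps, spec)
  chars <- pa$genome_chars

  # plant variants (activating ones mutate the genome at their site)
  pv <- plant_variants(chars, ann$sites, spec)
  chars <- pv$genome_chars

  genome <- Biostrings::DNAStringSet(paste0(chars, collapse = ""))
  names(genome) <- "chrS"
  sites <- extract_window(genome, ann$sites)

  junction_reads <- sim_junction_reads(ann, gb$transcripts, spec)
  editing <- sim_editing_fixture(chars, ann, gb$transcripts, spec)

  list(genome = genome, transcripts = gb$transcripts, annotation = ann,
       sites = sites, train_donor = train_donor,
       train_acceptor = train_acceptor, background = background,
       variants = pv$variants, junction_reads = junction_reads,
       polya = pa[c("reads", "alignments", "pcs_truth")],
       editing = editing, spec = spec)
}
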
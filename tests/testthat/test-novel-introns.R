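# PNI rescue from split-read evidence, event typing and support tables.

test_that("planted novel junctions are rescued with correct novelty flags", {
  fx <- std_fixture()
  pni <- rescue_pni(fx$junction_reads, fx$annotation,
                    transcripts = fx$transcripts, genome = fx$genome)
  truth <- fx$junction_reads |>
    dplyr::filter(!truth %in% c("annotated", "low_quality")) |>
    dplyr::distinct(chrom, strand, donor_boundary, acceptor_boundary,
                    truth)
  j <- dplyr::inner_join(pni, truth,
                         by = c("chrom", "strand", "donor_boundary",
                                "acceptor_boundary"))
  expect_equal(nrow(j), nrow(truth))      # every planted junction rescued
  expect_equal(nrow(pni), nrow(truth))    # and nothing else
  expect_true(all(j$donor_novel[j$truth == "novel_donor"]))
  expect_false(any(j$acceptor_novel[j$truth == "novel_donor"]))
  expect_true(all(j$donor_novel[j$truth == "novel_two"] &
                    j$acceptor_novel[j$truth == "novel_two"]))
  expect_false(any(j$donor_novel[j$truth == "novel_combination"] |
                     j$acceptor_novel[j$truth == "novel_combination"]))
})

test_that("annotated junctions and low-quality mappings never become PNIs", {
  fx <- std_fixture()
  pni <- rescue_pni(fx$junction_reads, fx$annotation,
                    transcripts = fx$transcripts)
  ann_keys <- with(fx$annotation$introns,
                   paste(chrom, strand, donor_boundary, acceptor_boundary))
  expect_false(any(paste(pni$chrom, pni$strand, pni$donor_boundary,
                         pni$acceptor_boundary) %in% ann_keys))
  lq <- fx$junction_reads |> dplyr::filter(truth == "low_quality")
  expect_false(any(paste(pni$donor_boundary, pni$acceptor_boundary) %in%
                     paste(lq$donor_boundary, lq$acceptor_boundary)))
  # raising mapq further only shrinks the PNI set
  pni_strict <- rescue_pni(fx$junction_reads, fx$annotation,
                           transcripts = fx$transcripts, min_mapq = 250)
  expect_lte(nrow(pni_strict), nrow(pni))
  # malformed junctions error
  bad <- fx$junction_reads[1, ]
  bad$acceptor_boundary <- bad$donor_boundary
  expect_error(rescue_pni(bad, fx$annotation), "malformed")
})

test_that("event typing separates internal, extension and pattern labels", {
  fx <- std_fixture()
  pni <- rescue_pni(fx$junction_reads, fx$annotation,
                    transcripts = fx$transcripts)
  truth <- fx$junction_reads |>
    dplyr::distinct(chrom, strand, donor_boundary, acceptor_boundary,
                    truth)
  ev <- classify_pni_event(pni, fx$transcripts) |>
    dplyr::inner_join(truth, by = c("chrom", "strand", "donor_boundary",
                                    "acceptor_boundary"))
  expect_true(all(ev$category[ev$truth == "novel_donor"] == "internal"))
  expect_true(all(ev$pattern[ev$truth == "novel_donor"] ==
                    "one-novel-donor"))
  expect_true(all(ev$pattern[ev$truth == "novel_two"] == "two-novel"))
  expect_true(all(ev$category[ev$truth == "novel_combination"] ==
                    "internal"))
  expect_true(all(ev$pattern[ev$truth == "novel_combination"] ==
                    "novel-combination"))
  expect_true(all(ev$category[ev$truth == "novel_extension"] ==
                    "extension"))
  expect_true(all(ev$subcategory[ev$truth == "novel_extension"] ==
                    "upstream_of_tss"))
})

test_that("canonical dinucleotide flags come from the genome", {
  fx <- std_fixture()
  pni <- rescue_pni(fx$junction_reads, fx$annotation,
                    transcripts = fx$transcripts, genome = fx$genome)
  # novel combinations reuse annotated GT/AG sites: always canonical
  truth <- fx$junction_reads |>
    dplyr::distinct(chrom, strand, donor_boundary, acceptor_boundary,
                    truth)
  j <- dplyr::inner_join(pni, truth,
                         by = c("chrom", "strand", "donor_boundary",
                                "acceptor_boundary"))
  expect_true(all(j$canonical[j$truth == "novel_combination"]))
})

test_that("support tables are hand-checkable and monotone", {
  pnis <- tibble::tibble(n_individuals = c(10, 200, 400, 460),
                         n_populations = c(1, 3, 3, 3))
  s <- support_summary(pnis, n_populations_total = 3)
  expect_equal(s$n_pnis[s$level == "all"], 4L)
  expect_equal(s$n_pnis[s$level == ">0 in all populations"], 3L)
  expect_equal(s$n_pnis[s$level == ">150 individuals"], 3L)
  expect_equal(s$n_pnis[s$level == ">300 individuals"], 2L)
  expect_equal(s$n_pnis[s$level == ">450 individuals"], 1L)
  thr <- s$n_pnis[grepl("individuals", s$level)]
  expect_true(all(diff(thr) <= 0))
  # boundary is strict: exactly 150 does not count as >150
  s2 <- support_summary(tibble::tibble(n_individuals = 150,
                                       n_populations = 1))
  expect_equal(s2$n_pnis[s2$level == ">150 individuals"], 0L)
  empty <- support_summary(tibble::tibble(n_individuals = numeric(),
                                          n_populations = numeric()))
  expect_true(all(empty$n_pnis == 0))
})

test_that("PNI confirmation is an exact junction match", {
  a <- tibble::tibble(chrom = "c1", strand = "+",
                      donor_boundary = c(10L, 20L, 30L, 40L),
                      acceptor_boundary = c(100L, 200L, 300L, 400L))
  expect_equal(attr(confirm_pni(a, a), "fraction"), 1)
  expect_equal(attr(confirm_pni(a, a[0, ]), "fraction"), 0)
  b <- a[2, ]
  b$acceptor_boundary <- 201L
  out <- confirm_pni(a, dplyr::bind_rows(a[1, ], b))
  expect_equal(attr(out, "fraction"), 0.25)
})

test_that("novel splice sites score and classify exactly like annotated ones", {
  fx <- std_fixture()
  pni <- rescue_pni(fx$junction_reads, fx$annotation,
                    transcripts = fx$transcripts, genome = fx$genome)
  novel_don <- pni |> dplyr::filter(donor_novel)
  sites <- tibble::tibble(
    site_id = paste0("pni_d", seq_len(nrow(novel_don))),
    chrom = novel_don$chrom, strand = novel_don$strand, kind = "donor",
    boundary = novel_don$donor_boundary)
  iv <- window_interval_for_test(sites$boundary, sites$strand)
  sites$window_start <- iv$start
  sites$window_end <- iv$end
  sites <- extract_window(fx$genome, sites)
  sc <- score_site(fx$donor_model, sites$ref_window, strict = FALSE)
  expect_true(all(is.finite(sc$score)))
  # a planted disrupting change at the shifted GT behaves identically to
  # the annotated-site pathway
  s1 <- sites[1, ]
  gpos <- s1$boundary + ifelse(s1$strand == "+", 1L, -1L)
  g <- as.character(fx$genome[["chrS"]])
  refb <- substr(g, gpos, gpos)
  v <- tibble::tibble(chrom = "chrS", pos = gpos, ref = refb,
                      alt = setdiff(c("A", "C", "G", "T"), refb)[1])
  cl <- classify_variants(fx$genome, s1, v, fx$donor_model,
                          fx$acceptor_model)
  expect_equal(nrow(cl), 1)
  expect_true(cl$effect_class %in% c("disrupting", "weakening",
                                     "neutral_nonfunctional"))
})
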
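# Poly-A read rescue, cleavage-site calling, hexamer scanning and motif
# variant classification.

test_that("candidate selection keeps A-tails and T-heads only", {
  reads <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    seq = c("ACGTGGCCAAAA", "TTTTACGTGGCC", "ACGTGGCCAAAG", "ACGTACGT"))
  out <- select_polya_reads(reads)
  expect_equal(out$read_id, c("a", "b"))
  expect_equal(out$tail_side, c("A3", "T5"))
})

test_that("tail trimming follows the one-mismatch, minimum-length rule", {
  tr <- function(seq, side = "A3") {
    trim_tail(tibble::tibble(seq = seq, tail_side = side))
  }
  # clean 10-A tail
  t1 <- tr(paste0("CGTCGGCGTCG", strrep("A", 10)))
  expect_equal(t1$tail_length, 10L)
  expect_equal(t1$trimmed_seq, "CGTCGGCGTCG")
  # one internal mismatch is absorbed: AAAAGAAAA trims fully (length 9)
  t2 <- tr("CGTCGGCGTCGAAAAGAAAA")
  expect_equal(t2$tail_length, 9L)
  expect_equal(t2$trimmed_seq, "CGTCGGCGTCG")
  # a 4-A tail is below the minimum and left untouched
  t3 <- tr("CGTCGGCGTCGAAAA")
  expect_equal(t3$tail_length, 0L)
  expect_equal(t3$trimmed_seq, "CGTCGGCGTCG AAAA" |> gsub(" ", "", x = _))
  # two mismatches stop the run
  t4 <- tr("CGAAAGAAAGAAAA")
  expect_equal(t4$tail_length, 8L)   # GAAAA + AAA absorbs one G only
  # T-heads trim from the 5' side
  t5 <- tr(paste0(strrep("T", 7), "CGTCGGCGTCG"), side = "T5")
  expect_equal(t5$tail_length, 7L)
  expect_equal(t5$trimmed_seq, "CGTCGGCGTCG")
  # trimming an already-trimmed read changes nothing
  t6 <- trim_tail(tibble::tibble(seq = t1$trimmed_seq, tail_side = "A3"))
  expect_equal(t6$trimmed_seq, t1$trimmed_seq)
  expect_equal(t6$tail_length, 0L)
})

test_that("informative-read filtering uses strict length and inclusive A+T bounds", {
  reads <- tibble::tibble(trimmed_seq = c(
    strrep("ACGTC", 5),                    # length 25: too short (not > 25)
    paste0(strrep("AT", 12), "ATGCGC"),    # length 30, 80% A+T: low complexity
    paste0(strrep("GC", 8), strrep("ACGT", 4))))  # length 32, 25% A+T: keep
  out <- filter_informative(reads)
  expect_equal(out$keep, c(FALSE, FALSE, TRUE))
  expect_equal(out$drop_reason, c("too_short", "low_complexity", NA))
})

test_that("cleavage sites collapse by exact position and strand with summed support", {
  al <- tibble::tibble(
    read_id = paste0("r", 1:5), chrom = "c1",
    strand = c("+", "+", "-", "-", "+"),
    start = c(101L, 101L, 201L, 201L, 301L),
    end = c(200L, 200L, 300L, 300L, 400L),
    unique = TRUE)
  pcs <- call_pcs(al)
  expect_equal(nrow(pcs), 3)
  plus <- pcs[pcs$strand == "+" & pcs$position == 200L, ]
  expect_equal(plus$read_support, 2L)
  expect_true(plus$conservative)
  minus <- pcs[pcs$strand == "-", ]
  expect_equal(minus$position, 201L)   # strand-symmetric anchor
  single <- pcs[pcs$position == 400L, ]
  expect_equal(single$read_support, 1L)
  expect_false(single$conservative)    # >= 2 reads needed
  # support conservation
  expect_equal(sum(pcs$read_support), nrow(al))
  # same position, opposite strands stay distinct
  al2 <- tibble::tibble(read_id = c("x", "y"), chrom = "c1",
                        strand = c("+", "-"), start = c(1L, 50L),
                        end = c(50L, 99L), unique = TRUE)
  expect_equal(nrow(call_pcs(al2)), 2)
  # non-unique alignments rejected in strict mode
  al$unique[1] <- FALSE
  expect_error(call_pcs(al), "non-unique")
})

test_that("raising the support threshold never increases the PCS count", {
  fx <- std_fixture()
  pcs <- call_pcs(fx$polya$alignments)
  n <- vapply(1:4, function(k) sum(pcs$read_support >= k), numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("cross-dataset PCS confirmation uses the +/-50 nt window inclusively", {
  a <- tibble::tibble(chrom = "c1", strand = "+",
                      position = c(1000L, 2000L, 3000L))
  b <- tibble::tibble(chrom = "c1", strand = "+",
                      position = c(1050L, 2051L))
  out <- confirm_pcs(a, b, window = 50)
  expect_equal(out$confirmed, c(TRUE, FALSE, FALSE))  # 50 in, 51 out
  expect_equal(attr(out, "fraction"), 1 / 3)
  empty <- confirm_pcs(a, b[0, ])
  expect_equal(attr(empty, "fraction"), 0)
})

test_that("the hexamer scan returns the smallest rank, closest occurrence", {
  pad <- function(s) {
    # embed at given offsets in a 101-nt backdrop free of listed hexamers
    backdrop <- strrep("C", 101)
    s(backdrop)
  }
  put <- function(backdrop, hex, at) {
    substr(backdrop, at, at + 5) <- hex
    backdrop
  }
  w <- put(put(strrep("C", 101), "TTTAAA", 10), "AATAAA", 70)
  hit <- scan_polya_motif(w)
  expect_equal(hit$hexamer, "AATAAA")  # rank 1 beats rank 11 regardless of distance
  expect_equal(hit$rank, 1L)
  w2 <- put(strrep("C", 101), "AATAGA", 20)
  hit2 <- scan_polya_motif(w2)
  expect_equal(hit2$rank, 13L)
  expect_equal(nrow(scan_polya_motif(strrep("C", 101))), 0)
  # among occurrences of the winning hexamer, the closest wins; at equal
  # distance the upstream one does
  w3 <- put(put(strrep("C", 101), "AATAAA", 11), "AATAAA", 81)
  # offsets: 11 -> -40; 81 -> +30: downstream closer
  expect_equal(scan_polya_motif(w3)$offset, 30L)
  w4 <- put(put(strrep("C", 101), "AATAAA", 21), "AATAAA", 81)
  # offsets -30 and +30: tie -> upstream
  expect_equal(scan_polya_motif(w4)$offset, -30L)
  # upstream-only mode ignores downstream occurrences
  expect_equal(scan_polya_motif(w3, upstream_only = TRUE)$offset, -40L)
})

test_that("scanner rank equals the minimum over an exhaustive occurrence scan", {
  withr::local_seed(61)
  for (i in 1:50) {
    w <- paste0(sample(c("A", "C", "G", "T"), 101, replace = TRUE,
                       prob = c(.35, .15, .15, .35)), collapse = "")
    hit <- scan_polya_motif(w)
    present <- vapply(polya_hexamers(), function(h) grepl(h, w, fixed = TRUE),
                      logical(1))
    if (!any(present)) {
      expect_equal(nrow(hit), 0)
    } else {
      expect_equal(hit$rank, min(which(present)))
    }
  }
})

test_that("motif variants classify by membership in the 13-hexamer list", {
  out <- classify_motif_variant(c("AATAAA", "AATAAA", "AATAAA", "AATAAA"),
                                c("ATTAAA", "AAGAAA", "AATCAA", "AATAAA"))
  expect_equal(out$status, c("altered", "altered", "degraded", "unchanged"))
  expect_error(classify_motif_variant("CCCCCC", "AATAAA"), "13 listed")
})

test_that("motif distance comparison flags a planted shift", {
  same <- motif_distance_comparison(c(5, 10, 15, 20), c(5, 10, 15, 20))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
  withr::local_seed(67)
  altered <- runif(200, 5, 30)
  degraded <- altered + 5
  r <- motif_distance_comparison(altered, degraded)
  expect_lt(r$p_value, 0.01)
  expect_equal(r$direction, "degraded_farther")
  expect_error(motif_distance_comparison(numeric(0), c(1, 2)), "non-empty")
})

test_that("planted cleavage sites round-trip through the full read pipeline", {
  fx <- std_fixture()
  sel <- select_polya_reads(fx$polya$reads)
  trimmed <- trim_tail(sel)
  kept <- filter_informative(trimmed)
  # every planted read survives; all junk reads are rejected
  expect_true(all(kept$keep[!grepl("^junk", kept$read_id)]))
  expect_false(any(kept$keep[grepl("^junk", kept$read_id)]))
  pcs <- call_pcs(fx$polya$alignments)
  truth <- fx$polya$pcs_truth
  expect_equal(nrow(pcs), nrow(truth))
  j <- dplyr::inner_join(pcs, truth, by = c("chrom", "strand", "position"))
  expect_equal(nrow(j), nrow(truth))
  expect_equal(j$read_support.x, j$read_support.y)
  expect_equal(sum(pcs$read_support), nrow(fx$polya$alignments))
  # planted hexamers are recovered from genomic scan windows
  g <- as.character(fx$genome[["chrS"]])
  with_motif <- truth[!is.na(truth$motif), ]
  for (i in seq_len(nrow(with_motif))) {
    p <- with_motif$position[i]
    win <- substr(g, p - 50, p + 50)
    if (with_motif$strand[i] == "-") {
      win <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(win)))
    }
    hit <- scan_polya_motif(win)
    expect_equal(hit$hexamer, with_motif$motif[i])
    expect_lt(hit$offset, 0)   # planted upstream of the cleavage site
  }
})
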
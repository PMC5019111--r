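# Variant windows, the five-class decision table, calibration, PSI and
# summaries.

mk_toy_site <- function(g, boundary = 101L, strand = "+", kind = "donor") {
  iv <- if (kind == "donor") {
    if (strand == "+") c(boundary - 2L, boundary + 6L) else
      c(boundary - 6L, boundary + 2L)
  } else {
    if (strand == "+") c(boundary - 23L, boundary + 3L) else
      c(boundary - 3L, boundary + 23L)
  }
  tibble::tibble(site_id = "s1", chrom = "c1", strand = strand,
                 kind = kind, boundary = boundary, window_start = iv[1],
                 window_end = iv[2])
}

toy_genome <- function(seed = 1, len = 300) {
  withr::local_seed(seed)
  g <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "")
  gs <- Biostrings::DNAStringSet(g)
  names(gs) <- "c1"
  list(string = g, genome = gs)
}

test_that("SNPs substitute in place; joint application is order-independent", {
  tg <- toy_genome()
  site <- mk_toy_site(tg$genome)
  ref_win <- substr(tg$string, 99, 107)
  # one SNP at relative -1 (genomic boundary-1 = 100)
  b100 <- substr(tg$string, 100, 100)
  alt <- setdiff(c("A", "C", "G", "T"), b100)[1]
  v1 <- tibble::tibble(pos = 100L, ref = b100, alt = alt)
  w1 <- apply_variants_to_window(tg$genome, site, v1)
  expect_false(w1$boundary_lost)
  diffs <- which(strsplit(w1$window, "")[[1]] !=
                   strsplit(ref_win, "")[[1]])
  expect_equal(diffs, 2L)  # window position 2 is relative -1
  # two SNPs: joint result equals either sequential order
  b104 <- substr(tg$string, 104, 104)
  v2 <- tibble::tibble(pos = c(100L, 104L), ref = c(b100, b104),
                       alt = c(alt, setdiff(c("A", "C", "G", "T"),
                                            b104)[1]))
  w_joint <- apply_variants_to_window(tg$genome, site, v2)$window
  for (ord in list(1:2, 2:1)) {
    g2 <- tg$string
    for (i in ord) {
      substr(g2, v2$pos[i], v2$pos[i]) <- v2$alt[i]
    }
    gs2 <- Biostrings::DNAStringSet(g2)
    names(gs2) <- "c1"
    expect_equal(substr(g2, 99, 107), w_joint)
  }
})

test_that("indels re-extract a full-length window anchored at the boundary", {
  tg <- toy_genome(2)
  site <- mk_toy_site(tg$genome)
  # 1-nt deletion at donor +5 (genomic 105): VCF anchor at 104
  del <- tibble::tibble(pos = 104L, ref = substr(tg$string, 104, 105),
                        alt = substr(tg$string, 104, 104))
  w <- apply_variants_to_window(tg$genome, site, del)
  expect_false(w$boundary_lost)
  expect_equal(nchar(w$window), 9L)
  manual <- paste0(substr(tg$string, 99, 104), substr(tg$string, 106, 108))
  expect_equal(w$window, manual)  # last base drawn from the next intronic base
  # an insertion shifts the downstream window content instead
  ins <- tibble::tibble(pos = 104L, ref = substr(tg$string, 104, 104),
                        alt = paste0(substr(tg$string, 104, 104), "ACG"))
  wi <- apply_variants_to_window(tg$genome, site, ins)
  expect_equal(nchar(wi$window), 9L)
  expect_equal(wi$window, paste0(substr(tg$string, 99, 104), "ACG"))
  # deleting through the anchoring boundary base is flagged
  killer <- tibble::tibble(pos = 99L, ref = substr(tg$string, 99, 103),
                           alt = substr(tg$string, 99, 99))
  wk <- apply_variants_to_window(tg$genome, site, killer)
  expect_true(wk$boundary_lost)
  expect_true(is.na(wk$window))
  # reference-allele mismatches are an error
  bad <- tibble::tibble(pos = 100L, ref = "NN", alt = "A")
  expect_error(apply_variants_to_window(tg$genome, site, bad), "mismatch")
})

# a model whose scores are fully controlled: all terms zero except the
# first window position, which carries hand-assigned log-odds
dial_model <- function() {
  withr::local_seed(4)
  m <- train_site_model(rand_windows(20, 9), rand_windows(3, 60), "donor",
                        pseudocount = 1)
  m$site_lp[] <- 0
  m$bg_lp[] <- 0
  m$seen[] <- TRUE
  m$site_lp["1::A"] <- 0
  m$site_lp["1::C"] <- 2.0
  m$site_lp["1::G"] <- 1.4
  m$site_lp["1::T"] <- 1.5
  m
}

test_that("the decision table respects the strict tau boundaries", {
  m <- dial_model()
  rest <- strrep("A", 8)
  pair <- function(rb, vb) {
    classify_windows(m, paste0(rb, rest), paste0(vb, rest), tau = 1.5)
  }
  expect_equal(pair("A", "C")$effect_class, "enhancing")   # delta +2.0
  expect_equal(pair("A", "G")$effect_class, "neutral")     # delta +1.4
  expect_equal(pair("A", "T")$effect_class, "neutral")     # delta +1.5: not > tau
  expect_equal(pair("C", "A")$effect_class, "weakening")   # delta -2.0
  # acceptor-style threshold 1.0 flips the +/-1.2 and +/-1.4 calls
  expect_equal(classify_windows(m, paste0("A", rest), paste0("G", rest),
                                tau = 1.0)$effect_class, "enhancing")
  # functionality flags dominate the score comparison
  m$seen["1::T"] <- FALSE
  expect_equal(pair("A", "T")$effect_class, "disrupting")
  expect_equal(pair("T", "A")$effect_class, "activating")
  m$seen["1::G"] <- FALSE
  expect_equal(pair("T", "G")$effect_class, "neutral_nonfunctional")
})

test_that("allele swap maps classes to their duals over randomized windows", {
  fx <- std_fixture()
  withr::local_seed(77)
  n <- 1200
  ref <- rand_windows(n, 9)
  var <- ref
  for (i in seq_len(n)) {
    p <- sample(9, 1)
    substr(var[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(ref[i], p, p)), 1)
  }
  fwd <- classify_windows(fx$donor_model, ref, var)
  rev <- classify_windows(fx$donor_model, var, ref)
  dual <- c(enhancing = "weakening", weakening = "enhancing",
            activating = "disrupting", disrupting = "activating",
            neutral = "neutral",
            neutral_nonfunctional = "neutral_nonfunctional")
  expect_equal(rev$effect_class, unname(dual[fwd$effect_class]))
  # totality: every pair gets exactly one known class
  expect_true(all(fwd$effect_class %in% names(dual)))
})

test_that("genome-level allele swap gives dual classes on planted variants", {
  fx <- std_fixture()
  truth <- fixture_truth(fx)
  snps <- truth[nchar(truth$ref) == 1 & nchar(truth$alt) == 1, ]
  snps <- snps[seq(1, nrow(snps), by = 10), ]   # a spot-check subset
  dual <- c(enhancing = "weakening", weakening = "enhancing",
            activating = "disrupting", disrupting = "activating",
            neutral = "neutral",
            neutral_nonfunctional = "neutral_nonfunctional")
  g <- as.character(fx$genome[["chrS"]])
  for (i in seq_len(nrow(snps))) {
    v <- snps[i, ]
    cls <- classify_variants(fx$genome, fx$sites, v, fx$donor_model,
                             fx$acceptor_model)
    g2 <- g
    substr(g2, v$pos, v$pos) <- v$alt
    gs2 <- Biostrings::DNAStringSet(g2)
    names(gs2) <- "chrS"
    sites2 <- extract_window(gs2, fx$annotation$sites)
    v2 <- v
    v2$ref <- v$alt; v2$alt <- v$ref
    cls2 <- classify_variants(gs2, sites2, v2, fx$donor_model,
                              fx$acceptor_model)
    expect_equal(cls2$effect_class, unname(dual[cls$effect_class]))
  }
})

test_that("planted variant classes are recovered at the default thresholds", {
  fx <- std_fixture()
  cl <- classify_variants(fx$genome, fx$sites, fx$variants,
                          fx$donor_model, fx$acceptor_model,
                          fx$donor_pwm, fx$acceptor_pwm)
  j <- dplyr::inner_join(cl, fixture_truth(fx),
                         by = c("site_id", "variant_id"))
  expect_equal(nrow(j), nrow(fx$variants))
  acc <- j |>
    dplyr::group_by(true_class) |>
    dplyr::summarise(acc = mean(effect_class == true_class))
  rates <- setNames(acc$acc, acc$true_class)
  expect_gte(rates[["disrupting"]], 0.95)
  expect_gte(rates[["activating"]], 0.95)
  expect_gte(rates[["weakening"]], 0.80)
  expect_gte(rates[["enhancing"]], 0.80)
  # PWM deltas computed in parallel are finite for scorable pairs
  expect_true(all(is.finite(j$delta_pwm[!j$boundary_lost])))
})

test_that("PSI combines flanking inclusion junctions with a coverage floor", {
  expect_equal(compute_psi(15, 15, 30), 0.5)
  expect_equal(compute_psi(30, 30, 0), 1.0)
  expect_equal(compute_psi(20, 10, 15), 2 / 3)  # combined inclusion 30 vs 15
  expect_true(is.na(compute_psi(2, 2, 2)))      # total 6 < 10
  expect_error(compute_psi(-1, 5, 5), "non-negative")
})

test_that("calibration recovers the scaled threshold and reports residuals", {
  withr::local_seed(19)
  delta_pwm <- runif(4000, -15, 15)
  delta_hmm <- 0.25 * delta_pwm   # perfect concordance at tau = 0.25 * 6
  cal <- calibrate_threshold(delta_hmm, delta_pwm, "donor",
                             tau_grid = seq(0, 2.5, by = 0.1))
  expect_equal(cal$best_tau, 1.5, tolerance = 1e-9)
  best <- tidy(cal)[tidy(cal)$tau == cal$best_tau, ]
  expect_true(all(c(best$res_weakening, best$res_neutral,
                    best$res_enhancing) > 0))
  # identical inputs give the identical argmax
  cal2 <- calibrate_threshold(delta_hmm, delta_pwm, "donor",
                              tau_grid = seq(0, 2.5, by = 0.1))
  expect_identical(glance(cal2)$best_tau, glance(cal)$best_tau)
  # independent classifications show no diagonal enrichment
  withr::local_seed(23)
  ih <- rnorm(10000, 0, 2)
  ip <- rnorm(10000, 0, 8)
  ical <- calibrate_threshold(ih, ip, "donor", tau_grid = 1.0)
  cells <- tidy(ical)
  expect_true(all(abs(c(cells$res_weakening, cells$res_neutral,
                        cells$res_enhancing)) < 3))
  # degenerate single-class PWM axis errors
  expect_error(calibrate_threshold(ih, rep(0, 10000), "donor"),
               "degenerate")
})

test_that("DAF summaries detect planted shifts and skip empty classes", {
  cls <- tibble::tibble(
    effect_class = rep(c("neutral", "disrupting"), each = 500),
    daf = c(runif(500), runif(500, 0, 0.3)))
  withr::local_seed(31)
  s <- summarize_class_daf(cls)
  expect_lt(s$tests$p_value[s$tests$effect_class == "disrupting"], 1e-6)
  # identical distributions: KS statistic 0
  same <- tibble::tibble(effect_class = rep(c("neutral", "enhancing"),
                                            each = 100),
                         daf = rep(seq(0.01, 1, length.out = 100), 2))
  s2 <- summarize_class_daf(same)
  expect_equal(s2$tests$ks_stat[s2$tests$effect_class == "enhancing"], 0)
  # a singleton class is skipped with a warning, not an error
  one <- dplyr::bind_rows(cls, tibble::tibble(effect_class = "activating",
                                              daf = 0.5))
  expect_warning(s3 <- summarize_class_daf(one), "activating")
  expect_false("activating" %in% s3$tests$effect_class)
})

test_that("variant burden tabulates per-site counts and indel repression", {
  fx <- std_fixture()
  b <- summarize_variant_burden(fx$sites, fx$variants)
  expect_equal(sum(b$site_counts$n_sites * b$site_counts$n_variants),
               nrow(fx$variants))
  expect_equal(b$indel$n_window_variants, nrow(fx$variants))
  # zero variants: empty table, no error
  b0 <- summarize_variant_burden(fx$sites,
                                 tibble::tibble(chrom = character(),
                                                pos = integer(),
                                                ref = character(),
                                                alt = character()))
  expect_equal(nrow(b0$site_counts), 0)
})
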
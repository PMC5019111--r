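# Independent brute-force evaluators and shared fixtures.  The oracles
# recount probabilities directly from the training sequences with plain
# loops; they share no code with the package's scoring path.

# per-position log-odds terms of an inhomogeneous Markov chain, computed
# from scratch
oracle_markov_terms <- function(site_windows, bg_seqs, window, order = 2,
                                pseudocount = 0, floor = log(1e-12)) {
  L <- nchar(window)
  terms <- numeric(L)
  seen <- logical(L)
  for (i in seq_len(L)) {
    k <- min(i - 1, order)
    ctx <- substr(window, i - k, i - 1)
    b <- substr(window, i, i)
    in_ctx <- substr(site_windows, i - k, i - 1) == ctx
    n_ctx <- sum(in_ctx)
    n_b <- sum(in_ctx & substr(site_windows, i, i) == b)
    seen[i] <- n_b > 0
    denom <- n_ctx + 4 * pseudocount
    ps <- if (denom > 0) (n_b + pseudocount) / denom else 0
    # pooled background occurrences of (ctx, base)
    nb_ctx <- 0; nb_b <- 0
    for (s in bg_seqs) {
      n <- nchar(s)
      if (n < k + 1) next
      for (j in seq_len(n - k)) {
        c2 <- if (k == 0) "" else substr(s, j, j + k - 1)
        if (c2 == ctx) {
          nb_ctx <- nb_ctx + 1
          if (substr(s, j + k, j + k) == b) nb_b <- nb_b + 1
        }
      }
    }
    denb <- nb_ctx + 4 * pseudocount
    pb <- if (denb > 0) (nb_b + pseudocount) / denb else 0
    terms[i] <- max(log(ps), floor) - max(log(pb), floor)
  }
  list(terms = terms, functional = all(seen))
}

oracle_markov_score <- function(site_windows, bg_seqs, window, ...) {
  o <- oracle_markov_terms(site_windows, bg_seqs, window, ...)
  list(score = sum(o$terms), functional = o$functional)
}

# brute-force PWM score from raw counts
oracle_pwm_score <- function(site_windows, window, bg = rep(0.25, 4),
                             pseudocount = 0.5) {
  names(bg) <- c("A", "C", "G", "T")
  s <- 0
  for (i in seq_len(nchar(window))) {
    col <- substr(site_windows, i, i)
    cnt <- sum(col == substr(window, i, i)) + pseudocount
    tot <- length(site_windows) + 4 * pseudocount
    s <- s + log((cnt / tot) / bg[[substr(window, i, i)]])
  }
  s
}

rand_windows <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
           collapse = "")
  }, character(1))
}

# the standard fixture and its trained models, built once per test run
std_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- sim_fixture(fixture_spec(seed = 1))
      fx$donor_model <- train_site_model(fx$train_donor, fx$background,
                                         "donor")
      fx$acceptor_model <- train_site_model(fx$train_acceptor,
                                            fx$background, "acceptor")
      fx$donor_pwm <- build_pwm(fx$train_donor, site_kind = "donor")
      fx$acceptor_pwm <- build_pwm(fx$train_acceptor,
                                   site_kind = "acceptor")
      cache <<- fx
    }
    cache
  }
})

fixture_truth <- function(fx) {
  dplyr::mutate(fx$variants,
                variant_id = paste(chrom, pos, ref, alt, sep = ":"))
}

# a minimal hand-checkable gene set: one plus- and one minus-strand gene
toy_transcripts <- function() {
  dplyr::bind_rows(
    tibble::tibble(gene_id = "gA", transcript_id = "gA.t1", chrom = "c1",
                   strand = "+", exon_start = c(1L, 201L, 401L),
                   exon_end = c(100L, 300L, 500L)),
    tibble::tibble(gene_id = "gB", transcript_id = "gB.t1", chrom = "c1",
                   strand = "-", exon_start = c(601L, 801L),
                   exon_end = c(700L, 900L))
  )
}

# test-side window sampler from a 4 x L probability matrix
sample_windows_for_test <- function(probs, n) {
  cols <- lapply(seq_len(ncol(probs)), function(i) {
    sample(rownames(probs), n, replace = TRUE, prob = probs[, i])
  })
  do.call(paste0, cols)
}

# test-side donor window interval (relative [-2..+7], no zero)
window_interval_for_test <- function(boundary, strand) {
  start <- ifelse(strand == "+", boundary - 2L, boundary - 6L)
  tibble::tibble(start = start, end = start + 8L)
}
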
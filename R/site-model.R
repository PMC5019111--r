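# Positional Markov models of splice-site composition and log-odds scoring.

all_kmers <- function(k) {
  if (k == 0) return("")
  do.call(paste0, rev(expand.grid(rep(list(DNA_BASES), k),
                                  stringsAsFactors = FALSE)))
}

# context of position i inside a window, up to `order` preceding bases
context_at <- function(windows, i, order) {
  if (i == 1) rep("", length(windows)) else
    str_sub(windows, max(1L, i - order), i - 1L)
}

count_transitions <- function(seqs, k) {
  # pooled (k-mer context, next base) counts across all positions of seqs
  ctxs <- all_kmers(k)
  m <- matrix(0L, nrow = length(ctxs), ncol = 4,
              dimnames = list(ctxs, DNA_BASES))
  for (s in seqs) {
    n <- nchar(s)
    if (n < k + 1) next
    starts <- seq_len(n - k)
    ctx <- if (k == 0) rep("", length(starts)) else
      substring(s, starts, starts + k - 1L)
    nxt <- substring(s, starts + k, starts + k)
    keep <- !grepl("[^ACGT]", ctx) & nxt %in% DNA_BASES
    t0 <- table(factor(ctx[keep], levels = ctxs),
                factor(nxt[keep], levels = DNA_BASES))
    m <- m + unclass(t0)
  }
  m
}

smooth_logprob <- function(counts, pseudocount) {
  # rows: contexts, cols: bases; conditional probabilities with additive
  # smoothing; a context with zero total and zero pseudocount keeps
  # probability 0 (log -Inf, floored at scoring time)
  tot <- rowSums(counts) + 4 * pseudocount
  p <- (counts + pseudocount) / ifelse(tot > 0, tot, 1)
  log(p)
}

#' Train a positional Markov splice-site model
#'
#' Estimates an inhomogeneous Markov chain of the given order over a
#' fixed-length splice-site window (9 nt for donors, 27 nt for acceptors),
#' together with a position-independent background chain of the same order
#' estimated from arbitrary-length background sequences.  Scoring a window
#' with [score_site()] sums, over window positions, the log-ratio of the
#' site-model probability to the background probability of the observed base
#' given its preceding context (positions with fewer preceding bases than
#' `order` condition on the shorter available context).
#'
#' The model also records which (position, context, base) triples were
#' actually observed in the site training windows (before any pseudocount
#' smoothing).  A window touching an unobserved triple is deemed
#' non-functional: its sequence was never seen among real sites, so it is
#' not assumed to represent a functional splice site.
#'
#' @param site_windows Character vector of training windows, all of the
#'   window length configured for `site_kind`.
#' @param background_sequences Character vector of background DNA (any
#'   lengths); transitions are pooled position-independently.
#' @param site_kind `"donor"` (window 9) or `"acceptor"` (window 27).
#' @param order Markov order (default 2).
#' @param pseudocount Additive smoothing count (default 0, which preserves
#'   exact absent-from-training semantics for functionality calls).
#' @param strict If `TRUE`, non-ACGT symbols in training data are an error.
#' @return An object of class `markov_site_model`.
#' @seealso [score_site()], [score_delta()], [write_site_model()]
#' @export
#' @examples
#' m <- train_site_model(c("AGGTAAGTA", "AGGTGAGTA"), c("ACGTACGTACGT"),
#'                       site_kind = "donor")
#' score_site(m, "AGGTAAGTA")
train_site_model <- function(site_windows, background_sequences,
                             site_kind = c("donor", "acceptor"),
                             order = 2, pseudocount = 0, strict = TRUE) {
  site_kind <- match.arg(site_kind)
  L <- site_window_length(site_kind)
  if (length(site_windows) == 0) abort("empty site training set")
  if (length(background_sequences) == 0) abort("empty background training set")
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  site_windows <- toupper(site_windows)
  background_sequences <- toupper(background_sequences)
  if (any(nchar(site_windows) != L)) {
    abort(sprintf("all %s windows must have length %d", site_kind, L))
  }
  check_dna(site_windows, strict, "site_windows")
  check_dna(background_sequences, strict, "background_sequences")

  # background: pooled conditionals for every context length 0..order
  bg_lp <- numeric(0)
  for (k in 0:order) {
    cnt <- count_transitions(background_sequences, k)
    lp <- smooth_logprob(cnt, pseudocount)
    bg_lp <- c(bg_lp, setNames(as.vector(t(lp)),
                               paste(rep(rownames(lp), each = 4),
                                     DNA_BASES, sep = ":")))
  }

  # site: per-position conditionals over the full context grid
  tabs <- vector("list", L)
  for (i in seq_len(L)) {
    k <- min(i - 1L, order)
    ctxs <- all_kmers(k)
    ctx <- context_at(site_windows, i, order)
    base <- str_sub(site_windows, i, i)
    keep <- !grepl("[^ACGT]", ctx) & base %in% DNA_BASES
    cnt <- unclass(table(factor(ctx[keep], levels = ctxs),
                         factor(base[keep], levels = DNA_BASES)))
    lp <- smooth_logprob(cnt, pseudocount)
    tabs[[i]] <- tibble(
      position = i,
      context = rep(rownames(cnt), each = 4),
      base = rep(DNA_BASES, times = nrow(cnt)),
      site_count = as.vector(t(cnt)),
      site_logprob = as.vector(t(lp))
    )
  }
  tab <- bind_rows(tabs)
  tab$background_logprob <- unname(bg_lp[paste(tab$context, tab$base, sep = ":")])
  tab$seen <- tab$site_count > 0

  key <- paste(tab$position, tab$context, tab$base, sep = ":")
  structure(
    list(
      site_kind = site_kind, window_length = L, order = order,
      pseudocount = pseudocount, n_train = length(site_windows),
      table = tab,
      site_lp = setNames(tab$site_logprob, key),
      bg_lp = setNames(tab$background_logprob, key),
      seen = setNames(tab$seen, key)
    ),
    class = "markov_site_model"
  )
}

window_keys <- function(model, windows) {
  L <- model$window_length
  lapply(seq_len(L), function(i) {
    paste(i, context_at(windows, i, model$order),
          str_sub(windows, i, i), sep = ":")
  })
}

#' Score windows under a positional Markov site model
#'
#' Computes the log-odds splicing score of each window: the sum over window
#' positions of `log P_site(base | context) - log P_bg(base | context)`.
#' A window is functional only when every scored (position, context, base)
#' triple occurred in the site training set; otherwise `functional` is
#' `FALSE` (the score is still reported, with zero-probability terms clamped
#' at `floor`).
#'
#' @param model A `markov_site_model`.
#' @param windows Character vector of windows of the model's window length.
#' @param floor Lower clamp for per-term log-probabilities, so that triples
#'   with probability zero (pseudocount 0) yield a finite score.  Default
#'   `log(1e-12)`.
#' @param base Logarithm base of the reported score; default `exp(1)`
#'   (natural log units).  Use `2` for bits.
#' @param strict If `TRUE`, non-ACGT windows are an error; if `FALSE` they
#'   are returned unscorable (`scorable = FALSE`, score `NA`).
#' @return A tibble with one row per window: `window`, `score`,
#'   `functional`, `scorable`.
#' @export
score_site <- function(model, windows, floor = log(1e-12), base = exp(1),
                       strict = TRUE) {
  stopifnot(inherits(model, "markov_site_model"))
  windows <- toupper(windows)
  if (any(nchar(windows) != model$window_length)) {
    abort(sprintf("windows must have length %d for %s sites",
                  model$window_length, model$site_kind))
  }
  bad <- check_dna(windows, strict, "windows")
  n <- length(windows)
  score <- numeric(n)
  func <- rep(TRUE, n)
  for (keys in window_keys(model, windows)) {
    s_lp <- pmax(model$site_lp[keys], floor)
    b_lp <- pmax(model$bg_lp[keys], floor)
    score <- score + (s_lp - b_lp)
    func <- func & model$seen[keys]
  }
  score <- unname(score) / log(base)
  func <- unname(func)
  score[bad] <- NA_real_
  func[bad] <- NA
  tibble(window = windows, score = score, functional = func,
         scorable = !bad)
}

#' Score difference between variant and reference windows
#'
#' `score(var_window) - score(ref_window)` under the Markov site model
#' (the variant-minus-reference convention, so negative deltas suggest
#' weakening and positive deltas enhancing changes).
#'
#' @inheritParams score_site
#' @param ref_window,var_window Character vectors of equal length (recycled
#'   length-1 allowed).
#' @return Numeric vector of score differences.
#' @export
score_delta <- function(model, ref_window, var_window, floor = log(1e-12),
                        base = exp(1), strict = TRUE) {
  score_site(model, var_window, floor, base, strict)$score -
    score_site(model, ref_window, floor, base, strict)$score
}

#' @export
print.markov_site_model <- function(x, ...) {
  cat(sprintf(
    "<markov_site_model> %s, window %d nt, order %d, pseudocount %g, %d training windows\n",
    x$site_kind, x$window_length, x$order, x$pseudocount, x$n_train))
  invisible(x)
}

#' @method tidy markov_site_model
#' @export
tidy.markov_site_model <- function(x, ...) {
  as_tibble(x$table)
}

#' @method glance markov_site_model
#' @export
glance.markov_site_model <- function(x, ...) {
  tibble(site_kind = x$site_kind, window_length = x$window_length,
         order = x$order, pseudocount = x$pseudocount, n_train = x$n_train,
         n_seen = sum(x$table$seen))
}

#' Write / read a site model as a plain-text TSV matrix
#'
#' One row per (position, context, base) with site and background
#' log-probabilities and a seen flag; model metadata travels in `#`-prefixed
#' header lines.
#'
#' @param model A `markov_site_model`.
#' @param path File path.
#' @return `write_site_model()` returns `path` invisibly;
#'   `read_site_model()` returns a `markov_site_model`.
#' @export
write_site_model <- function(model, path) {
  stopifnot(inherits(model, "markov_site_model"))
  hdr <- sprintf("# splicevar site model v1\n# site_kind=%s window_length=%d order=%d pseudocount=%g n_train=%d",
                 model$site_kind, model$window_length, model$order,
                 model$pseudocount, model$n_train)
  tab <- model$table
  out <- tibble(site_kind = model$site_kind, position = tab$position,
                context = tab$context, base = tab$base,
                site_logprob = tab$site_logprob,
                background_logprob = tab$background_logprob,
                seen_flag = as.integer(tab$seen),
                site_count = tab$site_count)
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(out, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' @rdname write_site_model
#' @export
read_site_model <- function(path) {
  hdr <- readLines(path, n = 2)
  meta <- hdr[grepl("site_kind=", hdr)]
  kv <- regmatches(meta, gregexpr("[a-z_]+=[^ ]+", meta))[[1]]
  vals <- setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           context = readr::col_character(),
                           base = readr::col_character()))
  tab$context[is.na(tab$context)] <- ""
  tab2 <- tibble(position = tab$position, context = tab$context,
                 base = tab$base, site_count = tab$site_count,
                 site_logprob = tab$site_logprob,
                 background_logprob = tab$background_logprob,
                 seen = tab$seen_flag > 0)
  key <- paste(tab2$position, tab2$context, tab2$base, sep = ":")
  structure(
    list(site_kind = vals[["site_kind"]],
         window_length = as.integer(vals[["window_length"]]),
         order = as.integer(vals[["order"]]),
         pseudocount = as.numeric(vals[["pseudocount"]]),
         n_train = as.integer(vals[["n_train"]]),
         table = tab2,
         site_lp = setNames(tab2$site_logprob, key),
         bg_lp = setNames(tab2$background_logprob, key),
         seen = setNames(tab2$seen, key)),
    class = "markov_site_model"
  )
}
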
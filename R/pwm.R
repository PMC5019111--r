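# Position weight matrices: the independent per-position log-odds scheme
# used to calibrate the Markov-model classification thresholds.

#' Build a position weight matrix from site windows
#'
#' Per-position log-odds of base frequencies in the site windows against a
#' position-independent background composition.  Unlike the Markov site
#' model, PWM scores are strictly local: a single-base substitution changes
#' the score only through the affected position.
#'
#' @inheritParams train_site_model
#' @param background_composition Named numeric vector of A/C/G/T background
#'   frequencies (normalized internally).  Default uniform.
#' @param pseudocount Additive smoothing count per cell (default 0.5 so a
#'   base absent from training keeps a finite log-odds).
#' @param neutral_band Half-width of the score-difference band treated as
#'   neutral when classifying variants with [pwm_class()] (default 6, the
#'   location of the minima separating the trimodal PWM score-difference
#'   distribution).
#' @return An object of class `site_pwm`.
#' @export
build_pwm <- function(site_windows, background_composition = NULL,
                      site_kind = c("donor", "acceptor"),
                      pseudocount = 0.5, neutral_band = 6, strict = TRUE) {
  site_kind <- match.arg(site_kind)
  L <- site_window_length(site_kind)
  if (length(site_windows) == 0) abort("empty site training set")
  if (neutral_band < 0) abort("neutral_band must be non-negative")
  site_windows <- toupper(site_windows)
  if (any(nchar(site_windows) != L)) {
    abort(sprintf("all %s windows must have length %d", site_kind, L))
  }
  check_dna(site_windows, strict, "site_windows")
  if (is.null(background_composition)) {
    background_composition <- setNames(rep(0.25, 4), DNA_BASES)
  }
  bg <- background_composition[DNA_BASES]
  if (anyNA(bg)) abort("background_composition must name A, C, G, T")
  bg <- bg / sum(bg)

  counts <- vapply(seq_len(L), function(i) {
    b <- str_sub(site_windows, i, i)
    as.vector(table(factor(b[b %in% DNA_BASES], levels = DNA_BASES)))
  }, numeric(4))
  rownames(counts) <- DNA_BASES
  freq <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  logodds <- log(freq / bg)

  structure(
    list(site_kind = site_kind, length = L, logodds = logodds,
         background = bg, pseudocount = pseudocount,
         neutral_band = neutral_band, n_train = length(site_windows)),
    class = "site_pwm"
  )
}

#' Score windows under a PWM
#'
#' Sum of per-position log-odds entries for the observed bases.
#'
#' @param pwm A `site_pwm`.
#' @inheritParams score_site
#' @return Numeric vector of PWM scores (`NA` for unscorable windows in
#'   lenient mode).
#' @export
score_pwm <- function(pwm, windows, strict = TRUE) {
  stopifnot(inherits(pwm, "site_pwm"))
  windows <- toupper(windows)
  if (any(nchar(windows) != pwm$length)) {
    abort(sprintf("windows must have length %d", pwm$length))
  }
  bad <- check_dna(windows, strict, "windows")
  s <- numeric(length(windows))
  for (i in seq_len(pwm$length)) {
    b <- str_sub(windows, i, i)
    idx <- match(b, DNA_BASES)
    s <- s + pwm$logodds[cbind(idx, i)]
  }
  s[bad] <- NA_real_
  s
}

#' Three-way PWM score-difference class
#'
#' Classifies PWM score differences into weakening / neutral / enhancing
#' using the neutral band: differences in `[-band, +band]` are neutral.
#'
#' @param delta_pwm Numeric vector of variant-minus-reference PWM scores.
#' @param band Half-width of the neutral band; defaults to the PWM's
#'   `neutral_band` when a `site_pwm` is given instead of a number.
#' @return Factor with levels weakening, neutral, enhancing.
#' @export
pwm_class <- function(delta_pwm, band = 6) {
  if (inherits(band, "site_pwm")) band <- band$neutral_band
  cls <- ifelse(delta_pwm > band, "enhancing",
                ifelse(delta_pwm < -band, "weakening", "neutral"))
  factor(cls, levels = c("weakening", "neutral", "enhancing"))
}

#' @export
print.site_pwm <- function(x, ...) {
  cat(sprintf("<site_pwm> %s, %d positions, neutral band +/-%g, %d training windows\n",
              x$site_kind, x$length, x$neutral_band, x$n_train))
  invisible(x)
}

#' @method tidy site_pwm
#' @export
tidy.site_pwm <- function(x, ...) {
  tibble(position = rep(seq_len(x$length), each = 4),
         base = rep(DNA_BASES, times = x$length),
         logodds = as.vector(x$logodds))
}

#' @method glance site_pwm
#' @export
glance.site_pwm <- function(x, ...) {
  tibble(site_kind = x$site_kind, length = x$length,
         neutral_band = x$neutral_band, pseudocount = x$pseudocount,
         n_train = x$n_train)
}
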
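# Threshold calibration against the PWM scheme, and downstream summaries
# (PSI, DAF distributions, variant burden).

hmm_class <- function(delta, tau) {
  factor(ifelse(delta > tau, "enhancing",
                ifelse(delta < -tau, "weakening", "neutral")),
         levels = c("weakening", "neutral", "enhancing"))
}

#' Calibrate the neutral threshold against PWM classes
#'
#' Sweeps the neutral threshold tau over a grid; at each tau, Markov score
#' differences are classified into weakening / neutral / enhancing and
#' cross-tabulated against the fixed PWM classification (neutral band
#' `+/-pwm_band`).  Agreement is measured by the chi-square statistic of
#' the 3x3 contingency table; enrichment of concordant calls by its
#' standardized residuals.  The returned best tau maximizes the statistic
#' (ties broken towards the smallest tau).
#'
#' @param delta_hmm,delta_pwm Paired numeric score differences.
#' @param site_kind Label stored with the result.
#' @param tau_grid Thresholds to sweep (default `seq(0, 2.5, by = 0.1)`).
#' @param pwm_band PWM neutral half-band (default 6).
#' @return An object of class `splice_calibration`: tibble of per-tau cells
#'   via [generics::tidy()], the best tau via [generics::glance()], raw
#'   contingency tables in `$tables`.
#' @export
calibrate_threshold <- function(delta_hmm, delta_pwm,
                                site_kind = c("donor", "acceptor"),
                                tau_grid = seq(0, 2.5, by = 0.1),
                                pwm_band = 6) {
  site_kind <- match.arg(site_kind)
  keep <- !is.na(delta_hmm) & !is.na(delta_pwm)
  delta_hmm <- delta_hmm[keep]; delta_pwm <- delta_pwm[keep]
  pwm_cls <- pwm_class(delta_pwm, pwm_band)
  if (length(unique(pwm_cls)) < 2) {
    abort("degenerate PWM classification: fewer than 2 classes present")
  }
  cells <- vector("list", length(tau_grid))
  tables <- vector("list", length(tau_grid))
  for (i in seq_along(tau_grid)) {
    tau <- tau_grid[i]
    hc <- hmm_class(delta_hmm, tau)
    tab <- table(hmm = hc, pwm = pwm_cls)
    tables[[i]] <- tab
    tab2 <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab2) < 2 || ncol(tab2) < 2) {
      cells[[i]] <- tibble(tau = tau, chisq_stat = NA_real_,
                           p_value = NA_real_,
                           res_weakening = NA_real_, res_neutral = NA_real_,
                           res_enhancing = NA_real_)
      next
    }
    ct <- suppressWarnings(chisq.test(tab2, correct = FALSE))
    stdres <- ct$stdres
    diag_res <- vapply(c("weakening", "neutral", "enhancing"), function(k) {
      if (k %in% rownames(stdres) && k %in% colnames(stdres)) {
        stdres[k, k]
      } else NA_real_
    }, numeric(1))
    cells[[i]] <- tibble(tau = tau, chisq_stat = unname(ct$statistic),
                         p_value = unname(ct$p.value),
                         res_weakening = diag_res[["weakening"]],
                         res_neutral = diag_res[["neutral"]],
                         res_enhancing = diag_res[["enhancing"]])
  }
  cells <- bind_rows(cells)
  ok <- which(!is.na(cells$chisq_stat))
  if (length(ok) == 0) abort("chi-square undefined on the whole grid")
  best <- ok[which.max(cells$chisq_stat[ok])]  # which.max: first = smallest tau
  structure(
    list(site_kind = site_kind, cells = cells, tables = tables,
         pwm_band = pwm_band, best_tau = cells$tau[best],
         n = length(delta_hmm)),
    class = "splice_calibration"
  )
}

#' @export
print.splice_calibration <- function(x, ...) {
  cat(sprintf(
    "<splice_calibration> %s: best tau = %g (chi-square %.1f over %d pairs, PWM band +/-%g)\n",
    x$site_kind, x$best_tau,
    x$cells$chisq_stat[x$cells$tau == x$best_tau], x$n, x$pwm_band))
  invisible(x)
}

#' @method tidy splice_calibration
#' @export
tidy.splice_calibration <- function(x, ...) x$cells

#' @method glance splice_calibration
#' @export
glance.splice_calibration <- function(x, ...) {
  best <- x$cells[x$cells$tau == x$best_tau, ]
  tibble(site_kind = x$site_kind, best_tau = x$best_tau,
         chisq_stat = best$chisq_stat, n = x$n, pwm_band = x$pwm_band)
}

#' Percent spliced-in from junction read counts
#'
#' PSI of an alternatively included exon:
#' `PSI = inclusion / (inclusion + exclusion)`, where the inclusion count
#' combines the two flanking inclusion junctions (so balanced evidence of
#' 15 reads per inclusion flank against 30 skipping reads gives 0.5).
#' PSI is `NA` when the total junction coverage is below `min_coverage`.
#'
#' @param inclusion_left,inclusion_right Reads supporting the two
#'   inclusion junctions flanking the exon.
#' @param exclusion Reads supporting the skipping junction.
#' @param min_coverage Minimum total coverage for a defined PSI
#'   (default 10).
#' @return Numeric vector of PSI values in `[0, 1]` (or `NA`).
#' @export
#' @examples
#' compute_psi(15, 15, 30)  # 0.5
compute_psi <- function(inclusion_left, inclusion_right, exclusion,
                        min_coverage = 10) {
  if (any(c(inclusion_left, inclusion_right, exclusion) < 0, na.rm = TRUE)) {
    abort("junction read counts must be non-negative")
  }
  inc <- inclusion_left + inclusion_right
  total <- inc + exclusion
  ifelse(total >= min_coverage, inc / total, NA_real_)
}

#' Derived-allele-frequency distributions by effect class
#'
#' Bins DAFs per effect class and tests each class against the neutral
#' class with a two-sample Kolmogorov-Smirnov test.
#'
#' @param classifications Tibble with `effect_class` and `daf` columns
#'   (e.g. from [classify_variants()]).
#' @param breaks Histogram break points on `[0, 1]`.
#' @return List with `bins` (class, bin, n, prop) and `tests` (class, n,
#'   ks_stat, p_value vs neutral).  Classes with fewer than 2 observations
#'   are skipped with a warning.
#' @export
summarize_class_daf <- function(classifications,
                                breaks = seq(0, 1, by = 0.1)) {
  df <- classifications |> filter(!is.na(.data$daf))
  neutral <- df$daf[df$effect_class == "neutral"]
  if (length(neutral) < 2) abort("need >= 2 neutral DAF observations")
  bins <- df |>
    mutate(bin = cut(.data$daf, breaks = breaks, include.lowest = TRUE)) |>
    count(.data$effect_class, .data$bin, name = "n") |>
    group_by(.data$effect_class) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup()
  classes <- setdiff(unique(df$effect_class), "neutral")
  tests <- lapply(classes, function(cl) {
    x <- df$daf[df$effect_class == cl]
    if (length(x) < 2) {
      warn(sprintf("class '%s' has <2 DAF observations; skipped", cl))
      return(NULL)
    }
    kt <- suppressWarnings(ks.test(x, neutral))
    tibble(effect_class = cl, n = length(x),
           ks_stat = unname(kt$statistic), p_value = kt$p.value)
  })
  list(bins = bins, tests = bind_rows(tests))
}

#' Variant burden of splice sites
#'
#' Tabulates how many sites carry 1..k overlapping variants and compares
#' the indel fraction inside windows with the genome-wide indel fraction
#' (two-sample proportion test).
#'
#' @param sites Site tibble.
#' @param variants All variants (`chrom`, `pos`, `ref`, `alt`).
#' @return List with `site_counts` (n_variants, n_sites), `indel`
#'   (fractions in windows and overall with the proportion-test p-value).
#' @export
summarize_variant_burden <- function(sites, variants) {
  sv <- site_variants(sites, variants)
  site_counts <- sv |>
    distinct(.data$site_id, .data$variant_id) |>
    count(.data$site_id, name = "n_variants") |>
    count(.data$n_variants, name = "n_sites")
  v_all <- variants |> mutate(type = variant_type(.data$ref, .data$alt))
  in_win <- sv |> distinct(.data$variant_id, .data$type)
  n_win <- nrow(in_win); n_all <- nrow(v_all)
  indel_win <- sum(in_win$type != "SNP")
  indel_all <- sum(v_all$type != "SNP")
  test <- if (n_win > 0 && n_all > 0 && indel_win + indel_all > 0) {
    suppressWarnings(prop.test(c(indel_win, indel_all), c(n_win, n_all)))
  } else NULL
  list(
    site_counts = site_counts,
    indel = tibble(
      n_window_variants = n_win,
      indel_frac_window = if (n_win > 0) indel_win / n_win else NA_real_,
      n_all_variants = n_all,
      indel_frac_all = if (n_all > 0) indel_all / n_all else NA_real_,
      p_value = if (!is.null(test)) test$p.value else NA_real_
    )
  )
}
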
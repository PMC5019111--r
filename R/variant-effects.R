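# Variant effect classification on splice-site windows: five classes
# (disrupting / weakening / neutral / enhancing / activating) from Markov
# score differences and training-set membership, calibrated against PWM
# classes.

#' Classification thresholds
#'
#' Container for the neutral-band thresholds: `tau_donor` and
#' `tau_acceptor` bound the Markov score differences still called neutral
#' (defaults 1.5 and 1.0, the values at which agreement with the
#' independent PWM classification peaks), and `pwm_band` is the PWM
#' neutral half-band (default 6).
#'
#' @param tau_donor,tau_acceptor,pwm_band Positive reals.
#' @return A named list of class `class_thresholds`.
#' @export
class_thresholds <- function(tau_donor = 1.5, tau_acceptor = 1.0,
                             pwm_band = 6) {
  if (tau_donor <= 0 || tau_acceptor <= 0 || pwm_band <= 0) {
    abort("all thresholds must be positive")
  }
  structure(list(tau_donor = tau_donor, tau_acceptor = tau_acceptor,
                 pwm_band = pwm_band), class = "class_thresholds")
}

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Intersect variants with splice-site scoring windows
#'
#' @param sites Site tibble (from [derive_introns()]; needs `site_id`,
#'   `chrom`, `strand`, `kind`, `boundary`, `window_start`, `window_end`).
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`, optional
#'   `daf`).
#' @return One row per (site, variant) pair whose reference span overlaps
#'   the window, with `variant_id`, `type` and the relative window position
#'   `rel_pos` of the variant start (NA for starts outside the window, e.g.
#'   deletions reaching in from upstream).
#' @export
site_variants <- function(sites, variants) {
  v <- variants |>
    select(dplyr::any_of(c("chrom", "pos", "ref", "alt", "daf", "qual",
                           "genotypes"))) |>
    mutate(variant_id = variant_id(.data$chrom, .data$pos, .data$ref,
                                   .data$alt),
           type = variant_type(.data$ref, .data$alt),
           var_end = .data$pos + nchar(.data$ref) - 1L)
  out <- sites |>
    inner_join(v, by = "chrom", relationship = "many-to-many") |>
    filter(.data$var_end >= .data$window_start,
           .data$pos <= .data$window_end)
  if (nrow(out) == 0) {
    out$rel_pos <- integer(0)
    return(out)
  }
  out |>
    mutate(rel_pos = genomic_to_rel(.data$pos, .data$boundary, .data$strand,
                                    .data$kind))
}

# Apply a set of variants jointly to the genomic region around one site and
# re-extract the fixed-length window anchored at the intron boundary.
# Returns list(window = chr or NA, boundary_lost = lgl).
variant_window_one <- function(genome, chrom, strand, kind, boundary,
                               pos, ref, alt) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  ord <- order(pos)
  pos <- pos[ord]; ref <- toupper(ref[ord]); alt <- toupper(alt[ord])
  maxlen <- max(nchar(ref), nchar(alt), 1L)
  pad <- 40L + maxlen
  reg_start <- max(1L, boundary - pad)
  contig_len <- if (inherits(genome, "DNAStringSet")) {
    length(genome[[chrom]])
  } else nchar(genome[[chrom]])
  reg_end <- min(contig_len, boundary + pad)
  seg <- genome_seq(genome, chrom, reg_start, reg_end)

  # reference-allele check
  for (j in seq_along(pos)) {
    off <- pos[j] - reg_start + 1L
    have <- substr(seg, off, off + nchar(ref[j]) - 1L)
    if (!identical(have, ref[j])) {
      abort(sprintf(
        "reference allele mismatch at %s:%d (expected %s, genome has %s)",
        chrom, pos[j], ref[j], have))
    }
  }

  # boundary tracking through the replacements
  b_off <- boundary - reg_start + 1L
  shift <- 0L
  lost <- FALSE
  for (j in seq_along(pos)) {
    p0 <- pos[j] - reg_start + 1L
    p1 <- p0 + nchar(ref[j]) - 1L
    if (p1 < b_off) {
      shift <- shift + nchar(alt[j]) - nchar(ref[j])
    } else if (p0 <= b_off) {
      inner <- b_off - p0                     # 0-based offset into ref span
      if (inner < nchar(alt[j])) {
        shift <- shift + 0L                   # boundary base survives in alt
      } else {
        lost <- TRUE
      }
    }
  }
  if (lost) return(list(window = NA_character_, boundary_lost = TRUE))

  # apply replacements right-to-left so earlier offsets stay valid
  for (j in rev(seq_along(pos))) {
    p0 <- pos[j] - reg_start + 1L
    p1 <- p0 + nchar(ref[j]) - 1L
    seg <- paste0(substr(seg, 1L, p0 - 1L), alt[j],
                  substr(seg, p1 + 1L, nchar(seg)))
  }
  b_new <- b_off + shift

  rel <- window_rel_positions(kind)
  segpos <- rel_to_genomic(rel, b_new, strand, kind)
  if (min(segpos) < 1L || max(segpos) > nchar(seg)) {
    return(list(window = NA_character_, boundary_lost = FALSE))
  }
  win <- substr(seg, min(segpos), max(segpos))
  if (strand == "-") win <- revcomp(win)
  list(window = win, boundary_lost = FALSE)
}

#' Build variant window sequences for a site
#'
#' Applies one or several variants (jointly) to the genome around a splice
#' site and re-extracts the fixed-length scoring window anchored at the
#' intron boundary: SNPs substitute in place, indels shift the downstream
#' sequence so the window is refilled to full length.  A deletion removing
#' the anchoring boundary base is flagged `boundary_lost` and returns an
#' unscorable window.
#'
#' @param genome A `DNAStringSet` or named character vector of contigs.
#' @param site One-row site tibble (`chrom`, `strand`, `kind`, `boundary`).
#' @param variants Variant tibble (`pos`, `ref`, `alt`) overlapping the
#'   site window; applied jointly (one haplotype).
#' @return A list with `window` (character or `NA`) and `boundary_lost`.
#' @export
apply_variants_to_window <- function(genome, site, variants) {
  variant_window_one(genome, site$chrom[1], site$strand[1], site$kind[1],
                     site$boundary[1], variants$pos, variants$ref,
                     variants$alt)
}

effect_class_levels <- c("disrupting", "weakening", "neutral", "enhancing",
                         "activating", "neutral_nonfunctional")

decide_class <- function(delta, ref_func, var_func, tau) {
  dplyr::case_when(
    ref_func & !var_func ~ "disrupting",
    !ref_func & var_func ~ "activating",
    !ref_func & !var_func ~ "neutral_nonfunctional",
    delta > tau ~ "enhancing",
    delta < -tau ~ "weakening",
    TRUE ~ "neutral"
  )
}

#' Classify reference/variant window pairs
#'
#' The window-level core of the five-class decision table, for callers
#' that already hold reference and variant window sequences: reference
#' functional and variant not, `disrupting`; the reverse, `activating`;
#' both functional, `enhancing` / `weakening` when the score difference
#' exceeds `+tau` / `-tau`, `neutral` otherwise; neither functional,
#' `neutral_nonfunctional`.
#'
#' @param model A `markov_site_model`.
#' @param ref_windows,var_windows Equal-length character vectors.
#' @param tau Neutral threshold (defaults to 1.5 for donors, 1.0 for
#'   acceptors).
#' @return Tibble with `delta_hmm`, `ref_functional`, `var_functional`,
#'   `effect_class`.
#' @export
classify_windows <- function(model, ref_windows, var_windows, tau = NULL) {
  if (is.null(tau)) {
    tau <- if (model$site_kind == "donor") 1.5 else 1.0
  }
  rs <- score_site(model, ref_windows, strict = FALSE)
  vs <- score_site(model, var_windows, strict = FALSE)
  tibble(delta_hmm = vs$score - rs$score, ref_functional = rs$functional,
         var_functional = vs$functional,
         effect_class = decide_class(vs$score - rs$score, rs$functional,
                                     vs$functional, tau))
}

#' Classify variants in splice-site windows into five effect classes
#'
#' For every (site, variant) pair whose variant overlaps the site's scoring
#' window, builds the variant window, scores reference and variant under
#' the Markov site model (and optionally a PWM), and applies the decision
#' table: reference functional and variant not, `disrupting`; reference not
#' functional and variant functional, `activating`; both functional,
#' `enhancing` / `weakening` when the score difference exceeds +tau / -tau
#' and `neutral` otherwise.  Pairs where neither window was ever seen in
#' training are reported as the distinct `neutral_nonfunctional` class.
#' Indels that delete the anchoring boundary base are reported as
#' `disrupting` with `boundary_lost = TRUE`.
#'
#' @param genome Contigs (`DNAStringSet` or named character).
#' @param sites Site tibble with reference windows (see [extract_window()]).
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`, optional
#'   `daf`).
#' @param donor_model,acceptor_model `markov_site_model`s (either may be
#'   `NULL` to skip that kind).
#' @param donor_pwm,acceptor_pwm Optional `site_pwm`s for a parallel PWM
#'   delta.
#' @param thresholds A [class_thresholds()] object.
#' @param mode `"per_variant"` (default; each variant applied alone to the
#'   reference window) or `"haplotype"` (all variants of a site applied
#'   jointly, one classification per site).
#' @return Tibble with one row per classification: site and variant ids,
#'   `kind`, `rel_pos`, `type`, `delta_hmm`, `delta_pwm`, `ref_functional`,
#'   `var_functional`, `effect_class`, `boundary_lost`, plus `daf` when
#'   present in `variants`.
#' @export
classify_variants <- function(genome, sites, variants, donor_model,
                              acceptor_model, donor_pwm = NULL,
                              acceptor_pwm = NULL,
                              thresholds = class_thresholds(),
                              mode = c("per_variant", "haplotype")) {
  mode <- match.arg(mode)
  sv <- site_variants(sites, variants)
  if (nrow(sv) == 0) {
    return(tibble(site_id = character(), variant_id = character(),
                  kind = character(), rel_pos = integer(),
                  type = character(), delta_hmm = numeric(),
                  delta_pwm = numeric(), ref_functional = logical(),
                  var_functional = logical(), effect_class = character(),
                  boundary_lost = logical()))
  }
  if (mode == "haplotype") {
    groups <- split(sv, sv$site_id)
  } else {
    groups <- split(sv, seq_len(nrow(sv)))
  }
  rows <- lapply(groups, function(g) {
    vw <- variant_window_one(genome, g$chrom[1], g$strand[1], g$kind[1],
                             g$boundary[1], g$pos, g$ref, g$alt)
    tibble(site_id = g$site_id[1], variant_id = paste(g$variant_id,
                                                      collapse = ","),
           kind = g$kind[1], rel_pos = g$rel_pos[1], type = if (mode ==
             "haplotype") NA_character_ else g$type[1],
           chrom = g$chrom[1], strand = g$strand[1], boundary = g$boundary[1],
           ref_window = g$ref_window[1], var_window = vw$window,
           boundary_lost = vw$boundary_lost,
           daf = if ("daf" %in% names(g)) g$daf[1] else NA_real_)
  })
  res <- bind_rows(rows)

  out <- lapply(c("donor", "acceptor"), function(kind) {
    df <- res |> filter(.data$kind == !!kind)
    if (nrow(df) == 0) return(NULL)
    model <- if (kind == "donor") donor_model else acceptor_model
    pwm <- if (kind == "donor") donor_pwm else acceptor_pwm
    tau <- if (kind == "donor") thresholds$tau_donor else
      thresholds$tau_acceptor
    if (is.null(model)) return(NULL)
    ok <- !is.na(df$var_window)
    rs <- score_site(model, df$ref_window, strict = FALSE)
    vs <- score_site(model, ifelse(ok, df$var_window, df$ref_window),
                     strict = FALSE)
    df$ref_score <- rs$score
    df$var_score <- ifelse(ok, vs$score, NA_real_)
    df$ref_functional <- rs$functional
    df$var_functional <- ifelse(ok, vs$functional, FALSE)
    df$delta_hmm <- df$var_score - df$ref_score
    if (!is.null(pwm)) {
      df$delta_pwm <- ifelse(ok,
                             score_pwm(pwm, ifelse(ok, df$var_window,
                                                   df$ref_window),
                                       strict = FALSE) -
                               score_pwm(pwm, df$ref_window, strict = FALSE),
                             NA_real_)
    } else {
      df$delta_pwm <- NA_real_
    }
    df$effect_class <- decide_class(df$delta_hmm, df$ref_functional,
                                    df$var_functional, tau)
    # boundary-deleting indels destroy the site outright
    df$effect_class[df$boundary_lost] <- "disrupting"
    df$var_functional[df$boundary_lost] <- FALSE
    df
  })
  bind_rows(out) |>
    select("site_id", "variant_id", "kind", "rel_pos", "type", "daf",
           "ref_score", "var_score", "delta_hmm", "delta_pwm",
           "ref_functional", "var_functional", "effect_class",
           "boundary_lost", "ref_window", "var_window")
}

#' Write variant classifications as TSV
#'
#' @param classifications Output of [classify_variants()].
#' @param path Output path.
#' @param params Optional named list echoed into `#` header lines.
#' @return `path`, invisibly.
#' @export
write_classifications_tsv <- function(classifications, path, params = NULL) {
  hdr <- c(sprintf("# splicevar classifications v%s",
                   as.character(utils::packageVersion("splicevar"))),
           if (!is.null(params)) {
             sprintf("# %s", paste(names(params), unlist(params), sep = "=",
                                   collapse = " "))
           })
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(classifications, path, append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}
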
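#' Per-position nucleotide misincorporation profile
#'
#' Tallies, for each position from the read 5' end, the fraction of
#' reference-C sites read as T (`ct_5p`) and, from the 3' end, the fraction of
#' reference-G sites read as A (`ga_3p`) — the classic ancient-DNA cytosine
#' deamination signature. Reverse-strand alignments are mapped into read
#' orientation before tallying, so deamination always appears as C->T at the
#' read 5' end regardless of mapping strand. Sites where the read or the
#' reference carries an ambiguity code are excluded from numerator and
#' denominator alike.
#'
#' @param alignments a `read_alignments` data.frame carrying per-base pairing
#'   (ungapped CIGARs or M/I/D CIGARs with the read sequence).
#' @param reference the reference sequence the reads are aligned to.
#' @param window number of terminal positions profiled from each end
#'   (default 25; must be >= 5).
#' @return a `damage_profile` list: `window`, `ct_5p`, `ga_3p` (fractions,
#'   `NaN` where no observations), `n_obs_5p`, `n_obs_3p` (denominators) and
#'   `interior_ct_baseline`, the pooled C->T rate at positions more than
#'   `window` from both ends.
#' @export
misincorporation_profile <- function(alignments, reference, window = 25L) {
  window <- as.integer(window)
  if (window < 5L) stop("'window' must be >= 5")
  cols <- alignment_columns(alignments, reference)

  # read-oriented bases: complement both strands' bases on minus alignments
  minus <- cols$strand == "-"
  rb <- cols$ref_base; qb <- cols$base
  if (any(minus)) {
    rb[minus] <- unname(COMPLEMENT[rb[minus]])
    qb[minus] <- unname(COMPLEMENT[qb[minus]])
  }
  ok <- rb %in% BASES & qb %in% BASES
  d5 <- cols$dist5; d3 <- cols$dist3
  sel_c5 <- ok & rb == "C" & d5 <= window
  n_obs_5p <- tabulate(d5[sel_c5], nbins = window)
  ct_ct5 <- tabulate(d5[sel_c5 & qb == "T"], nbins = window)
  sel_g3 <- ok & rb == "G" & d3 <= window
  n_obs_3p <- tabulate(d3[sel_g3], nbins = window)
  ga_ct3 <- tabulate(d3[sel_g3 & qb == "A"], nbins = window)

  interior <- ok & d5 > window & d3 > window & rb == "C"
  base_n <- sum(interior)
  baseline <- if (base_n > 0) sum(interior & qb == "T") / base_n else NaN

  structure(list(
    window = window,
    ct_5p = ifelse(n_obs_5p > 0, ct_ct5 / n_obs_5p, NaN),
    ga_3p = ifelse(n_obs_3p > 0, ga_ct3 / n_obs_3p, NaN),
    n_obs_5p = n_obs_5p, n_obs_3p = n_obs_3p,
    interior_ct_baseline = baseline,
    interior_n = base_n
  ), class = "damage_profile")
}

#' Authenticate a sample as ancient from its damage profile
#'
#' Applies a two-part decision rule to a misincorporation profile: the
#' terminal C->T rate must reach `min_terminal_rate` *and* exceed the interior
#' baseline by `min_fold_over_baseline`; when 3'-end observations are present
#' the symmetric G->A conditions must hold as well. The thresholds are
#' reported alongside the decision so the rule is auditable.
#'
#' @param profile a `damage_profile` from [misincorporation_profile()].
#' @param min_terminal_rate minimum C->T fraction at read position 1
#'   (default 0.05).
#' @param min_fold_over_baseline minimum ratio of the terminal rate to the
#'   interior baseline (default 2.0); a zero baseline passes this part.
#' @return a list with `authentic` (TRUE/FALSE, or NA with
#'   `status = "insufficient data"` when position 1 has no observations) and a
#'   `report` carrying every quantity entering the decision.
#' @export
authenticate <- function(profile, min_terminal_rate = 0.05,
                         min_fold_over_baseline = 2.0) {
  stopifnot(inherits(profile, "damage_profile"))
  report <- list(ct_5p_1 = profile$ct_5p[1], ga_3p_1 = profile$ga_3p[1],
                 n_obs_5p_1 = profile$n_obs_5p[1],
                 n_obs_3p_1 = profile$n_obs_3p[1],
                 interior_ct_baseline = profile$interior_ct_baseline,
                 min_terminal_rate = min_terminal_rate,
                 min_fold_over_baseline = min_fold_over_baseline)
  if (is.na(profile$n_obs_5p[1]) || profile$n_obs_5p[1] == 0L)
    return(list(authentic = NA, status = "insufficient data", report = report))
  pass_end <- function(rate) {
    if (is.nan(rate)) return(NA)
    base <- profile$interior_ct_baseline
    fold_ok <- if (is.nan(base) || base == 0) TRUE else
      rate >= min_fold_over_baseline * base
    rate >= min_terminal_rate && fold_ok
  }
  ok5 <- pass_end(profile$ct_5p[1])
  ok3 <- if (profile$n_obs_3p[1] > 0L) pass_end(profile$ga_3p[1]) else TRUE
  list(authentic = isTRUE(ok5) && isTRUE(ok3), status = "ok", report = report)
}

#' Write a damage profile as a TSV table
#'
#' @param profile a `damage_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_damage_profile <- function(profile, path) {
  write_tsv(data.frame(position = seq_len(profile$window),
                       ct_5p = profile$ct_5p, n_obs_5p = profile$n_obs_5p,
                       ga_3p = profile$ga_3p, n_obs_3p = profile$n_obs_3p),
            path)
}
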
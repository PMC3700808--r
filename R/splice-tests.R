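#' Fraction of a position set missing from an isoform
#'
#' @param bits Mask bit vector.
#' @param positions Non-empty 1-based positions within the mask length.
#' @return Fraction in `[0, 1]` of `positions` carrying bit 1.
#' @export
missing_fraction <- function(bits, positions) {
  if (length(positions) == 0) abort("empty position set")
  if (any(positions < 1 | positions > length(bits))) {
    abort("positions outside the canonical protein length")
  }
  mean(bits[positions] == 1L)
}

#' Decide interface removal at a threshold
#'
#' A heterodimeric semi-interface is removed when the isoform lacks at least
#' `threshold` percent of its residues; a homodimeric interface is removed
#' when at least one of its two semi-interfaces does (the comparison is
#' inclusive: a fraction exactly at the threshold counts as removed).
#'
#' @param interface One-row interface tibble ([extract_interface()] layout).
#' @param protein_id Protein of the isoform mask.
#' @param bits Mask bit vector for that protein.
#' @param threshold Interface-removal threshold, percent.
#' @return One-row tibble: `missing_fraction`, `removed`, `threshold`.
#' @export
is_removed <- function(interface, protein_id, bits, threshold) {
  kind <- interface$kind[[1]]
  if (kind == "homo") {
    if (!identical(interface$protein_a[[1]], protein_id)) {
      abort("mask protein does not match the homodimer protein")
    }
    frac <- max(missing_fraction(bits, interface$positions_a[[1]]),
                missing_fraction(bits, interface$positions_b[[1]]))
  } else {
    if (identical(interface$protein_a[[1]], protein_id)) {
      pos <- interface$positions_a[[1]]
    } else if (identical(interface$protein_b[[1]], protein_id)) {
      pos <- interface$positions_b[[1]]
    } else {
      abort("mask protein matches neither side of the interface")
    }
    frac <- missing_fraction(bits, pos)
  }
  tibble(missing_fraction = frac, removed = frac >= threshold / 100,
         threshold = threshold)
}

#' Keep only isoforms retaining enough of the canonical protein
#'
#' @param masks Mask tibble with a `bits` list-column.
#' @param min_coverage Minimum retained fraction, percent (0 to 100).
#' @return The subset of `masks` with coverage at or above the threshold.
#' @export
filter_by_coverage <- function(masks, min_coverage) {
  stopifnot(min_coverage >= 0, min_coverage <= 100)
  masks[map_dbl(masks$bits, mask_coverage) >= min_coverage / 100, ]
}

# reduce a pairs table to per-stratum real/control missing fractions.
# single mode: one row per (semi-)interface/isoform pair, columns `positions`
# (list), optional `positions_b` (homodimers), `bits` (list), `controls`
# (list of mode-"single" control sets).
# all mode: one row per interface, `masks` (list of mask tibbles) instead of
# `bits`, `controls` of mode "all"; the statistic per stratum is the maximum
# fraction over isoforms (removed in at least one isoform <=> max >= t).
pair_fractions <- function(pairs, mode = c("single", "all")) {
  mode <- rlang::arg_match(mode)
  has_b <- "positions_b" %in% names(pairs)
  side_b <- function(i) if (has_b && !is.null(pairs$positions_b[[i]]))
    pairs$positions_b[[i]] else NULL
  if (mode == "single") {
    if (!all(c("positions", "bits", "controls") %in% names(pairs))) {
      abort("pairs must have columns positions, bits, controls")
    }
    real <- map_dbl(seq_len(nrow(pairs)), function(i) {
      f <- missing_fraction(pairs$bits[[i]], pairs$positions[[i]])
      pb <- side_b(i)
      if (!is.null(pb)) f <- max(f, missing_fraction(pairs$bits[[i]], pb))
      f
    })
    ctrl <- map(seq_len(nrow(pairs)), function(i) {
      cs <- pairs$controls[[i]]
      if (is.null(cs) || cs$n_controls < 1) abort("pair with zero controls")
      f <- control_fractions(cs, pairs$positions[[i]])
      pb <- side_b(i)
      if (!is.null(pb)) f <- pmax(f, control_fractions(cs, pb))
      f
    })
  } else {
    if (!all(c("positions", "masks", "controls") %in% names(pairs))) {
      abort("items must have columns positions, masks, controls")
    }
    real <- map_dbl(seq_len(nrow(pairs)), function(i) {
      masks <- pairs$masks[[i]]
      if (nrow(masks) == 0) abort("empty isoform group")
      f <- map_dbl(masks$bits, missing_fraction, positions = pairs$positions[[i]])
      pb <- side_b(i)
      if (!is.null(pb)) {
        f <- pmax(f, map_dbl(masks$bits, missing_fraction, positions = pb))
      }
      max(f)
    })
    ctrl <- map(seq_len(nrow(pairs)), function(i) {
      cs <- pairs$controls[[i]]
      if (is.null(cs) || cs$n_controls < 1) abort("interface with zero controls")
      f <- control_fractions(cs, pairs$positions[[i]])
      pb <- side_b(i)
      if (!is.null(pb)) f <- pmax(f, control_fractions(cs, pb))
      apply(f, 1, max)
    })
  }
  list(real = real, ctrl = ctrl)
}

fractions_to_strata <- function(fr, threshold) {
  t <- threshold / 100
  tibble(
    a = as.integer(fr$real >= t),
    b = 1L - as.integer(fr$real >= t),
    c = map_int(fr$ctrl, ~ sum(.x >= t)),
    d = map_int(fr$ctrl, ~ sum(.x < t))
  )
}

#' Single-isoform removal test
#'
#' One stratum per (semi-)interface/isoform pair: the real isoform (one row)
#' against its own decoys, columns removed/not removed at the given
#' interface-removal threshold, combined with the CMH chi-square test so
#' that controls are compared only with the isoform they derive from.
#'
#' @param pairs Tibble, one row per pair, with list-columns `positions`
#'   (semi-interface positions; add `positions_b` for homodimers), `bits`
#'   (the isoform mask), `controls` (a mode-"single" [control_set_single()]).
#' @param threshold Interface-removal threshold, percent.
#' @param correction Continuity correction flag, passed to [cmh_test()].
#' @return A `cmh_result`.
#' @export
single_isoform_test <- function(pairs, threshold, correction = TRUE) {
  fr <- pair_fractions(pairs, "single")
  cmh_test(fractions_to_strata(fr, threshold), correction = correction)
}

#' All-isoforms removal test
#'
#' One stratum per interface: the real isoform group (removed when at least
#' one isoform removes the interface at the threshold) against control
#' groups of decoy isoforms that preserve the overlap structure of the real
#' missing stretches.
#'
#' @param items Tibble, one row per interface, with list-columns `positions`
#'   (plus `positions_b` for homodimers), `masks` (mask tibble of the
#'   protein's isoforms), `controls` (a mode-"all" [control_set_all()]).
#' @inheritParams single_isoform_test
#' @return A `cmh_result`.
#' @export
all_isoforms_test <- function(items, threshold, correction = TRUE) {
  fr <- pair_fractions(items, "all")
  cmh_test(fractions_to_strata(fr, threshold), correction = correction)
}

#' Hot-spot independence test
#'
#' Tests whether the splicing of an interface residue is independent of its
#' hot-spot status: one stratum per semi-interface/isoform pair with rows
#' hot-spot/non-hot-spot residues and columns removed/retained under the real
#' mask. Pairs without hot spots are excluded (with a warning); degenerate
#' strata (e.g. no residue removed) are skipped inside the CMH test.
#'
#' @param pairs Tibble with list-columns `positions`, `hotspots`
#'   (subset of `positions`), `bits`.
#' @param correction Continuity correction flag.
#' @return A `cmh_result`.
#' @export
hotspot_independence_test <- function(pairs, correction = TRUE) {
  has_hs <- map_int(pairs$hotspots, length) > 0
  if (any(!has_hs)) {
    warn(paste0(sum(!has_hs), " pair(s) without hot spots excluded"))
    pairs <- pairs[has_hs, ]
  }
  if (nrow(pairs) == 0) abort("no pairs with hot spots")
  strata <- map(seq_len(nrow(pairs)), function(i) {
    hs <- pairs$hotspots[[i]]
    other <- setdiff(pairs$positions[[i]], hs)
    if (length(other) == 0) {
      warn("pair with no non-hot-spot residues: stratum skipped")
      return(NULL)
    }
    bits <- pairs$bits[[i]]
    tibble(a = sum(bits[hs] == 1L), b = sum(bits[hs] == 0L),
           c = sum(bits[other] == 1L), d = sum(bits[other] == 0L))
  })
  strata <- bind_rows(strata)
  if (nrow(strata) == 0) abort("no usable strata")
  cmh_test(strata, correction = correction)
}

#' Sweep the interface-removal threshold
#'
#' Runs the single-isoform or all-isoforms test over a grid of
#' interface-removal thresholds, computing the per-pair real and control
#' missing fractions once. Both frequency curves are non-increasing in the
#' threshold.
#'
#' @param pairs Pairs/items tibble as for [single_isoform_test()] or
#'   [all_isoforms_test()].
#' @param thresholds Percent grid (default `seq(10, 100, 10)`).
#' @param mode `"single"` or `"all"`.
#' @param correction Continuity correction flag.
#' @return Tibble of class `splice_sweep`: one row per threshold with
#'   `mode`, `threshold`, `n_strata`, `n_skipped`, `real_frequency`,
#'   `control_frequency`, `statistic`, `p_value`, `correction`.
#' @export
sweep_removal_thresholds <- function(pairs, thresholds = seq(10, 100, 10),
                                     mode = c("single", "all"),
                                     correction = TRUE) {
  mode <- rlang::arg_match(mode)
  fr <- pair_fractions(pairs, mode)
  rows <- map(thresholds, function(t) {
    res <- cmh_test(fractions_to_strata(fr, t), correction = correction)
    tibble(mode = mode, threshold = t, n_strata = res$n_strata,
           n_skipped = res$n_skipped, real_frequency = res$real_frequency,
           control_frequency = res$control_frequency,
           statistic = res$statistic, p_value = res$p_value,
           correction = correction)
  })
  out <- bind_rows(rows)
  class(out) <- c("splice_sweep", class(out))
  out
}
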
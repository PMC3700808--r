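#' Selectivity scores of interface removal
#'
#' For each (semi-)interface/isoform pair in which the real isoform removes
#' the interface at the threshold, the score is the fraction of the pair's
#' single-isoform controls that also remove it (low score = selectively
#' removed relative to the splicing background). Interfaces that are not
#' removed in any isoform get instead the fraction of the all-isoforms
#' control groups that remove them (high score = selectively protected).
#'
#' @param single_pairs Pairs tibble as for [single_isoform_test()], plus id
#'   columns `interface_id`, `isoform_id`, `protein_id`.
#' @param all_items Items tibble as for [all_isoforms_test()], plus
#'   `interface_id`, `protein_id`.
#' @param threshold Interface-removal threshold, percent.
#' @return Tibble `interface_id`, `isoform_id` (`NA` for the all-isoforms
#'   basis), `protein_id`, `basis` (`"single"`/`"all"`), `score`.
#' @export
selectivity_scores <- function(single_pairs, all_items, threshold) {
  t <- threshold / 100
  out <- list()
  if (!is.null(single_pairs) && nrow(single_pairs)) {
    fr <- pair_fractions(single_pairs, "single")
    spliced <- which(fr$real >= t)
    out$single <- tibble(
      interface_id = single_pairs$interface_id[spliced],
      isoform_id = single_pairs$isoform_id[spliced],
      protein_id = single_pairs$protein_id[spliced],
      basis = "single",
      score = map_dbl(fr$ctrl[spliced], ~ mean(.x >= t))
    )
  }
  if (!is.null(all_items) && nrow(all_items)) {
    fr <- pair_fractions(all_items, "all")
    never <- which(fr$real < t)
    out$all <- tibble(
      interface_id = all_items$interface_id[never],
      isoform_id = NA_character_,
      protein_id = all_items$protein_id[never],
      basis = "all",
      score = map_dbl(fr$ctrl[never], ~ mean(.x >= t))
    )
  }
  bind_rows(out)
}

#' Partition proteins by removal/protection selectivity
#'
#' A protein is selectively removed when at least one of its spliced
#' interface/isoform pairs has a single-isoform score strictly below the
#' cutoff, and selectively protected when one of its never-spliced
#' interfaces has an all-isoforms score strictly above the cutoff. Scores
#' exactly at the cutoff join neither class.
#'
#' @param scores Output of [selectivity_scores()].
#' @param cutoff Score cutoff (default 0.5).
#' @return List with character vectors `selectively_removed` and
#'   `selectively_protected` (protein ids).
#' @export
partition_proteins <- function(scores, cutoff = 0.5) {
  list(
    selectively_removed = sort(unique(
      scores$protein_id[scores$basis == "single" & scores$score < cutoff])),
    selectively_protected = sort(unique(
      scores$protein_id[scores$basis == "all" & scores$score > cutoff]))
  )
}

#' Hypergeometric term enrichment with BH correction
#'
#' Upper-tail hypergeometric test of each annotation term's overlap with the
#' target set against the background, with Benjamini-Hochberg correction
#' across terms. Terms with no annotated background gene are skipped.
#'
#' @param target Character vector of target ids (must be a subset of
#'   `background`).
#' @param background Character vector of background ids.
#' @param annotations Tibble with columns `gene_id`, `term_id`.
#' @param q_max Significance cutoff on the q-value (default 0.05).
#' @return Tibble `term_id`, `target_count`, `background_count`, `p_value`,
#'   `q_value`, `significant`, sorted by p-value.
#' @export
hypergeometric_enrichment <- function(target, background, annotations,
                                      q_max = 0.05) {
  target <- unique(target); background <- unique(background)
  if (!all(target %in% background)) {
    abort("target must be a subset of the background")
  }
  ann <- annotations |>
    filter(.data$gene_id %in% background) |>
    distinct(.data$gene_id, .data$term_id)
  if (nrow(ann) == 0 || length(target) == 0) {
    return(tibble(term_id = character(), target_count = integer(),
                  background_count = integer(), p_value = double(),
                  q_value = double(), significant = logical()))
  }
  n_bg <- length(background)
  n_tg <- length(target)
  per_term <- ann |>
    group_by(.data$term_id) |>
    summarise(
      background_count = dplyr::n(),
      target_count = sum(.data$gene_id %in% target),
      .groups = "drop"
    ) |>
    mutate(p_value = phyper(.data$target_count - 1, .data$background_count,
                            n_bg - .data$background_count, n_tg,
                            lower.tail = FALSE))
  per_term |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           significant = .data$q_value < q_max) |>
    arrange(.data$p_value, .data$term_id)
}
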
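swap_interface_sides <- function(rec) {
  swapped <- rec
  swapped$protein_a <- rec$protein_b; swapped$protein_b <- rec$protein_a
  swapped$positions_a <- rec$positions_b; swapped$positions_b <- rec$positions_a
  swapped$hotspots_a <- rec$hotspots_b; swapped$hotspots_b <- rec$hotspots_a
  swapped$coverage_a <- rec$coverage_b; swapped$coverage_b <- rec$coverage_a
  if ("n_unmapped_a" %in% names(rec)) {
    swapped$n_unmapped_a <- rec$n_unmapped_b
    swapped$n_unmapped_b <- rec$n_unmapped_a
  }
  swapped
}

read_fasta_tbl <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(id = names(x), seq = as.character(x))
}

# which sides of an interface record contribute test pairs: homodimers use
# both sides jointly; heterodimers both sides separately unless a
# `pair_sides` column restricts them (set by the redundancy step)
interface_pair_sides <- function(rec) {
  if (rec$kind == "homo") return(list(c("a", "b")))
  ps <- if ("pair_sides" %in% names(rec)) rec$pair_sides else NA
  if (identical(ps, "a")) list("a")
  else if (identical(ps, "b")) list("b")
  else list("a", "b")
}

#' Extract interfaces from a directory of structures
#'
#' Parses every `*.pdb` file, finds contacting residue pairs between the
#' first two chains, maps them to canonical protein positions through the
#' mapping table, and applies the inclusion filters.
#'
#' @param structures_dir Directory of PDB files (file name stem = structure
#'   id as used in the mapping table).
#' @param sifts Mapping tibble ([read_sifts()] layout) covering the chains.
#' @param protein_lengths Named vector of canonical protein lengths.
#' @param min_side,min_coverage,biounit_ok Passed to
#'   [apply_inclusion_filters()].
#' @param radii,margin Passed to [find_contact_residues()].
#' @return Interface tibble with filter columns (`keep`, `drop_reasons`).
#' @export
extract_interfaces_dir <- function(structures_dir, sifts, protein_lengths = NULL,
                                   min_side = 5, min_coverage = 0.30,
                                   biounit_ok = TRUE, radii = vdw_radii(),
                                   margin = 0.5) {
  files <- sort(list.files(structures_dir, pattern = "\\.pdb$",
                           full.names = TRUE))
  if (length(files) == 0) abort("no PDB files found")
  recs <- map(files, function(f) {
    sid <- sub("\\.pdb$", "", basename(f))
    atoms <- read_pdb(f)
    chains <- sort(unique(atoms$chain_id))
    if (length(chains) < 2) return(NULL)
    a <- filter(atoms, .data$chain_id == chains[1])
    b <- filter(atoms, .data$chain_id == chains[2])
    contacts <- find_contact_residues(a, b, radii = radii, margin = margin)
    if (nrow(contacts) == 0) return(NULL)
    smap <- filter(sifts, .data$structure_id == sid)
    extract_interface(contacts,
                      filter(smap, .data$chain_id == chains[1]),
                      filter(smap, .data$chain_id == chains[2]),
                      structure_id = sid, protein_lengths = protein_lengths)
  })
  out <- bind_rows(recs)
  apply_inclusion_filters(out, min_side = min_side, min_coverage = min_coverage,
                          biounit_ok = biounit_ok)
}

#' Build isoform masks for every gene of a bundle
#'
#' For each gene, selects the reference transcript by comparing the
#' canonical protein with the translated candidates (identical sequence
#' preferred, then at most `max_diffs` non-contiguous differences),
#' enumerates the alternative isoforms (excluding NMD transcripts and
#' reference-identical coding sequences), and encodes each alternative as a
#' two-bit mask through the CDS genomic coordinates.
#'
#' @param exons Exon tibble (internal convention, all transcripts).
#' @param genes Tibble `gene_id`, `protein_id` linking genes to canonical
#'   proteins.
#' @param proteins Tibble `protein_id`, `seq`.
#' @param transcripts Tibble `id`, `seq` of translated transcript sequences.
#' @param max_diffs Reference-selection difference bound (default 5).
#' @return List: `masks` (tibble `protein_id`, `isoform_id`, `bits`),
#'   `references` (per-gene selection report).
#' @export
build_gene_masks <- function(exons, genes, proteins, transcripts,
                             max_diffs = 5) {
  masks <- list(); refs <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]; pid <- genes$protein_id[i]
    pseq <- proteins$seq[match(pid, proteins$protein_id)]
    gex <- filter(exons, .data$gene_id == gid)
    cand_ids <- setdiff(unique(gex$transcript_id[!gex$is_nmd]), character(0))
    cand <- tibble(transcript_id = cand_ids,
                   seq = transcripts$seq[match(cand_ids, transcripts$id)])
    cand <- filter(cand, !is.na(.data$seq))
    sel <- select_reference_transcript(pseq, cand, max_diffs = max_diffs)
    refs[[gid]] <- mutate(sel, gene_id = gid, protein_id = pid, .before = 1)
    if (is.na(sel$transcript_id)) next
    translations <- setNames(cand$seq, cand$transcript_id)
    alt <- enumerate_alternative_isoforms(gex, sel$transcript_id, translations)
    ref_ex <- filter(gex, .data$transcript_id == sel$transcript_id)
    for (tid in unique(alt$transcript_id)) {
      bits <- build_isoform_mask(ref_ex,
                                 filter(alt, .data$transcript_id == tid))
      if (all(bits == 0L)) next
      masks[[paste(gid, tid)]] <- tibble(protein_id = pid, isoform_id = tid,
                                         bits = list(bits))
    }
  }
  list(masks = bind_rows(masks), references = bind_rows(refs))
}

#' Assemble single-isoform test pairs with fresh control sets
#'
#' One pair per (semi-)interface/isoform combination: heterodimeric
#' interfaces contribute each side whose protein has isoform masks;
#' homodimeric interfaces contribute both sides jointly. Each pair gets its
#' own [control_set_single()] of `n_controls` decoys.
#'
#' @param interfaces Interface tibble (kept records).
#' @param masks Mask tibble (`protein_id`, `isoform_id`, `bits`).
#' @param n_controls Decoys per pair (default 1000).
#' @param max_attempts Redraw bound.
#' @return Pairs tibble for [single_isoform_test()] with id columns
#'   `interface_id`, `isoform_id`, `protein_id`, `kind`, plus `hotspots`.
#' @export
assemble_single_pairs <- function(interfaces, masks, n_controls = 1000,
                                  max_attempts = 1000) {
  rows <- list()
  for (i in seq_len(nrow(interfaces))) {
    rec <- interfaces[i, ]
    iid <- rec$structure_id %||% as.character(i)
    sides <- interface_pair_sides(rec)
    for (sd in sides) {
      pid <- if (sd[1] == "a") rec$protein_a else rec$protein_b
      pm <- filter(masks, .data$protein_id == pid)
      if (nrow(pm) == 0) next
      pos <- if (sd[1] == "a") rec$positions_a[[1]] else rec$positions_b[[1]]
      hs <- if (sd[1] == "a") rec$hotspots_a[[1]] else rec$hotspots_b[[1]]
      pos_b <- if (length(sd) == 2) rec$positions_b[[1]] else NULL
      for (j in seq_len(nrow(pm))) {
        rows[[length(rows) + 1]] <- tibble(
          interface_id = iid, kind = rec$kind, side = paste(sd, collapse = ""),
          protein_id = pid, isoform_id = pm$isoform_id[j],
          positions = list(pos), positions_b = list(pos_b),
          hotspots = list(hs), bits = pm$bits[j],
          controls = list(control_set_single(pm$bits[[j]], n_controls,
                                             max_attempts))
        )
      }
    }
  }
  bind_rows(rows)
}

#' Assemble all-isoforms test items with fresh control sets
#'
#' One item per interface whose protein has isoform masks; each item carries
#' the protein's full mask group and a [control_set_all()] of `n_controls`
#' decoy groups.
#'
#' A protein whose joint control constraints cannot be satisfied within
#' `max_attempts` is skipped with a warning rather than aborting the run.
#'
#' @inheritParams assemble_single_pairs
#' @return Items tibble for [all_isoforms_test()].
#' @export
assemble_all_items <- function(interfaces, masks, n_controls = 1000,
                               max_attempts = 1e5) {
  rows <- list()
  control_cache <- list()
  for (i in seq_len(nrow(interfaces))) {
    rec <- interfaces[i, ]
    iid <- rec$structure_id %||% as.character(i)
    sides <- interface_pair_sides(rec)
    for (sd in sides) {
      pid <- if (sd[1] == "a") rec$protein_a else rec$protein_b
      pm <- filter(masks, .data$protein_id == pid)
      if (nrow(pm) == 0) next
      if (is.null(control_cache[[pid]])) {
        cs <- tryCatch(
          control_set_all(select(pm, "isoform_id", "bits"), n_controls,
                          max_attempts = max_attempts, protein_id = pid),
          error = function(e) {
            warn(paste0("skipping protein ", pid, ": ", conditionMessage(e)))
            NULL
          })
        if (is.null(cs)) next
        control_cache[[pid]] <- cs
      }
      rows[[length(rows) + 1]] <- tibble(
        interface_id = iid, kind = rec$kind, protein_id = pid,
        positions = list(if (sd[1] == "a") rec$positions_a[[1]] else
          rec$positions_b[[1]]),
        positions_b = list(if (length(sd) == 2) rec$positions_b[[1]] else NULL),
        masks = list(select(pm, "isoform_id", "bits")),
        controls = control_cache[pid]
      )
    }
  }
  bind_rows(rows)
}

#' Run the full analysis on a file bundle
#'
#' End-to-end orchestration: interface extraction and filtering, redundancy
#' reduction, reference-transcript selection and mask construction, decoy
#' control generation, and the single-isoform / all-isoforms CMH sweeps over
#' the interface-removal threshold grid, separately for heterodimeric and
#' homodimeric interfaces and for each isoform-coverage filter value. Also
#' runs the hot-spot independence test on heterodimeric pairs with hot
#' spots, and the selectivity scoring/partition per threshold.
#'
#' @param dir Bundle directory ([simulate_dataset()] layout: `proteins.fasta`,
#'   `transcripts.fasta`, `exons.tsv`, `genes.tsv`, `structures/`,
#'   `sifts.tsv`, `hotspots.tsv`).
#' @param thresholds Interface-removal grid, percent.
#' @param coverage_grid Isoform-coverage filter values, percent.
#' @param n_controls Decoys per pair / control groups per protein.
#' @param seed RNG seed (controls decoys and random tie-breaks).
#' @param correction CMH continuity correction flag.
#' @param annotations Optional `gene_id`/`term_id` tibble for enrichment.
#' @param selectivity_cutoff Score cutoff of the protein partition.
#' @return List of class `spliceshield_run`: `interfaces`, `dedupe`, `masks`,
#'   `references`, `results` (a `splice_sweep` tibble with `kind` and
#'   `coverage_min` columns), `hotspot` (a `cmh_result`), `selectivity`,
#'   `partition`, `enrichment`, `provenance`.
#' @export
run_full_analysis <- function(dir, thresholds = seq(10, 100, 10),
                              coverage_grid = 0, n_controls = 1000,
                              seed = 1, correction = TRUE,
                              annotations = NULL, selectivity_cutoff = 0.5) {
  set.seed(seed)
  proteins <- read_fasta_tbl(file.path(dir, "proteins.fasta")) |>
    rename(protein_id = "id")
  transcripts <- read_fasta_tbl(file.path(dir, "transcripts.fasta"))
  exons <- read_exon_tsv(file.path(dir, "exons.tsv"))
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"), col_types = "cc")
  sifts <- read_sifts(file.path(dir, "sifts.tsv"))
  hotspots <- readr::read_tsv(file.path(dir, "hotspots.tsv"),
                              col_types = readr::cols(
                                protein_id = readr::col_character(),
                                position = readr::col_integer()))
  plens <- setNames(nchar(proteins$seq), proteins$protein_id)

  interfaces <- extract_interfaces_dir(file.path(dir, "structures"), sifts,
                                       protein_lengths = plens)
  interfaces <- filter(interfaces, .data$keep)
  # attach hot-spot labels to side a (heterodimeric convention of the input)
  interfaces$hotspots_a <- map2(interfaces$protein_a, interfaces$positions_a,
    function(p, pos) {
      intersect(pos, hotspots$position[hotspots$protein_id == p])
    })

  iface_proteins <- unique(c(interfaces$protein_a, interfaces$protein_b))
  dedupe <- dedupe_interfaces(interfaces,
                              filter(proteins, .data$protein_id %in% iface_proteins))
  # the heterodimeric analysis unit is the semi-interface: keep one record per
  # representative semi-interface, canonicalized so that side a carries it
  het_keep <- list()
  if (!is.null(dedupe$hetero$representative)) {
    reps <- filter(dedupe$hetero, .data$representative)
    for (i in seq_len(nrow(reps))) {
      rec <- interfaces[reps$interface_row[i], ]
      if (reps$side[i] == "b") rec <- swap_interface_sides(rec)
      rec$pair_sides <- "a"
      het_keep[[i]] <- rec
    }
  }
  homo_rows <- if (!is.null(dedupe$homo$representative)) {
    dedupe$homo$interface_row[dedupe$homo$representative]
  } else integer(0)
  homo_keep <- interfaces[homo_rows, ]
  if (nrow(homo_keep)) homo_keep$pair_sides <- "ab"
  interfaces <- bind_rows(bind_rows(het_keep), homo_keep)

  bm <- build_gene_masks(exons, genes, proteins, transcripts)
  results <- list(); selectivity <- list()
  for (cov in coverage_grid) {
    masks_c <- filter_by_coverage(bm$masks, cov)
    for (kind in intersect(c("hetero", "homo"), unique(interfaces$kind))) {
      recs <- filter(interfaces, .data$kind == !!kind)
      pairs <- assemble_single_pairs(recs, masks_c, n_controls)
      items <- assemble_all_items(recs, masks_c, n_controls)
      if (nrow(pairs)) {
        r <- sweep_removal_thresholds(pairs, thresholds, "single", correction)
        results[[paste(cov, kind, "single")]] <-
          mutate(r, kind = kind, coverage_min = cov, .before = 1)
      }
      if (nrow(items)) {
        r <- sweep_removal_thresholds(items, thresholds, "all", correction)
        results[[paste(cov, kind, "all")]] <-
          mutate(r, kind = kind, coverage_min = cov, .before = 1)
      }
      if (cov == min(coverage_grid) && kind == "hetero" && nrow(pairs)) {
        for (t in thresholds) {
          sc <- selectivity_scores(pairs, items, t)
          if (nrow(sc)) {
            selectivity[[as.character(t)]] <- mutate(sc, threshold = t,
                                                     .before = 1)
          }
        }
      }
    }
  }
  results <- bind_rows(results)
  class(results) <- c("splice_sweep", class(results))
  selectivity <- bind_rows(selectivity)

  hot_pairs <- NULL; hotspot_res <- NULL
  het <- filter(interfaces, .data$kind == "hetero")
  if (nrow(het)) {
    hp <- assemble_single_pairs(het, bm$masks, n_controls = 1)
    hp <- hp[map_int(hp$hotspots, length) > 0, ]
    if (nrow(hp)) {
      hotspot_res <- suppressWarnings(
        hotspot_independence_test(hp, correction = correction))
    }
    hot_pairs <- hp
  }

  partition <- if (nrow(selectivity)) {
    map(split(selectivity, selectivity$threshold), partition_proteins,
        cutoff = selectivity_cutoff)
  } else list()
  enrichment <- NULL
  if (!is.null(annotations) && length(partition)) {
    bg <- unique(genes$protein_id)
    enrichment <- bind_rows(imap(partition, function(p, t) {
      bind_rows(
        mutate(hypergeometric_enrichment(p$selectively_removed, bg, annotations),
               class = "selectively_removed", threshold = as.numeric(t)),
        mutate(hypergeometric_enrichment(p$selectively_protected, bg, annotations),
               class = "selectively_protected", threshold = as.numeric(t))
      )
    }))
  }
  out <- list(
    interfaces = interfaces, dedupe = dedupe, masks = bm$masks,
    references = bm$references, results = results, hotspot = hotspot_res,
    selectivity = selectivity, partition = partition, enrichment = enrichment,
    provenance = list(
      seed = seed, n_controls = n_controls, thresholds = thresholds,
      coverage_grid = coverage_grid, correction = correction,
      config_hash = rlang::hash(list(thresholds, coverage_grid, n_controls,
                                     seed, correction)),
      package_version = as.character(utils::packageVersion("spliceshield"))
    )
  )
  class(out) <- "spliceshield_run"
  out
}

#' @export
print.spliceshield_run <- function(x, ...) {
  cat("<spliceshield_run>\n")
  cat("  interfaces kept:", nrow(x$interfaces), "\n")
  cat("  isoform masks:", nrow(x$masks), "\n")
  cat("  result rows:", nrow(x$results), "\n")
  cat("  seed:", x$provenance$seed, " config hash:",
      x$provenance$config_hash, "\n")
  invisible(x)
}

#' Plot real versus randomized removal frequencies across thresholds
#'
#' Reproduces the removal-frequency summary: the frequency at which
#' interfaces are removed by real splicing (red) and by randomized splicing
#' (blue) as a function of the interface-removal threshold, with filled
#' points where the CMH p-value is below `alpha`.
#'
#' @param object A `splice_sweep` tibble.
#' @param alpha Significance level for the point marking (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot splice_sweep
#' @export
autoplot.splice_sweep <- function(object, alpha = 0.05, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("real_frequency", "control_frequency"),
                              names_to = "series", values_to = "frequency")
  long$series <- ifelse(long$series == "real_frequency", "real splicing",
                        "randomized splicing")
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$threshold, y = .data$frequency, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$p_value < alpha)) +
    ggplot2::scale_colour_manual(values = c("real splicing" = "#c0392b",
                                            "randomized splicing" = "#2980b9")) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = paste0("p < ", alpha)) +
    ggplot2::labs(x = "interface-removal threshold (%)",
                  y = "removal frequency", colour = NULL)
  facets <- intersect(c("kind", "mode", "coverage_min"), names(object))
  if (length(facets) >= 2) {
    p <- p + ggplot2::facet_grid(stats::reformulate(facets[2], facets[1]))
  } else if (length(facets) == 1) {
    p <- p + ggplot2::facet_wrap(facets)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Worked example: partial interface removal on a cullin-adaptor pair
#'
#' Computes, for the chain of interest of a two-chain structure, the size of
#' its semi-interface and how many of those residues fall within an
#' N-terminal prefix removed by alternative splicing. This mirrors the
#' CUL4A/DDB1 case, where alternative transcripts lack the first 100
#' residues and with them most of the DDB1-binding semi-interface.
#'
#' @param pdb_path Structure file with the two chains.
#' @param sifts_path Chain-to-protein mapping TSV.
#' @param removed_prefix_len Length of the spliced-out N-terminal prefix
#'   (default 100).
#' @param chain,partner_chain Chain of interest and its partner.
#' @return One-row tibble: `semi_interface_size`, `n_in_removed_prefix`.
#' @export
cul4a_case_study <- function(pdb_path, sifts_path, removed_prefix_len = 100,
                             chain = "A", partner_chain = "B") {
  atoms <- read_pdb(pdb_path)
  if (!all(c(chain, partner_chain) %in% atoms$chain_id)) {
    abort(paste0("chains ", chain, "/", partner_chain, " not found in structure"))
  }
  sifts <- read_sifts(sifts_path)
  contacts <- find_contact_residues(
    filter(atoms, .data$chain_id == !!chain),
    filter(atoms, .data$chain_id == !!partner_chain))
  rec <- extract_interface(contacts,
                           filter(sifts, .data$chain_id == !!chain),
                           filter(sifts, .data$chain_id == !!partner_chain))
  pos <- rec$positions_a[[1]]
  tibble(semi_interface_size = length(pos),
         n_in_removed_prefix = sum(pos <= removed_prefix_len))
}

#' Synthetic stand-in bundle for the cullin worked example
#'
#' Writes a synthetic toy structure (not derived from any deposited
#' structure) whose chain-A semi-interface has 30 residues, 19 of which fall
#' within the first 100 positions of the canonical protein — the geometry of
#' the published CUL4A/DDB1 case — so the worked example can run without
#' downloads.
#'
#' @param dir Output directory.
#' @return List with `pdb` and `sifts` file paths.
#' @export
synthetic_cul4a_bundle <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  positions_a <- sort(c(61:79, 131:141))  # 19 within 1..100, 11 beyond
  positions_b <- 201:235
  toy <- emit_toy_structure(positions_a, positions_b, len_a = 250, len_b = 300,
                            protein_a = "CUL4A_SYN", protein_b = "DDB1_SYN",
                            structure_id = "SYN_CUL4A")
  pdb <- file.path(dir, "syn_cul4a.pdb")
  sifts <- file.path(dir, "syn_cul4a_sifts.tsv")
  writeLines(toy$pdb, pdb)
  readr::write_tsv(toy$sifts, sifts)
  list(pdb = pdb, sifts = sifts)
}
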
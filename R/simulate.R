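#' Configuration of the synthetic study generator
#'
#' Defines the study conditions for the synthetic data: gene models with
#' multi-exon CDS, a canonical isoform per gene, alternative isoforms formed
#' by skipping internal coding exons, and interfaces (5-60 residues by
#' default) with clustered hot-spot subsets. The splicing `bias` multiplies
#' the skip probability of interface-overlapping exons: 1 is neutral, values
#' below 1 make splicing avoid the interface (protection), values above 1
#' make it target the interface. Terminal coding exons are never skipped and
#' are kept short (2-6 codons) so that alternative splicing can reach most of
#' the canonical sequence; interfaces are placed uniformly over the protein.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(min, max)` of coding exons.
#' @param exon_len Codon-length range of internal exons.
#' @param terminal_exon_len Codon-length range of the first and last exon.
#' @param isoforms_per_gene Integer range of alternative isoforms.
#' @param skip_prob Baseline skip probability of an internal exon.
#' @param interface_len Residue-count range of an interface.
#' @param hotspot_frac Fraction of interface residues flagged as hot spots.
#' @param homo_frac Fraction of genes given a homodimeric interface.
#' @param bias Splicing bias towards interface-overlapping exons.
#' @param seed RNG seed used by [simulate_dataset()]/[simulate_study()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 50, exons_per_gene = c(6, 10),
                       exon_len = c(10, 35), terminal_exon_len = c(2, 6),
                       isoforms_per_gene = c(1, 4), skip_prob = 0.25,
                       interface_len = c(5, 60), hotspot_frac = 0.25,
                       homo_frac = 0.25, bias = 1, seed = 1) {
  stopifnot(n_genes >= 1, exons_per_gene[1] >= 3, skip_prob >= 0,
            skip_prob <= 1, hotspot_frac >= 0, hotspot_frac <= 1,
            homo_frac >= 0, homo_frac <= 1, bias >= 0,
            interface_len[1] >= 1)
  structure(as.list(environment()), class = "sim_config")
}

rand_range <- function(range) {
  if (range[1] >= range[2]) return(as.integer(range[1]))
  range[1] + runif_int(1, range[2] - range[1] + 1) - 1L
}

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Simulate one gene model with its canonical protein
#'
#' Exon codon counts are drawn uniformly from the configured ranges; exons
#' are laid out on a toy contig separated by 100-nt introns on a random
#' strand; the concatenated CDS length is a multiple of 3 by construction
#' and the canonical protein is a random sequence of matching length.
#'
#' @param cfg A [sim_config()].
#' @param gene_id,protein_id Identifiers for the gene and its protein.
#' @return List: `gene_id`, `protein_id`, `protein_seq`, `L`, `exons`
#'   (reference transcript exon tibble, internal convention), `exon_residues`
#'   (tibble `exon`, `res_start`, `res_end`), `codons` (per-exon codon
#'   counts).
#' @export
simulate_gene <- function(cfg, gene_id = "G1", protein_id = paste0(gene_id, "_P")) {
  n_ex <- rand_range(cfg$exons_per_gene)
  codons <- c(rand_range(cfg$terminal_exon_len),
              map_int(seq_len(n_ex - 2L), ~ rand_range(cfg$exon_len)),
              rand_range(cfg$terminal_exon_len))
  nt <- codons * 3L
  strand <- sample(c("+", "-"), 1)
  gstart <- cumsum(c(0L, head(nt, -1) + 100L))
  if (strand == "-") {
    # 5'->3' order means descending genomic coordinates
    total <- sum(nt) + 100L * (n_ex - 1L)
    gstart <- total - (gstart + nt)
  }
  exons <- tibble(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".ref"),
    strand = strand, start = as.integer(gstart),
    end = as.integer(gstart + nt), is_nmd = FALSE
  )
  ends <- cumsum(codons)
  list(
    gene_id = gene_id, protein_id = protein_id,
    protein_seq = rand_protein(sum(codons)), L = sum(codons),
    exons = exons,
    exon_residues = tibble(exon = seq_len(n_ex),
                           res_start = ends - codons + 1L, res_end = ends),
    codons = codons
  )
}

#' Simulate an interface on a protein
#'
#' Draws a contiguous-ish residue cluster (positions sampled inside a window
#' 1.2 times the interface size) placed uniformly on the protein, with a
#' contiguous run of hot spots mirroring the clustering of hot regions.
#'
#' @param protein_len Canonical protein length.
#' @param cfg A [sim_config()].
#' @return List with sorted integer `positions` and `hotspots` (subset).
#' @export
simulate_interface <- function(protein_len, cfg) {
  len <- min(rand_range(cfg$interface_len), protein_len)
  w <- min(protein_len, max(len, round(len * 1.2)))
  wstart <- runif_int(1, protein_len - w + 1L)
  positions <- sort(sample(seq(wstart, wstart + w - 1L), len))
  nh <- round(cfg$hotspot_frac * len)
  hotspots <- if (nh > 0) {
    at <- runif_int(1, len - nh + 1L)
    positions[at:(at + nh - 1L)]
  } else integer(0)
  list(positions = positions, hotspots = hotspots)
}

#' Simulate alternative isoforms of a gene by biased exon skipping
#'
#' Each internal exon is skipped independently with probability
#' `skip_prob * bias^overlap`, where `overlap` indicates whether the exon
#' codes for at least one interface residue; the first and last exon are
#' never skipped. Patterns with no skipped exon are redrawn (an alternative
#' must differ from the reference); transcripts are never flagged for
#' nonsense-mediated decay.
#'
#' @param gene Output of [simulate_gene()].
#' @param interface_positions Interface residues on the canonical protein.
#' @param cfg A [sim_config()].
#' @param bias Overrides `cfg$bias` when given.
#' @return List: `exons` (alternative transcript exon tibble), `masks`
#'   (tibble `isoform_id`, `bits` of truth masks).
#' @export
simulate_isoforms <- function(gene, interface_positions, cfg, bias = cfg$bias) {
  n_ex <- nrow(gene$exons)
  internal <- seq(2L, n_ex - 1L)
  overlap <- map_lgl(internal, function(e) {
    any(interface_positions >= gene$exon_residues$res_start[e] &
        interface_positions <= gene$exon_residues$res_end[e])
  })
  p <- pmin(cfg$skip_prob * bias^as.numeric(overlap), 0.95)
  n_iso <- rand_range(cfg$isoforms_per_gene)
  exons <- list(); masks <- list()
  for (k in seq_len(n_iso)) {
    skip <- NULL
    for (try in 1:100) {
      s <- runif(length(internal)) < p
      if (any(s)) { skip <- s; break }
    }
    if (is.null(skip)) next  # e.g. bias 0 with every internal exon on the interface
    iso_id <- paste0(gene$gene_id, ".iso", k)
    kept <- setdiff(seq_len(n_ex), internal[skip])
    ex <- gene$exons[kept, ]
    ex$transcript_id <- iso_id
    bits <- integer(gene$L)
    for (e in internal[skip]) {
      bits[gene$exon_residues$res_start[e]:gene$exon_residues$res_end[e]] <- 1L
    }
    exons[[k]] <- ex
    masks[[k]] <- tibble(isoform_id = iso_id, bits = list(bits))
  }
  list(exons = bind_rows(exons), masks = bind_rows(masks))
}

pdb_atom_line <- function(serial, chain, resnum, x, y, z,
                          name = "CA", resname = "GLY", element = "C") {
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), resname, chain, resnum, x, y, z, 1, 0,
          element)
}

#' Emit a toy two-chain structure realizing a prescribed interface
#'
#' One pseudo-atom (carbon) per residue. Every intended contact pair is
#' placed at 3.0 Angstrom (inside the carbon-carbon threshold of 3.9), all
#' other inter-chain atom pairs at 8 Angstrom or more, so the extraction
#' pipeline recovers exactly the prescribed residue sets. Chain author
#' numbering is offset from protein numbering by a random shift recorded in
#' the accompanying mapping table.
#'
#' @param positions_a,positions_b Interface residues of each side (1-based
#'   protein positions, non-empty).
#' @param len_a,len_b Protein lengths (every residue gets an atom).
#' @param protein_a,protein_b Protein ids (equal for a homodimer).
#' @param structure_id Structure identifier for the mapping table.
#' @param chain_a,chain_b Chain identifiers.
#' @return List: `pdb` (character vector of PDB lines), `sifts` (mapping
#'   tibble in [read_sifts()] layout).
#' @export
emit_toy_structure <- function(positions_a, positions_b, len_a, len_b,
                               protein_a = "PA", protein_b = "PB",
                               structure_id = "TOY1",
                               chain_a = "A", chain_b = "B") {
  if (length(positions_a) == 0 || length(positions_b) == 0) {
    abort("both interface sides must be non-empty")
  }
  na <- length(positions_a); nb <- length(positions_b)
  m <- min(na, nb)
  coord_a <- matrix(NA_real_, len_a, 3)
  coord_b <- matrix(NA_real_, len_b, 3)
  # paired interface residues in contact clusters 12 Angstrom apart
  for (k in seq_len(m)) {
    coord_a[positions_a[k], ] <- c(12 * k, 0, 0)
    coord_b[positions_b[k], ] <- c(12 * k, 3, 0)
  }
  # the longer side's excess residues all contact the last residue of the
  # shorter side, on a 3.0-Angstrom sphere around it
  excess <- if (na > nb) positions_a[seq(m + 1, na)] else
    if (nb > na) positions_b[seq(m + 1, nb)] else integer(0)
  if (length(excess)) {
    anchor <- c(12 * m, if (na > nb) 3 else 0, 0)
    th <- seq(0.3, pi - 0.3, length.out = length(excess))
    for (j in seq_along(excess)) {
      pt <- anchor + 3 * c(0, cos(th[j]) * (if (na > nb) -1 else 1), sin(th[j]))
      if (na > nb) coord_a[excess[j], ] <- pt else coord_b[excess[j], ] <- pt
    }
  }
  # non-interface residues on compact grids far from the contact zone (and
  # within the fixed-width PDB coordinate fields): chain A below y = -30,
  # chain B above y = 50
  grid <- function(n, y0, dy) {
    i <- seq_len(n) - 1L
    cbind(-10 - 5 * (i %% 60L), y0 + dy * 5 * (i %/% 60L), 0)
  }
  rest_a <- setdiff(seq_len(len_a), positions_a)
  rest_b <- setdiff(seq_len(len_b), positions_b)
  coord_a[rest_a, ] <- grid(length(rest_a), -30, -1)
  coord_b[rest_b, ] <- grid(length(rest_b), 50, +1)
  # generator self-check: non-intended inter-chain pairs stay clearly outside
  # the contact threshold
  intended <- matrix(FALSE, len_a, len_b)
  intended[cbind(positions_a[seq_len(m)], positions_b[seq_len(m)])] <- TRUE
  if (length(excess)) {
    if (na > nb) intended[cbind(excess, positions_b[m])] <- TRUE
    else intended[cbind(positions_a[m], excess)] <- TRUE
  }
  d2 <- outer(rowSums(coord_a^2), rowSums(coord_b^2), "+") -
    2 * tcrossprod(coord_a, coord_b)
  if (min(d2[!intended]) <= 4.5^2) {
    abort("infeasible toy geometry: a non-intended pair fell below 4.5 A")
  }
  off_a <- runif_int(1, 100L); off_b <- runif_int(1, 100L)
  lines <- c(
    pdb_atom_line(seq_len(len_a), chain_a, seq_len(len_a) + off_a,
                  coord_a[, 1], coord_a[, 2], coord_a[, 3]),
    pdb_atom_line(len_a + seq_len(len_b), chain_b, seq_len(len_b) + off_b,
                  coord_b[, 1], coord_b[, 2], coord_b[, 3]),
    "END"
  )
  sifts <- bind_rows(
    tibble(structure_id = structure_id, chain_id = chain_a,
           pdb_resnum = seq_len(len_a) + off_a, pdb_icode = "",
           protein_id = protein_a, protein_pos = seq_len(len_a)),
    tibble(structure_id = structure_id, chain_id = chain_b,
           pdb_resnum = seq_len(len_b) + off_b, pdb_icode = "",
           protein_id = protein_b, protein_pos = seq_len(len_b))
  )
  list(pdb = lines, sifts = sifts)
}

#' Simulate a full in-memory study
#'
#' Generates genes, canonical proteins, (semi-)interfaces with hot spots,
#' alternative isoforms under the configured splicing bias, and truth masks.
#' Heterodimeric genes get a non-spliced partner protein. Use
#' [simulate_dataset()] to additionally write the file bundle (FASTA, exon
#' TSV, toy PDB structures, mapping and hot-spot tables, truth JSON).
#'
#' @param cfg A [sim_config()]. The RNG is seeded with `cfg$seed` unless
#'   `seed = NULL` is passed explicitly in `cfg` (then the session RNG state
#'   is used as-is).
#' @return List with tibbles `proteins` (`protein_id`, `seq`, `role`),
#'   `exons` (all transcripts), `interfaces` ([extract_interface()] layout
#'   with hot spots filled), `masks` (`protein_id`, `isoform_id`, `bits`),
#'   and the `truth` list keyed by gene.
#' @export
simulate_study <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  proteins <- list(); exons <- list(); interfaces <- list()
  masks <- list(); truth <- list()
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%03d", i)
    gene <- simulate_gene(cfg, gid)
    homo <- runif(1) < cfg$homo_frac
    si_a <- simulate_interface(gene$L, cfg)
    if (homo) {
      si_b <- simulate_interface(gene$L, cfg)
      partner_id <- gene$protein_id
      partner_len <- gene$L
      interface_pos <- sort(unique(c(si_a$positions, si_b$positions)))
    } else {
      partner_id <- paste0(gid, "_Q")
      partner_len <- max(60L, rand_range(c(80L, 200L)))
      si_b <- simulate_interface(partner_len, cfg)
      si_b$hotspots <- integer(0)
      interface_pos <- si_a$positions
      proteins[[partner_id]] <- tibble(protein_id = partner_id,
                                       seq = rand_protein(partner_len),
                                       role = "partner")
    }
    iso <- simulate_isoforms(gene, interface_pos, cfg)
    proteins[[gene$protein_id]] <- tibble(protein_id = gene$protein_id,
                                          seq = gene$protein_seq,
                                          role = "canonical")
    exons[[gid]] <- bind_rows(gene$exons, iso$exons)
    interfaces[[gid]] <- tibble(
      kind = if (homo) "homo" else "hetero",
      structure_id = paste0("S", gid),
      protein_a = gene$protein_id,
      positions_a = list(si_a$positions), hotspots_a = list(si_a$hotspots),
      protein_b = partner_id,
      positions_b = list(si_b$positions), hotspots_b = list(si_b$hotspots),
      resolution = round(runif(1, 1.5, 3.0), 2),
      coverage_a = 1, coverage_b = 1,
      n_unmapped_a = 0L, n_unmapped_b = 0L
    )
    if (nrow(iso$masks)) {
      masks[[gid]] <- mutate(iso$masks, protein_id = gene$protein_id,
                             .before = 1)
    }
    truth[[gid]] <- list(
      gene_id = gid, protein_id = gene$protein_id, L = gene$L,
      exon_residues = gene$exon_residues,
      interface = si_a, interface_b = si_b, kind = if (homo) "homo" else "hetero",
      partner_id = partner_id, partner_len = partner_len,
      isoform_masks = iso$masks, bias = cfg$bias
    )
  }
  list(proteins = bind_rows(proteins), exons = bind_rows(exons),
       interfaces = bind_rows(interfaces), masks = bind_rows(masks),
       truth = truth, config = cfg)
}

# translated protein of an alternative isoform given the truth mask: the
# canonical residues whose codons the transcript retains
masked_translation <- function(protein_seq, bits) {
  paste(strsplit(protein_seq, "")[[1]][bits == 0L], collapse = "")
}

#' Simulate a study and write the file bundle
#'
#' Writes `proteins.fasta` (canonical and partner proteins),
#' `transcripts.fasta` (translated transcript sequences), `exons.tsv`
#' (simplified exon dialect, including an NMD-flagged duplicate transcript
#' for roughly one gene in five, to exercise the NMD exclusion),
#' `structures/<id>.pdb` toy structures realizing each interface,
#' `sifts.tsv`, `hotspots.tsv`, and `truth.json`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the [simulate_study()] list plus `$paths`.
#' @export
simulate_dataset <- function(cfg, dir) {
  study <- simulate_study(cfg)
  dir.create(file.path(dir, "structures"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    proteins = file.path(dir, "proteins.fasta"),
    transcripts = file.path(dir, "transcripts.fasta"),
    exons = file.path(dir, "exons.tsv"),
    genes = file.path(dir, "genes.tsv"),
    sifts = file.path(dir, "sifts.tsv"),
    hotspots = file.path(dir, "hotspots.tsv"),
    truth = file.path(dir, "truth.json"),
    structures = file.path(dir, "structures")
  )
  prot <- Biostrings::AAStringSet(setNames(study$proteins$seq,
                                           study$proteins$protein_id))
  Biostrings::writeXStringSet(prot, paths$proteins)

  tr_seqs <- list(); exon_out <- list(); sifts <- list(); hs <- list()
  for (g in study$truth) {
    gid <- g$gene_id
    ref_id <- paste0(gid, ".ref")
    tr_seqs[[ref_id]] <- study$proteins$seq[study$proteins$protein_id == g$protein_id]
    seqs <- map_chr(g$isoform_masks$bits %||% list(), function(b) {
      masked_translation(tr_seqs[[ref_id]], b)
    })
    if (nrow(g$isoform_masks)) {
      names(seqs) <- g$isoform_masks$isoform_id
      tr_seqs <- c(tr_seqs, as.list(seqs))
    }
    ex <- filter(study$exons, .data$gene_id == gid)
    if (nrow(g$isoform_masks) && runif(1) < 0.2) {
      nmd <- filter(ex, .data$transcript_id == g$isoform_masks$isoform_id[1])
      nmd$transcript_id <- paste0(gid, ".nmd1")
      nmd$is_nmd <- TRUE
      ex <- bind_rows(ex, nmd)
    }
    exon_out[[gid]] <- ex
    iface <- filter(study$interfaces, .data$protein_a == g$protein_id)
    toy <- emit_toy_structure(
      iface$positions_a[[1]], iface$positions_b[[1]],
      g$L, g$partner_len,
      protein_a = g$protein_id, protein_b = g$partner_id,
      structure_id = iface$structure_id[[1]]
    )
    writeLines(toy$pdb, file.path(paths$structures,
                                  paste0(iface$structure_id[[1]], ".pdb")))
    sifts[[gid]] <- toy$sifts
    hs[[gid]] <- tibble(protein_id = g$protein_id,
                        position = g$interface$hotspots)
  }
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unlist(tr_seqs)), paths$transcripts)
  write_exon_tsv(bind_rows(exon_out), paths$exons)
  readr::write_tsv(tibble(gene_id = map_chr(study$truth, "gene_id"),
                          protein_id = map_chr(study$truth, "protein_id")),
                   paths$genes)
  readr::write_tsv(bind_rows(sifts), paths$sifts)
  readr::write_tsv(bind_rows(hs), paths$hotspots)
  truth_json <- map(study$truth, function(g) {
    list(gene_id = g$gene_id, protein_id = g$protein_id, L = g$L,
         kind = g$kind, partner_id = g$partner_id, bias = g$bias,
         interface_positions = g$interface$positions,
         hotspots = g$interface$hotspots,
         interface_positions_b = g$interface_b$positions,
         masks = if (nrow(g$isoform_masks))
           as.list(setNames(map_chr(g$isoform_masks$bits, encode_mask_rle),
                            g$isoform_masks$isoform_id)) else NULL)
  })
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE, digits = NA)
  study$paths <- paths
  invisible(study)
}
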
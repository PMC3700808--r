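pairwise_identity <- function(seq_a, seq_b) {
  aln <- global_align(seq_a, seq_b)
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  both <- a != "-" & b != "-"
  ncb <- sum(both)
  list(
    identity = if (ncb == 0) 0 else sum(both & a == b) / ncb,
    coverage_a = ncb / nchar(seq_a),
    coverage_b = ncb / nchar(seq_b)
  )
}

# center-star progressive alignment: returns, per sequence, the alignment
# column of each residue position. Insertions relative to the center are
# right-justified inside their column block; the clustering downstream only
# consumes the column identifiers.
center_star_columns <- function(seqs) {
  m <- length(seqs)
  if (m == 1) return(list(seq_len(nchar(seqs[[1]]))))
  center <- which.max(nchar(seqs))
  n <- nchar(seqs[[center]])
  # slot k = insertion block before center residue k; slot n+1 trails
  aligned <- vector("list", m)
  ins <- matrix(0L, m, n + 1L)
  for (i in seq_len(m)) {
    if (i == center) next
    aln <- global_align(seqs[[center]], seqs[[i]])
    ca <- strsplit(aln$aligned_a, "")[[1]]
    mb <- strsplit(aln$aligned_b, "")[[1]]
    slot <- cumsum(ca != "-") + 1L         # insertion before this center residue
    slot[ca != "-"] <- NA                   # columns holding a center residue
    aligned[[i]] <- list(ca = ca, mb = mb, slot = slot)
    if (any(!is.na(slot))) {
      tab <- table(slot[!is.na(slot) & mb != "-"])
      ins[i, as.integer(names(tab))] <- as.integer(tab)
    }
  }
  width <- apply(ins, 2, max)                       # block widths
  # column of center residue k = total width of blocks 1..k + k
  center_col <- cumsum(width[seq_len(n)]) + seq_len(n)
  out <- vector("list", m)
  out[[center]] <- as.integer(center_col)
  block_col_end <- c(center_col - 1L, sum(width) + n)  # last column of block k
  for (i in seq_len(m)) {
    if (i == center) next
    al <- aligned[[i]]
    cols <- integer(sum(al$mb != "-"))
    ci <- cumsum(al$ca != "-")
    pos <- 0L
    run_left <- 0L; run_slot <- 0L
    for (j in seq_along(al$mb)) {
      if (al$mb[j] == "-") next
      pos <- pos + 1L
      if (al$ca[j] != "-") {
        cols[pos] <- center_col[ci[j]]
        run_left <- 0L
      } else {
        k <- al$slot[j]
        if (k != run_slot) {  # start of an insertion run: right-justify it
          run_len <- sum(al$slot == k & al$mb != "-", na.rm = TRUE)
          run_left <- run_len
          run_slot <- k
        }
        cols[pos] <- block_col_end[k] - run_left + 1L
        run_left <- run_left - 1L
      }
    }
    out[[i]] <- cols
  }
  out
}

#' Group similar proteins and assign alignment columns
#'
#' Greedy single-linkage grouping: two proteins are joined when their global
#' alignment shows identity of at least `min_identity` over aligned columns
#' covering at least `min_coverage` of each sequence (identity is computed as
#' matches over columns where neither sequence is gapped); groups are the
#' transitive closure of this relation. Each group then receives a multiple
#' alignment (built-in center-star progressive alignment, or a user-supplied
#' aligned FASTA) so that interface residues can be compared through
#' alignment-column identifiers.
#'
#' @param proteins Tibble with columns `protein_id`, `seq`.
#' @param min_identity Minimum pairwise identity fraction (default 0.30).
#' @param min_coverage Minimum covered fraction of each sequence (default 0.90).
#' @param msa Optional named character vector of pre-aligned sequences (gaps
#'   as `-`, names are protein ids); overrides the built-in alignment for the
#'   proteins it covers when a whole cluster is covered.
#' @return Input tibble plus `cluster_id` (integer) and `columns` (list-column:
#'   integer alignment column of each residue position).
#' @export
cluster_proteins <- function(proteins, min_identity = 0.30, min_coverage = 0.90,
                             msa = NULL) {
  n <- nrow(proteins)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        p <- pairwise_identity(proteins$seq[[i]], proteins$seq[[j]])
        if (p$identity >= min_identity && p$coverage_a >= min_coverage &&
            p$coverage_b >= min_coverage) {
          edges <- rbind(edges, c(i, j))
        }
      }
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  cl <- igraph::components(g)$membership[seq_len(n)]
  proteins$cluster_id <- as.integer(cl)
  proteins$columns <- vector("list", n)
  for (cid in unique(proteins$cluster_id)) {
    idx <- which(proteins$cluster_id == cid)
    ids <- proteins$protein_id[idx]
    if (!is.null(msa) && all(ids %in% names(msa))) {
      proteins$columns[idx] <- map(msa[ids], function(a) {
        chars <- strsplit(a, "")[[1]]
        which(chars != "-")
      })
    } else {
      proteins$columns[idx] <- center_star_columns(proteins$seq[idx])
    }
  }
  proteins
}

#' Overlap between two semi-interfaces
#'
#' `O = |intersection| / min(|si_1|, |si_2|)` over alignment-column (or
#' position) identifiers. `O = 1` for identical sets, 0 for disjoint sets.
#'
#' @param si_1,si_2 Non-empty integer sets of residue identifiers.
#' @return Overlap value in `[0, 1]`.
#' @export
semi_interface_overlap <- function(si_1, si_2) {
  if (length(si_1) == 0 || length(si_2) == 0) abort("empty semi-interface")
  length(intersect(si_1, si_2)) / min(length(si_1), length(si_2))
}

#' Overlap between two homodimeric interfaces
#'
#' Each interface contributes two semi-interfaces on the same protein; since
#' either side of one dimer can be compared with either side of the other,
#' the numerator takes the side pairing that maximizes the shared identifier
#' count. The denominator is the total residue count of the smaller interface
#' (both sides summed).
#'
#' @param int_1,int_2 Lists of two non-empty identifier sets.
#' @return Overlap value in `[0, 1]`.
#' @export
interface_overlap_homo <- function(int_1, int_2) {
  if (any(lengths(int_1) == 0) || any(lengths(int_2) == 0)) {
    abort("empty semi-interface side")
  }
  straight <- length(intersect(int_1[[1]], int_2[[1]])) +
    length(intersect(int_1[[2]], int_2[[2]]))
  crossed <- length(intersect(int_1[[1]], int_2[[2]])) +
    length(intersect(int_1[[2]], int_2[[1]]))
  den <- min(length(int_1[[1]]) + length(int_1[[2]]),
             length(int_2[[1]]) + length(int_2[[2]]))
  max(straight, crossed) / den
}

#' Complete-linkage interface clustering at overlap 0.5
#'
#' Agglomerates on the distance `1 - O` with complete linkage and cuts the
#' tree at height 0.5, so that every pair within a flat cluster has overlap
#' `O >= 0.5` (the complete-linkage diameter guarantee).
#'
#' @param o_matrix Symmetric overlap matrix with unit diagonal.
#' @param h Cut height on the `1 - O` scale (default 0.5).
#' @return Integer vector of flat cluster labels.
#' @export
cluster_interfaces <- function(o_matrix, h = 0.5) {
  n <- nrow(o_matrix)
  if (n == 1) return(1L)
  tree <- hclust(as.dist(1 - o_matrix), method = "complete")
  as.integer(cutree(tree, h = h))
}

#' Elect the representative of an interface cluster
#'
#' Lexicographic criteria: largest chain coverage (for homodimers, product of
#' the two chains' coverages, precomputed by the caller), then best (lowest)
#' resolution, then largest residue count, then a random choice under the
#' session RNG. A missing resolution sorts worse than any numeric value.
#'
#' @param candidates Tibble with numeric columns `coverage`, `resolution`,
#'   `n_residues` (one row per cluster member).
#' @return Integer row index of the elected representative.
#' @export
elect_representative <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  cov <- ifelse(is.na(candidates$coverage), -Inf, candidates$coverage)
  res <- ifelse(is.na(candidates$resolution), Inf, candidates$resolution)
  idx <- which(cov == max(cov))
  idx <- idx[res[idx] == min(res[idx])]
  idx <- idx[candidates$n_residues[idx] == max(candidates$n_residues[idx])]
  if (length(idx) > 1) idx <- idx[runif_int(1, length(idx))]
  idx
}

#' Redundancy reduction of an interface set
#'
#' Full deduplication: proteins are grouped by sequence similarity
#' ([cluster_proteins()]); within each protein group, heterodimeric
#' semi-interfaces (and, separately, homodimeric whole interfaces) are mapped
#' to alignment columns, clustered by overlap ([cluster_interfaces()]), and
#' one representative is elected per flat cluster.
#'
#' @param interfaces Interface tibble ([extract_interface()] rows).
#' @param proteins Tibble `protein_id`, `seq` covering the interface proteins.
#' @inheritParams cluster_proteins
#' @return List with `hetero` (one row per semi-interface: `interface_row`,
#'   `side`, `protein_id`, `positions`, `coverage`, `resolution`,
#'   `protein_cluster`, `interface_cluster`, `representative`) and `homo`
#'   (one row per interface, analogous).
#' @export
dedupe_interfaces <- function(interfaces, proteins, min_identity = 0.30,
                              min_coverage = 0.90, msa = NULL) {
  pc <- cluster_proteins(proteins, min_identity, min_coverage, msa)
  colmap <- setNames(pc$columns, pc$protein_id)
  pcl <- setNames(pc$cluster_id, pc$protein_id)
  to_cols <- function(protein_id, positions) {
    unname(colmap[[protein_id]][positions])
  }

  het <- filter(interfaces, .data$kind == "hetero")
  hetero_units <- bind_rows(
    tibble(interface_row = which(interfaces$kind == "hetero"), side = "a",
           protein_id = het$protein_a, positions = het$positions_a,
           coverage = het$coverage_a, resolution = het$resolution),
    tibble(interface_row = which(interfaces$kind == "hetero"), side = "b",
           protein_id = het$protein_b, positions = het$positions_b,
           coverage = het$coverage_b, resolution = het$resolution)
  )
  if (nrow(hetero_units)) {
    hetero_units$protein_cluster <- unname(pcl[hetero_units$protein_id])
    hetero_units$cols <- map2(hetero_units$protein_id, hetero_units$positions,
                              to_cols)
    hetero_units <- hetero_units |>
      group_by(.data$protein_cluster) |>
      group_modify(function(d, key) {
        n <- nrow(d)
        o <- diag(1, n)
        if (n > 1) {
          for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
            o[i, j] <- o[j, i] <- semi_interface_overlap(d$cols[[i]], d$cols[[j]])
          }
        }
        d$interface_cluster <- cluster_interfaces(o)
        d$n_residues <- lengths(d$positions)
        d$representative <- FALSE
        for (cl in unique(d$interface_cluster)) {
          members <- which(d$interface_cluster == cl)
          win <- elect_representative(d[members, c("coverage", "resolution",
                                                   "n_residues")])
          d$representative[members[win]] <- TRUE
        }
        d
      }) |>
      ungroup() |>
      select(-"cols")
  }

  hom <- filter(interfaces, .data$kind == "homo")
  homo_units <- tibble(
    interface_row = which(interfaces$kind == "homo"),
    protein_id = hom$protein_a,
    positions_a = hom$positions_a, positions_b = hom$positions_b,
    coverage = hom$coverage_a * hom$coverage_b,
    resolution = hom$resolution
  )
  if (nrow(homo_units)) {
    homo_units$protein_cluster <- unname(pcl[homo_units$protein_id])
    homo_units$cols_a <- map2(homo_units$protein_id, homo_units$positions_a, to_cols)
    homo_units$cols_b <- map2(homo_units$protein_id, homo_units$positions_b, to_cols)
    homo_units <- homo_units |>
      group_by(.data$protein_cluster) |>
      group_modify(function(d, key) {
        n <- nrow(d)
        o <- diag(1, n)
        if (n > 1) {
          for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
            o[i, j] <- o[j, i] <- interface_overlap_homo(
              list(d$cols_a[[i]], d$cols_b[[i]]),
              list(d$cols_a[[j]], d$cols_b[[j]]))
          }
        }
        d$interface_cluster <- cluster_interfaces(o)
        d$n_residues <- lengths(d$positions_a) + lengths(d$positions_b)
        d$representative <- FALSE
        for (cl in unique(d$interface_cluster)) {
          members <- which(d$interface_cluster == cl)
          win <- elect_representative(d[members, c("coverage", "resolution",
                                                   "n_residues")])
          d$representative[members[win]] <- TRUE
        }
        d
      }) |>
      ungroup() |>
      select(-"cols_a", -"cols_b")
  }
  list(hetero = hetero_units, homo = homo_units)
}
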
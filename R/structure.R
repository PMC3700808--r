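#' Default van der Waals radii table
#'
#' Element radii (in Angstrom) used by the contact criterion: two residues on
#' different chains are in contact when any two of their atoms lie within
#' `r_vdw(a) + r_vdw(b) + margin`. The shipped values are the conventional
#' single-element radii for the atoms found in protein chains.
#'
#' @param path Optional path to a two-column TSV (`element`, `radius`) that
#'   replaces the built-in table.
#' @return Named numeric vector of radii in Angstrom.
#' @export
#' @examples
#' vdw_radii()[["C"]]
vdw_radii <- function(path = NULL) {
  if (is.null(path)) {
    return(c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    element = readr::col_character(), radius = readr::col_double()
  ))
  setNames(tab$radius, tab$element)
}

#' Read protein ATOM records from a PDB file
#'
#' Parses a PDB-format coordinate file and returns one row per ATOM record of
#' a protein chain. HETATM records (including waters) are excluded. When a
#' residue has alternate locations, the highest-occupancy conformer is kept
#' (ties broken by the alphabetically first altloc). Hydrogens are kept if
#' present.
#'
#' @param path Path to a PDB-format file.
#' @return Tibble with columns `chain_id`, `residue_number`, `insertion_code`,
#'   `residue_name`, `atom_name`, `element`, `x`, `y`, `z`, `occupancy`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM")
  is_het <- startsWith(lines, "HETATM")
  if (!any(is_atom) && !any(is_het)) {
    abort(paste0("no coordinate records found in '", path, "'"))
  }
  # contract check before delegating: coordinate fields must be parseable
  for (i in which(is_atom)) {
    ln <- lines[[i]]
    bad <- nchar(ln) < 54 ||
      anyNA(suppressWarnings(as.numeric(c(
        substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
      ))))
    if (bad) abort(paste0("malformed ATOM record at line ", i, " of '", path, "'"))
  }
  if (!any(is_atom)) {
    return(tibble(
      chain_id = character(), residue_number = integer(),
      insertion_code = character(), residue_name = character(),
      atom_name = character(), element = character(),
      x = double(), y = double(), z = double(), occupancy = double()
    ))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- as_tibble(pdb$atom)
  at <- filter(at, .data$type == "ATOM", !.data$resid %in% c("HOH", "WAT", "DOD"))
  at <- transmute(at,
    chain_id = as.character(.data$chain),
    residue_number = as.integer(.data$resno),
    insertion_code = ifelse(is.na(.data$insert), "", as.character(.data$insert)),
    residue_name = as.character(.data$resid),
    atom_name = as.character(.data$elety),
    altloc = ifelse(is.na(.data$alt), "", as.character(.data$alt)),
    element = toupper(trimws(ifelse(
      is.na(.data$elesy) | trimws(.data$elesy) == "",
      substr(trimws(.data$elety), 1, 1), .data$elesy
    ))),
    x = .data$x, y = .data$y, z = .data$z,
    occupancy = ifelse(is.na(.data$o), 1, .data$o)
  )
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")])))) {
    abort(paste0("non-finite coordinates in '", path, "'"))
  }
  # altloc: highest occupancy wins, ties by first letter
  at <- at |>
    group_by(.data$chain_id, .data$residue_number, .data$insertion_code,
             .data$atom_name) |>
    arrange(desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$chain_id, .data$residue_number, .data$insertion_code) |>
    select(-"altloc")
  at
}

res_key <- function(chain, resnum, icode) paste(chain, resnum, icode, sep = "|")

atom_radii <- function(elements, radii, fallback_radius) {
  r <- unname(radii[elements])
  unknown <- unique(elements[is.na(r)])
  if (length(unknown)) {
    if (is.null(fallback_radius) || is.na(fallback_radius)) {
      abort(paste0("no van der Waals radius for element(s): ",
                   paste(unknown, collapse = ", ")))
    }
    warn(paste0("using fallback radius ", fallback_radius, " A for element(s): ",
                paste(unknown, collapse = ", ")))
    r[is.na(r)] <- fallback_radius
  }
  r
}

#' Find contacting residue pairs between two chains
#'
#' A residue of chain A and a residue of chain B are in contact when at least
#' one atom pair lies within the sum of the two atoms' van der Waals radii
#' plus `margin` (default 0.5 Angstrom).
#'
#' @param atoms_a,atoms_b Atom tibbles as returned by [read_pdb()] (typically
#'   filtered to one chain each). Both must be non-empty.
#' @param radii Named radii vector, see [vdw_radii()].
#' @param margin Distance margin in Angstrom added to the radii sum.
#' @param fallback_radius Radius used (with a warning) for elements absent
#'   from `radii`; set to `NULL` to make unknown elements an error.
#' @return Tibble of unique contacting residue pairs with columns
#'   `chain_a`, `resnum_a`, `icode_a`, `chain_b`, `resnum_b`, `icode_b`.
#' @export
find_contact_residues <- function(atoms_a, atoms_b, radii = vdw_radii(),
                                  margin = 0.5, fallback_radius = 1.8) {
  stopifnot(margin >= 0)
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) {
    abort("both atom sets must be non-empty")
  }
  ra <- atom_radii(atoms_a$element, radii, fallback_radius)
  rb <- atom_radii(atoms_b$element, radii, fallback_radius)
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  thr2 <- outer(ra, rb, function(u, v) (u + v + margin)^2)
  hit <- which(d2 <= thr2 + 1e-12, arr.ind = TRUE)
  out <- tibble(
    chain_a = atoms_a$chain_id[hit[, 1]],
    resnum_a = atoms_a$residue_number[hit[, 1]],
    icode_a = atoms_a$insertion_code[hit[, 1]],
    chain_b = atoms_b$chain_id[hit[, 2]],
    resnum_b = atoms_b$residue_number[hit[, 2]],
    icode_b = atoms_b$insertion_code[hit[, 2]]
  )
  distinct(out)
}

#' Read a SIFTS-style chain-to-protein residue mapping
#'
#' @param path TSV with columns `structure_id`, `chain_id`, `pdb_resnum`,
#'   `pdb_icode`, `protein_id`, `protein_pos` (1-based canonical position).
#' @return Tibble with those columns; missing insertion codes become `""`.
#' @export
read_sifts <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    structure_id = readr::col_character(),
    chain_id = readr::col_character(),
    pdb_resnum = readr::col_integer(),
    pdb_icode = readr::col_character(),
    protein_id = readr::col_character(),
    protein_pos = readr::col_integer()
  ))
  m$pdb_icode[is.na(m$pdb_icode)] <- ""
  dup <- m |> count(.data$structure_id, .data$chain_id, .data$pdb_resnum,
                    .data$pdb_icode) |>
    filter(.data$n > 1)
  if (nrow(dup)) abort("chain-to-protein mapping is not injective per chain")
  m
}

map_side <- function(keys, map, side) {
  hit <- match(res_key(keys$chain, keys$resnum, keys$icode),
               res_key(map$chain_id, map$pdb_resnum, map$pdb_icode))
  n_unmapped <- sum(is.na(hit))
  if (all(is.na(hit))) {
    abort(paste0("no contacting residue on side ", side,
                 " could be mapped to a protein position"))
  }
  if (n_unmapped > 0) {
    warn(paste0(n_unmapped, " contacting residue(s) on side ", side,
                " had no protein mapping and were dropped"))
  }
  hit <- hit[!is.na(hit)]
  pid <- unique(map$protein_id[hit])
  if (length(pid) != 1) {
    abort(paste0("side ", side, " maps to more than one protein: ",
                 paste(pid, collapse = ", ")))
  }
  list(protein_id = pid,
       positions = sort(unique(map$protein_pos[hit])),
       n_unmapped = n_unmapped)
}

chain_coverage <- function(map, chain, protein_id, protein_lengths) {
  if (is.null(protein_lengths)) return(NA_real_)
  if (is.data.frame(protein_lengths)) {
    protein_lengths <- setNames(protein_lengths$length, protein_lengths$protein_id)
  }
  len <- protein_lengths[[protein_id]]
  if (is.null(len)) return(NA_real_)
  n_obs <- map |>
    filter(.data$chain_id == chain) |>
    distinct(.data$protein_pos) |> nrow()
  n_obs / len
}

#' Build an interface record from contacts and residue mappings
#'
#' Converts the contacting residues of a chain pair into canonical-protein
#' positions (one semi-interface per side). The record is heterodimeric when
#' the two sides map to different proteins and homodimeric otherwise.
#' Contacting residues without a mapping entry are dropped with a warning;
#' the per-side dropped counts are returned in `n_unmapped_a`/`n_unmapped_b`.
#'
#' @param contacts Output of [find_contact_residues()].
#' @param map_a,map_b Mapping tibbles in [read_sifts()] layout for each side's
#'   chain.
#' @param structure_id,resolution Structure metadata carried into the record.
#' @param protein_lengths Optional named vector (or tibble `protein_id`,
#'   `length`) of canonical protein lengths; enables the chain-coverage
#'   fractions, otherwise `coverage_a`/`coverage_b` are `NA`.
#' @return One-row tibble: `kind` ("hetero"/"homo"), `structure_id`,
#'   `protein_a`, `positions_a`, `hotspots_a`, `protein_b`, `positions_b`,
#'   `hotspots_b` (list-columns of integer positions), `resolution`,
#'   `coverage_a`, `coverage_b`, `n_unmapped_a`, `n_unmapped_b`.
#' @export
extract_interface <- function(contacts, map_a, map_b, structure_id = NA_character_,
                              resolution = NA_real_, protein_lengths = NULL) {
  if (nrow(contacts) == 0) abort("no contacts to extract an interface from")
  side_a <- map_side(
    list(chain = contacts$chain_a, resnum = contacts$resnum_a, icode = contacts$icode_a),
    map_a, "a")
  side_b <- map_side(
    list(chain = contacts$chain_b, resnum = contacts$resnum_b, icode = contacts$icode_b),
    map_b, "b")
  kind <- if (identical(side_a$protein_id, side_b$protein_id)) "homo" else "hetero"
  tibble(
    kind = kind,
    structure_id = structure_id,
    protein_a = side_a$protein_id,
    positions_a = list(side_a$positions),
    hotspots_a = list(integer(0)),
    protein_b = side_b$protein_id,
    positions_b = list(side_b$positions),
    hotspots_b = list(integer(0)),
    resolution = resolution,
    coverage_a = chain_coverage(map_a, contacts$chain_a[[1]], side_a$protein_id,
                                protein_lengths),
    coverage_b = chain_coverage(map_b, contacts$chain_b[[1]], side_b$protein_id,
                                protein_lengths),
    n_unmapped_a = side_a$n_unmapped,
    n_unmapped_b = side_b$n_unmapped
  )
}

#' Apply the interface inclusion filters
#'
#' An interface is kept only when both sides contribute at least `min_side`
#' residues, both chains cover at least `min_coverage` of their canonical
#' protein sequence, and the chain pair passed the biological-unit orientation
#' check. A missing (`NA`) coverage is treated as unknown and does not drop
#' the record.
#'
#' @param interfaces Tibble of interface records ([extract_interface()] rows).
#' @param min_side Minimum residues per side (default 5).
#' @param min_coverage Minimum chain coverage fraction (default 0.30).
#' @param biounit_ok Logical scalar or vector: chain pair confirmed in a
#'   biological unit (consumed as a precomputed flag). If the tibble has a
#'   `biounit_ok` column it takes precedence.
#' @return Input tibble plus `keep` (logical) and `drop_reasons` (comma-joined
#'   codes among `MIN_SIDE`, `COVERAGE`, `BIOUNIT`; `""` when kept).
#' @export
apply_inclusion_filters <- function(interfaces, min_side = 5, min_coverage = 0.30,
                                    biounit_ok = TRUE) {
  if ("biounit_ok" %in% names(interfaces)) {
    biounit_ok <- interfaces$biounit_ok
  }
  biounit_ok <- rep_len(biounit_ok, nrow(interfaces))
  na <- map_int(interfaces$positions_a, length)
  nb <- map_int(interfaces$positions_b, length)
  small <- na < min_side | nb < min_side
  lowcov <-
    (!is.na(interfaces$coverage_a) & interfaces$coverage_a < min_coverage) |
    (!is.na(interfaces$coverage_b) & interfaces$coverage_b < min_coverage)
  reasons <- pmap(list(small, lowcov, !biounit_ok), function(s, c, b) {
    c(if (s) "MIN_SIDE", if (c) "COVERAGE", if (b) "BIOUNIT")
  })
  interfaces$keep <- !small & !lowcov & biounit_ok
  interfaces$drop_reasons <- map_chr(reasons, paste, collapse = ",")
  interfaces
}
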
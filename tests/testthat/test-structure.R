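test_that("toy structures round-trip through the PDB parser", {
  set.seed(1)
  toy <- emit_toy_structure(c(3, 5, 9), c(2, 4, 6, 8), 20, 15)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toy$pdb, tf)
  atoms <- read_pdb(tf)
  expect_equal(nrow(atoms), 35)
  expect_setequal(unique(atoms$chain_id), c("A", "B"))
  expect_true(all(atoms$element == "C"))
})

test_that("HETATM-only files give an empty atom table, empty files error", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 501      10.000  10.000  10.000  1.00  0.00           O",
    "END"), tf)
  expect_equal(nrow(read_pdb(tf)), 0)
  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), tf2)
  expect_error(read_pdb(tf2), "no coordinate records")
})

test_that("a truncated coordinate field is a parse error naming the line", {
  set.seed(1)
  toy <- emit_toy_structure(c(2, 4), c(3, 5), 10, 10)
  lines <- toy$pdb
  lines[4] <- substr(lines[4], 1, 40)
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  expect_error(read_pdb(tf), "line 4")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       5.000   0.000   0.000  1.00  0.00           C",
    "END"), tf)
  atoms <- read_pdb(tf)
  expect_equal(nrow(atoms), 2)
  expect_equal(atoms$x[atoms$residue_number == 1], 9)
})

test_that("contact decision follows the radii-sum-plus-margin threshold", {
  a <- atoms_tbl("A", 1, 0)
  expect_equal(nrow(find_contact_residues(a, atoms_tbl("B", 1, 3.89))), 1)
  expect_equal(nrow(find_contact_residues(a, atoms_tbl("B", 1, 3.91))), 0)
  # unknown element: fallback with warning, or error when disabled
  expect_warning(find_contact_residues(a, atoms_tbl("B", 1, 3.0, element = "ZZ")),
                 "fallback")
  expect_error(
    find_contact_residues(a, atoms_tbl("B", 1, 3.0, element = "ZZ"),
                          fallback_radius = NULL),
    "ZZ")
  expect_error(find_contact_residues(a[0, ], a), "non-empty")
})

test_that("contact detection equals the brute-force all-pairs oracle", {
  radii <- vdw_radii()
  for (rep in 1:5) {
    set.seed(rep)
    na <- 50; nb <- 50
    a <- atoms_tbl("A", sample(1:20, na, TRUE), runif(na, 0, 15),
                   runif(na, 0, 15), runif(na, 0, 15),
                   element = sample(c("C", "N", "O", "S"), na, TRUE))
    b <- atoms_tbl("B", sample(1:20, nb, TRUE), runif(nb, 0, 15),
                   runif(nb, 0, 15), runif(nb, 0, 15),
                   element = sample(c("C", "N", "O", "S"), nb, TRUE))
    got <- find_contact_residues(a, b) |> arrange(resnum_a, resnum_b)
    want <- list()
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - c(b$x[j], b$y[j], b$z[j]))^2))
      if (d <= radii[[a$element[i]]] + radii[[b$element[j]]] + 0.5) {
        want[[length(want) + 1]] <- c(a$residue_number[i], b$residue_number[j])
      }
    }
    want <- unique(do.call(rbind, want))
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(cbind(got$resnum_a, got$resnum_b), unname(want))
  }
})

sample_map <- function(chain, resnums, protein_id, offset = 0L) {
  tibble(structure_id = "S", chain_id = chain, pdb_resnum = resnums,
         pdb_icode = "", protein_id = protein_id,
         protein_pos = resnums + offset)
}

test_that("interface extraction maps contacts and sets the dimer kind", {
  contacts <- tibble(chain_a = "A", resnum_a = 1:6, icode_a = "",
                     chain_b = "B", resnum_b = rep(1:7, length.out = 6),
                     icode_b = "")
  contacts <- bind_rows(contacts, tibble(chain_a = "A", resnum_a = 1,
                                         icode_a = "", chain_b = "B",
                                         resnum_b = 7, icode_b = ""))
  rec <- extract_interface(contacts, sample_map("A", 1:10, "P1", 5L),
                           sample_map("B", 1:10, "P2"))
  expect_equal(rec$kind, "hetero")
  expect_length(rec$positions_a[[1]], 6)
  expect_length(rec$positions_b[[1]], 7)
  expect_equal(rec$positions_a[[1]], 6:11)  # offset mapping applied

  rec2 <- extract_interface(contacts, sample_map("A", 1:10, "P1"),
                            sample_map("B", 1:10, "P1"))
  expect_equal(rec2$kind, "homo")
})

test_that("unmapped contacting residues are dropped with a count, all-unmapped errors", {
  contacts <- tibble(chain_a = "A", resnum_a = 1:6, icode_a = "",
                     chain_b = "B", resnum_b = 1:6, icode_b = "")
  expect_warning(
    rec <- extract_interface(contacts, sample_map("A", 1:4, "P1"),
                             sample_map("B", 1:10, "P2")),
    "2 contacting")
  expect_length(rec$positions_a[[1]], 4)
  expect_equal(rec$n_unmapped_a, 2L)
  expect_error(
    suppressWarnings(
      extract_interface(contacts, sample_map("A", 7:9, "P1"),
                        sample_map("B", 1:10, "P2"))),
    "side a")
})

test_that("inclusion filters apply the size, coverage and biounit rules", {
  rec <- function(na, nb, cov_a, cov_b) {
    tibble(kind = "hetero", structure_id = "S", protein_a = "P1",
           positions_a = list(seq_len(na)), hotspots_a = list(integer(0)),
           protein_b = "P2", positions_b = list(seq_len(nb)),
           hotspots_b = list(integer(0)), resolution = 2,
           coverage_a = cov_a, coverage_b = cov_b)
  }
  out <- apply_inclusion_filters(bind_rows(
    rec(5, 5, 0.31, 0.90), rec(5, 4, 0.31, 0.90), rec(5, 5, 0.25, 0.90)))
  expect_equal(out$keep, c(TRUE, FALSE, FALSE))
  expect_equal(out$drop_reasons, c("", "MIN_SIDE", "COVERAGE"))
  out2 <- apply_inclusion_filters(rec(6, 6, 0.9, 0.9), biounit_ok = FALSE)
  expect_equal(out2$drop_reasons, "BIOUNIT")
})

test_that("filters are monotone in min_side and min_coverage", {
  set.seed(42)
  for (i in 1:50) {
    r <- tibble(kind = "hetero", structure_id = "S", protein_a = "P1",
                positions_a = list(seq_len(sample(1:12, 1))),
                hotspots_a = list(integer(0)), protein_b = "P2",
                positions_b = list(seq_len(sample(1:12, 1))),
                hotspots_b = list(integer(0)), resolution = 2,
                coverage_a = runif(1), coverage_b = runif(1))
    lo <- apply_inclusion_filters(r, min_side = 3, min_coverage = 0.2)$keep
    hi <- apply_inclusion_filters(r, min_side = 6, min_coverage = 0.5)$keep
    expect_false(!lo && hi)
  }
})
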
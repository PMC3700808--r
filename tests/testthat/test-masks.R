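# reference gene on the plus strand: exons of the given codon counts
# separated by 100-nt introns
ref_exons <- function(codons, gene_id = "G", transcript_id = "G.ref",
                      strand = "+") {
  nt <- codons * 3L
  gstart <- cumsum(c(0L, head(nt, -1) + 100L))
  if (strand == "-") {
    total <- sum(nt) + 100L * (length(nt) - 1L)
    gstart <- total - (gstart + nt)
  }
  tibble(gene_id = gene_id, transcript_id = transcript_id, strand = strand,
         start = as.integer(gstart), end = as.integer(gstart + nt),
         is_nmd = FALSE)
}

drop_exons <- function(exons, which, transcript_id) {
  out <- if (length(which)) exons[-which, ] else exons
  out$transcript_id <- transcript_id
  out
}

test_that("masks mark exactly the codons whose bases the alternative lacks", {
  for (strand in c("+", "-")) {
    ref <- ref_exons(c(10, 15, 20, 5), strand = strand)
    expect_equal(build_isoform_mask(ref, drop_exons(ref, integer(0), "G.i0")),
                 integer(50))
    # second exon codes residues 11..25
    bits <- build_isoform_mask(ref, drop_exons(ref, 2, "G.i1"))
    expect_equal(which(bits == 1L), 11:25)
    # first 10 codons absent (alternative starts downstream, same remainder)
    bits2 <- build_isoform_mask(ref, drop_exons(ref, 1, "G.i2"))
    expect_equal(which(bits2 == 1L), 1:10)
  }
})

test_that("a residue is missing when any base of its codon is absent", {
  ref <- ref_exons(c(10, 10))
  alt <- drop_exons(ref, integer(0), "G.i")
  alt$end[1] <- alt$end[1] - 1L  # clip one base of codon 10
  bits <- build_isoform_mask(ref, alt)
  expect_equal(which(bits == 1L), 10L)
})

test_that("mask construction validates gene, strand and frame", {
  ref <- ref_exons(c(10, 10))
  alt <- drop_exons(ref, integer(0), "X.i"); alt$gene_id <- "X"
  expect_error(build_isoform_mask(ref, alt), "same gene")
  bad <- ref; bad$end[1] <- bad$end[1] + 1L
  expect_error(build_isoform_mask(bad, drop_exons(ref, integer(0), "G.i")),
               "divisible by 3")
})

test_that("mask bits are monotone under removal of further exon bases", {
  set.seed(3)
  for (i in 1:20) {
    ref <- ref_exons(sample(3:12, 5, TRUE))
    k1 <- sample(2:4, 1)
    bits1 <- build_isoform_mask(ref, drop_exons(ref, k1, "G.i1"))
    k2 <- sample(setdiff(2:4, k1), 1)
    bits2 <- build_isoform_mask(ref, drop_exons(ref, c(k1, k2), "G.i2"))
    expect_true(all(bits2 >= bits1))
  }
})

test_that("stretch decomposition follows the missing/non-missing definitions", {
  d <- decompose_mask(c(0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(d$missing, tibble(start = c(4L, 9L), length = c(3L, 2L)))
  expect_equal(d$non_missing, tibble(start = 7L, length = 2L))
  expect_equal(d$variable_region, c(4L, 10L))

  z <- decompose_mask(integer(8))
  expect_equal(nrow(z$missing), 0)
  expect_null(z$variable_region)
  expect_equal(z$coverage, 1)

  o <- decompose_mask(rep(1L, 6))
  expect_equal(o$missing, tibble(start = 1L, length = 6L))
  expect_equal(o$variable_region, c(1L, 6L))
})

test_that("decompose/reconstruct is the identity and coverage matches", {
  set.seed(5)
  for (i in 1:2000) {
    bits <- random_mask(sample(10:80, 1))
    d <- decompose_mask(bits)
    expect_identical(reconstruct_mask(d, length(bits)), bits)
    expect_equal(d$coverage, 1 - sum(d$missing$length) / length(bits))
  }
})

test_that("run-length serialization round-trips, also through TSV", {
  expect_equal(encode_mask_rle(c(0L, 0L, 1L, 1L, 1L, 0L)), "0:2,1:3,0:1")
  set.seed(6)
  masks <- tibble(protein_id = "P", isoform_id = paste0("i", 1:20),
                  bits = lapply(1:20, function(i) random_mask(60)))
  for (b in masks$bits) expect_identical(decode_mask_rle(encode_mask_rle(b)), b)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_masks_tsv(masks, tf)
  back <- read_masks_tsv(tf)
  expect_identical(back$bits, masks$bits)
})

test_that("reference transcript selection prefers identity, bounds differences", {
  pseq <- "ACDEFGHIKLMNPQRSTVWY"
  cand <- tibble(transcript_id = c("t2", "t1"), seq = c(pseq, pseq))
  sel <- select_reference_transcript(pseq, cand)
  expect_equal(sel$transcript_id, "t1")  # lexicographic tie-break
  expect_equal(sel$reason, "identical")

  # six separated substitutions -> too different under the default bound
  too_far <- "AVDEVGHVKLVNPVRSVVWY"
  sel2 <- select_reference_transcript(pseq, tibble(transcript_id = "t",
                                                   seq = too_far))
  expect_true(is.na(sel2$transcript_id))
  expect_equal(sel2$reason, "too_different")

  # one internal deletion -> similar
  sel3 <- select_reference_transcript(
    pseq, tibble(transcript_id = "t", seq = "ACDEFGHIKLMNPQVWY"))
  expect_equal(sel3$reason, "similar")
  expect_equal(sel3$n_differences, 1L)

  expect_equal(select_reference_transcript(pseq, cand[0, ])$reason,
               "no_candidates")
})

test_that("alternative isoform enumeration excludes reference, NMD and identical CDS", {
  ref <- ref_exons(c(5, 5, 5))
  alt1 <- drop_exons(ref, 2, "G.i1")
  nmd <- drop_exons(ref, 2, "G.nmd"); nmd$is_nmd <- TRUE
  same <- drop_exons(ref, integer(0), "G.same")  # identical CDS to reference
  exons <- bind_rows(ref, alt1, nmd, same)
  out <- enumerate_alternative_isoforms(exons, "G.ref")
  expect_equal(unique(out$transcript_id), "G.i1")

  # transcripts sharing one coding sequence distinct from the reference are
  # all retained
  shared <- bind_rows(ref, lapply(1:4, function(k) drop_exons(ref, 2,
                                                              paste0("G.s", k))))
  out2 <- enumerate_alternative_isoforms(shared, "G.ref")
  expect_length(unique(out2$transcript_id), 4)

  expect_equal(nrow(enumerate_alternative_isoforms(ref, "G.ref")), 0)
  expect_error(enumerate_alternative_isoforms(ref, "nope"), "not present")
})

test_that("CDS features read from GTF match the exon TSV dialect", {
  ref <- ref_exons(c(4, 6, 5))
  alt <- drop_exons(ref, 2, "G.i1")
  nmd <- drop_exons(ref, 2, "G.nmd")
  gtf_row <- function(e, biotype) {
    sprintf(paste0('chr1\ttest\tCDS\t%d\t%d\t.\t%s\t0\tgene_id "%s"; ',
                   'transcript_id "%s"; transcript_biotype "%s";'),
            e$start + 1L, e$end, e$strand, e$gene_id, e$transcript_id, biotype)
  }
  lines <- c(
    unlist(lapply(seq_len(nrow(ref)), function(i) gtf_row(ref[i, ],
                                                          "protein_coding"))),
    unlist(lapply(seq_len(nrow(alt)), function(i) gtf_row(alt[i, ],
                                                          "protein_coding"))),
    unlist(lapply(seq_len(nrow(nmd)), function(i)
      gtf_row(nmd[i, ], "nonsense_mediated_decay")))
  )
  tf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(lines, tf)
  exons <- read_cds_gff(tf)
  expect_setequal(unique(exons$transcript_id), c("G.ref", "G.i1", "G.nmd"))
  expect_true(all(exons$is_nmd[exons$transcript_id == "G.nmd"]))
  ref_back <- filter(exons, transcript_id == "G.ref") |>
    select(gene_id, transcript_id, strand, start, end)
  expect_equal(as.data.frame(ref_back),
               as.data.frame(select(ref, -is_nmd)))
  # the NMD transcript is excluded downstream, the other alternative kept
  kept <- enumerate_alternative_isoforms(exons, "G.ref")
  expect_equal(unique(kept$transcript_id), "G.i1")
  bits <- build_isoform_mask(filter(exons, transcript_id == "G.ref"),
                             filter(exons, transcript_id == "G.i1"))
  expect_equal(which(bits == 1L), 5:10)
})

test_that("exon TSV IO converts between 1-based inclusive and internal", {
  ref <- ref_exons(c(4, 6))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_exon_tsv(ref, tf)
  raw <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(raw$exon_start, ref$start + 1L)
  expect_equal(raw$exon_end, ref$end)
  expect_equal(as.data.frame(read_exon_tsv(tf)), as.data.frame(ref))
})
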
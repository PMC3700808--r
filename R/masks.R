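#' Read the simplified coding-exon TSV dialect
#'
#' One row per coding exon with columns `gene_id`, `transcript_id`, `strand`
#' (`+`/`-`), `exon_start`, `exon_end` (1-based, inclusive, genomic), and
#' `is_nmd` (logical: transcript subject to nonsense-mediated decay). Rows
#' must be ordered 5' to 3' within a transcript. Coordinates are converted to
#' the package's internal convention (0-based, half-open `start`/`end`).
#'
#' @param path TSV path.
#' @return Tibble `gene_id`, `transcript_id`, `strand`, `start`, `end`,
#'   `is_nmd`, ordered 5' to 3' within transcript.
#' @export
read_exon_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    transcript_id = readr::col_character(),
    strand = readr::col_character(),
    exon_start = readr::col_integer(),
    exon_end = readr::col_integer(),
    is_nmd = readr::col_logical()
  ))
  transmute(tab,
    gene_id = .data$gene_id, transcript_id = .data$transcript_id,
    strand = .data$strand,
    start = .data$exon_start - 1L, end = .data$exon_end,
    is_nmd = .data$is_nmd
  )
}

#' @rdname read_exon_tsv
#' @param exons Internal-convention exon tibble.
#' @export
write_exon_tsv <- function(exons, path) {
  out <- transmute(exons,
    gene_id = .data$gene_id, transcript_id = .data$transcript_id,
    strand = .data$strand,
    exon_start = .data$start + 1L, exon_end = .data$end,
    is_nmd = .data$is_nmd
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read coding exons from a GTF/GFF file
#'
#' Imports `CDS` features whose attributes carry `transcript_id` and
#' `gene_id` (the GTF convention; Ensembl-style GFF3 with those attributes
#' also works) and converts them to the internal exon layout. Transcripts
#' whose `transcript_biotype` attribute equals
#' `"nonsense_mediated_decay"` are flagged `is_nmd`.
#'
#' @param path GTF/GFF3 path.
#' @return Exon tibble as from [read_exon_tsv()].
#' @export
read_cds_gff <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(gr) == 0) abort("no CDS features found")
  md <- as.data.frame(gr)
  if (!all(c("transcript_id", "gene_id") %in% names(md))) {
    abort("CDS features must carry transcript_id and gene_id attributes")
  }
  nmd <- if ("transcript_biotype" %in% names(md)) {
    !is.na(md$transcript_biotype) &
      md$transcript_biotype == "nonsense_mediated_decay"
  } else rep(FALSE, nrow(md))
  out <- tibble(
    gene_id = md$gene_id, transcript_id = md$transcript_id,
    strand = as.character(md$strand),
    start = as.integer(md$start - 1L), end = as.integer(md$end),
    is_nmd = nmd
  )
  # order exons 5' to 3' within each transcript
  out |>
    group_by(.data$transcript_id) |>
    arrange(if (first(.data$strand) == "-") dplyr::desc(.data$start)
            else .data$start, .by_group = TRUE) |>
    ungroup()
}

# genomic positions (0-based) of each CDS base in translation (5'->3') order
cds_base_positions <- function(exons) {
  strand <- unique(exons$strand)
  if (length(strand) != 1) abort("transcript exons must share one strand")
  pos <- Map(function(s, e) {
    if (e <= s) abort("empty exon interval")
    if (strand == "+") s:(e - 1L) else (e - 1L):s
  }, exons$start, exons$end)
  as.integer(unlist(pos))
}

#' Build a two-bit isoform mask over the canonical protein
#'
#' Residue i of the canonical protein is marked missing (bit 1) when any of
#' the three genomic bases of its codon is absent from the alternative
#' transcript's coding exons, and present (bit 0) otherwise. The comparison is
#' purely coordinate-based: the two transcripts are aligned through the
#' genomic coordinates of their coding sequences.
#'
#' @param reference,alternative Coding-exon tibbles (internal convention, one
#'   transcript each, rows 5' to 3'); must share gene and strand.
#' @return Integer vector of 0/1 bits of length `CDS length / 3`.
#' @export
build_isoform_mask <- function(reference, alternative) {
  if (!identical(unique(reference$gene_id), unique(alternative$gene_id))) {
    abort("reference and alternative must belong to the same gene")
  }
  if (!identical(unique(reference$strand), unique(alternative$strand))) {
    abort("reference and alternative must share the strand")
  }
  pos <- cds_base_positions(reference)
  if (length(pos) %% 3L != 0L) {
    abort("reference CDS length is not divisible by 3")
  }
  alt <- arrange(alternative, .data$start)
  idx <- findInterval(pos, alt$start)
  base_present <- idx > 0L & pos < alt$end[pmax(idx, 1L)]
  as.integer(colSums(matrix(!base_present, nrow = 3L)) > 0L)
}

#' Decompose a mask into missing stretches, non-missing stretches and the
#' variable region
#'
#' A missing stretch is a maximal run of 1-bits (a contiguous protein region
#' removed by splicing); a non-missing stretch is a run of retained residues
#' lying strictly between two missing stretches; the variable region spans
#' from the start of the first missing stretch to the end of the last one.
#'
#' @param bits Integer 0/1 vector (1 = residue missing in the isoform).
#' @return List with `missing` and `non_missing` (tibbles of 1-based `start`,
#'   `length`), `variable_region` (integer `c(start, end)`, or `NULL` for an
#'   all-zero mask), and `coverage` (fraction of 0-bits).
#' @export
#' @examples
#' decompose_mask(c(0, 0, 0, 1, 1, 1, 0, 0, 1, 1, 0, 0, 0))
decompose_mask <- function(bits) {
  stopifnot(all(bits %in% c(0L, 1L)))
  L <- length(bits)
  r <- rle(as.integer(bits))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  miss <- tibble(start = starts[r$values == 1L], length = r$lengths[r$values == 1L])
  if (nrow(miss) == 0) {
    return(list(missing = miss, non_missing = miss[0, ],
                variable_region = NULL, coverage = 1))
  }
  vr <- c(miss$start[1], miss$start[nrow(miss)] + miss$length[nrow(miss)] - 1L)
  inside <- r$values == 0L & starts > vr[1] & ends < vr[2]
  list(
    missing = miss,
    non_missing = tibble(start = starts[inside], length = r$lengths[inside]),
    variable_region = as.integer(vr),
    coverage = sum(bits == 0L) / L
  )
}

#' Rebuild a mask from its stretch decomposition
#'
#' @param decomposition Output of [decompose_mask()].
#' @param length Canonical protein length.
#' @return Integer 0/1 vector.
#' @export
reconstruct_mask <- function(decomposition, length) {
  bits <- integer(length)
  m <- decomposition$missing
  for (i in seq_len(nrow(m))) {
    bits[m$start[i]:(m$start[i] + m$length[i] - 1L)] <- 1L
  }
  bits
}

#' Fraction of the canonical protein retained by an isoform
#' @param bits Mask bit vector.
#' @export
mask_coverage <- function(bits) mean(bits == 0L)

#' Run-length mask serialization
#'
#' Masks are serialized as `"0:10,1:5,0:85"` (bit:value run lengths).
#'
#' @param bits Integer 0/1 vector.
#' @export
encode_mask_rle <- function(bits) {
  r <- rle(as.integer(bits))
  paste(paste0(r$values, ":", r$lengths), collapse = ",")
}

#' @rdname encode_mask_rle
#' @param txt Serialized run-length string.
#' @export
decode_mask_rle <- function(txt) {
  parts <- strsplit(strsplit(txt, ",")[[1]], ":")
  unlist(map(parts, function(p) rep(as.integer(p[1]), as.integer(p[2]))))
}

#' Read/write isoform masks as TSV
#'
#' Columns: `protein_id`, `isoform_id`, `bits` (run-length string, see
#' [encode_mask_rle()]). In memory the `bits` column is a list-column of
#' integer vectors.
#'
#' @param path TSV path.
#' @export
read_masks_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    isoform_id = readr::col_character(),
    bits = readr::col_character()
  ))
  mutate(tab, bits = map(.data$bits, decode_mask_rle))
}

#' @rdname read_masks_tsv
#' @param masks Mask tibble (`protein_id`, `isoform_id`, list-column `bits`).
#' @export
write_masks_tsv <- function(masks, path) {
  out <- mutate(masks, bits = map_chr(.data$bits, encode_mask_rle))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Select the reference transcript for a canonical protein
#'
#' Prefers a candidate whose translated sequence is identical to the
#' canonical protein; otherwise the most similar candidate with at most
#' `max_diffs` non-contiguous differences (maximal runs of gap or
#' substitution columns in the global alignment); otherwise none. Ties are
#' broken by the lexicographically smallest transcript id.
#'
#' @param protein_seq Canonical protein sequence.
#' @param candidates Tibble with columns `transcript_id` and `seq` (translated
#'   candidate sequences).
#' @param max_diffs Maximum allowed non-contiguous differences (default 5).
#' @return One-row tibble: `transcript_id` (`NA` if none qualifies),
#'   `n_differences`, `reason` (`"identical"`, `"similar"`,
#'   `"too_different"`, or `"no_candidates"`).
#' @export
select_reference_transcript <- function(protein_seq, candidates, max_diffs = 5) {
  none <- function(reason) {
    tibble(transcript_id = NA_character_, n_differences = NA_integer_,
           reason = reason)
  }
  if (is.null(candidates) || nrow(candidates) == 0) return(none("no_candidates"))
  exact <- candidates$transcript_id[candidates$seq == protein_seq]
  if (length(exact)) {
    return(tibble(transcript_id = sort(exact)[1], n_differences = 0L,
                  reason = "identical"))
  }
  scored <- candidates |>
    mutate(aln = map(.data$seq, ~ global_align(protein_seq, .x)),
           n_differences = map_int(.data$aln, ~ as.integer(.x$n_differences)),
           score = map_dbl(.data$aln, "score")) |>
    filter(.data$n_differences <= max_diffs) |>
    arrange(.data$n_differences, desc(.data$score), .data$transcript_id)
  if (nrow(scored) == 0) return(none("too_different"))
  tibble(transcript_id = scored$transcript_id[1],
         n_differences = scored$n_differences[1], reason = "similar")
}

#' Enumerate the alternative splicing isoforms of a gene
#'
#' Returns every full-length coding transcript of the gene except the
#' reference, transcripts flagged for nonsense-mediated decay, and
#' transcripts encoding a protein identical to the reference. Without
#' sequence information, "identical protein" is decided by an identical
#' coding-exon interval set; supply `translations` (named character vector,
#' transcript id to protein sequence) to decide it at sequence level.
#'
#' @param exons Exon tibble for one gene (internal convention, possibly many
#'   transcripts).
#' @param reference_id Transcript id of the reference.
#' @param translations Optional named translated sequences.
#' @return Exon tibble restricted to the retained alternative transcripts.
#' @export
enumerate_alternative_isoforms <- function(exons, reference_id, translations = NULL) {
  ids <- unique(exons$transcript_id)
  if (!reference_id %in% ids) abort("reference transcript not present in gene")
  cds_sig <- function(id) {
    e <- arrange(filter(exons, .data$transcript_id == id), .data$start)
    paste(e$start, e$end, sep = "-", collapse = ";")
  }
  ref_sig <- cds_sig(reference_id)
  keep <- map_lgl(ids, function(id) {
    if (id == reference_id) return(FALSE)
    if (any(exons$is_nmd[exons$transcript_id == id])) return(FALSE)
    if (!is.null(translations) && !is.null(translations[[id]]) &&
        !is.null(translations[[reference_id]])) {
      return(translations[[id]] != translations[[reference_id]])
    }
    cds_sig(id) != ref_sig
  })
  filter(exons, .data$transcript_id %in% ids[keep])
}
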
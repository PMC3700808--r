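#' Poisson pulsing of stretch sizes
#'
#' Each stretch receives a new size drawn from a Poisson distribution with
#' mean equal to its real size, independently. Zero draws are allowed (the
#' stretch vanishes), so the expected total size is preserved exactly.
#'
#' @param sizes Positive integer vector of real stretch sizes.
#' @return Integer vector of pulsed sizes (same length).
#' @export
pulse_sizes <- function(sizes) {
  stopifnot(all(sizes >= 1))
  rpois(length(sizes), sizes)
}

# variable-region layout of a mask: alternating stretch sizes, starting and
# ending with a missing stretch
mask_layout <- function(bits) {
  d <- decompose_mask(bits)
  if (nrow(d$missing) == 0) abort("mask has no missing stretch; no decoy defined")
  vr <- d$variable_region
  r <- rle(as.integer(bits[vr[1]:vr[2]]))
  list(sizes = as.integer(r$lengths), status = as.integer(r$values),
       L = length(bits), vr_start = vr[1])
}

layout_to_bits <- function(sizes, status, start, L) {
  bits <- integer(L)
  offs <- start + cumsum(c(0L, sizes[-length(sizes)]))
  for (j in which(status == 1L & sizes > 0L)) {
    bits[offs[j]:(offs[j] + sizes[j] - 1L)] <- 1L
  }
  bits
}

# vectorized draw of n pulsed layouts for one variable region; rejects draws
# whose pulsed variable region is empty or longer than the protein
sample_decoy_layouts <- function(sizes, L, n, max_attempts = 1000) {
  k <- length(sizes)
  S <- matrix(rpois(n * k, rep(sizes, each = n)), nrow = n)
  v <- rowSums(S)
  attempt <- 1L
  while (any(bad <- v == 0L | v > L)) {
    if (attempt >= max_attempts) {
      abort("max_attempts exhausted while drawing decoy stretch sizes")
    }
    nb <- sum(bad)
    S[bad, ] <- matrix(rpois(nb * k, rep(sizes, each = nb)), nrow = nb)
    v <- rowSums(S)
    attempt <- attempt + 1L
  }
  starts <- runif_int(n, L - v + 1L)
  list(sizes = S, starts = starts, vprime = v)
}

#' Create one randomized-splicing decoy of an isoform mask
#'
#' Every missing and non-missing stretch of the variable region is given a
#' new size drawn from a Poisson distribution with mean equal to its real
#' size; the pulsed stretches are concatenated in their original order and
#' the start of the new variable region is placed uniformly among all
#' positions that keep it inside the protein. Bits outside the new variable
#' region are 0. A draw whose pulsed variable region is empty or exceeds the
#' protein length is rejected and redrawn (up to `max_attempts`).
#'
#' @param bits Mask bit vector with at least one missing stretch.
#' @param max_attempts Redraw bound.
#' @return Decoy mask bit vector of the same length.
#' @export
make_single_isoform_decoy <- function(bits, max_attempts = 1000) {
  lo <- mask_layout(bits)
  d <- sample_decoy_layouts(lo$sizes, lo$L, 1L, max_attempts)
  layout_to_bits(d$sizes[1, ], lo$status, d$starts[1], lo$L)
}

#' Generate a single-isoform control set
#'
#' Draws `n_controls` decoys of one isoform mask (see
#' [make_single_isoform_decoy()]) and stores them in compact layout form.
#' Use [control_fractions()] to score interface removal against the set and
#' [control_masks()] to materialize the decoy bit vectors.
#'
#' @param bits Real mask bit vector (at least one missing stretch).
#' @param n_controls Number of decoys (default 1000).
#' @param max_attempts Redraw bound per rejection round.
#' @return A `control_set` object (mode `"single"`).
#' @export
control_set_single <- function(bits, n_controls = 1000, max_attempts = 1000) {
  stopifnot(n_controls >= 1)
  lo <- mask_layout(bits)
  d <- sample_decoy_layouts(lo$sizes, lo$L, n_controls, max_attempts)
  structure(list(mode = "single", L = lo$L, status = lo$status,
                 real_sizes = lo$sizes, sizes = d$sizes, starts = d$starts,
                 n_controls = n_controls),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat("<control_set mode=", x$mode, " n=", x$n_controls, " L=", x$L, ">\n",
      sep = "")
  invisible(x)
}

# count, per decoy, how many of `p` (sorted positions) fall in missing
# stretches described by a sizes matrix + starts vector + status vector
count_in_missing <- function(sizes, starts, status, p) {
  n <- nrow(sizes)
  counts <- integer(n)
  off <- starts
  for (j in seq_along(status)) {
    if (status[j] == 1L) {
      b <- off + sizes[, j] - 1L
      counts <- counts + (findInterval(b, p) - findInterval(off - 1L, p))
    }
    off <- off + sizes[, j]
  }
  counts
}

#' Missing fraction of an interface under each control
#'
#' For a single-isoform set, returns the fraction of `positions` falling in
#' missing stretches of each decoy (numeric vector of length `n_controls`).
#' For an all-isoforms set, returns a matrix (controls by isoforms).
#'
#' @param cs A `control_set`.
#' @param positions Non-empty integer set of interface positions.
#' @export
control_fractions <- function(cs, positions) {
  if (length(positions) == 0) abort("empty position set")
  p <- sort(as.integer(positions))
  if (cs$mode == "single") {
    return(count_in_missing(cs$sizes, cs$starts, cs$status, p) / length(p))
  }
  n <- cs$n_controls
  iso <- cs$isoform_ids
  out <- matrix(0L, n, length(iso), dimnames = list(NULL, iso))
  for (g in cs$groups) {
    gl <- cs$draws[[g$id]]
    for (m in seq_along(g$members)) {
      st <- g$status[m, ]
      if (!any(st == 1L)) next
      out[, g$members[m]] <- out[, g$members[m]] +
        count_in_missing(gl$sizes, gl$starts, st, p)
    }
  }
  out / length(p)
}

#' Materialize control masks
#'
#' @param cs A `control_set`.
#' @return Mode `"single"`: list of decoy bit vectors. Mode `"all"`: list of
#'   mask tibbles (`isoform_id`, `bits`), one per control group.
#' @export
control_masks <- function(cs) {
  if (cs$mode == "single") {
    return(map(seq_len(cs$n_controls), function(i) {
      layout_to_bits(cs$sizes[i, ], cs$status, cs$starts[i], cs$L)
    }))
  }
  map(seq_len(cs$n_controls), function(i) {
    bits <- map(cs$isoform_ids, function(id) integer(cs$L))
    names(bits) <- cs$isoform_ids
    for (g in cs$groups) {
      gl <- cs$draws[[g$id]]
      offs <- gl$starts[i] + cumsum(c(0L, gl$sizes[i, -ncol(gl$sizes)]))
      for (m in seq_along(g$members)) {
        for (j in which(g$status[m, ] == 1L & gl$sizes[i, ] > 0L)) {
          bits[[g$members[m]]][offs[j]:(offs[j] + gl$sizes[i, j] - 1L)] <- 1L
        }
      }
    }
    tibble(isoform_id = cs$isoform_ids, bits = unname(bits))
  })
}

#' Partition isoforms of a protein into overlap groups
#'
#' Two isoforms are connected when any missing-stretch position is shared;
#' overlap groups are the connected components of this relation (an isoform
#' with no partner forms a singleton group). For each group, the overlapping
#' variable region spans from the minimum to the maximum missing position of
#' its members, and every junction between a missing and a non-missing
#' stretch (or the outside) splits the region into segments with a constant
#' per-isoform missing-status vector.
#'
#' @param masks Mask tibble: `isoform_id`, `bits` (list-column), one protein.
#' @return List of groups: each has `id`, `members` (isoform ids), `region`
#'   (`c(start, end)`), `segments` (tibble `start`, `length`), and `status`
#'   (members-by-segments 0/1 matrix).
#' @export
build_overlap_groups <- function(masks) {
  n <- nrow(masks)
  dec <- map(masks$bits, decompose_mask)
  miss <- map(dec, "missing")
  if (any(map_int(miss, nrow) == 0)) {
    abort("every mask must have at least one missing stretch")
  }
  ivl_overlap <- function(a, b) {
    any(outer(a$start, b$start + b$length - 1L, "<=") &
        outer(a$start + a$length - 1L, b$start, ">="))
  }
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (ivl_overlap(miss[[i]], miss[[j]])) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  map(seq_len(max(comp)), function(cid) {
    idx <- which(comp == cid)
    ms <- bind_rows(miss[idx])
    region <- c(min(ms$start), max(ms$start + ms$length - 1L))
    breaks <- sort(unique(c(ms$start, ms$start + ms$length,
                            region[1], region[2] + 1L)))
    breaks <- breaks[breaks >= region[1] & breaks <= region[2] + 1L]
    seg_start <- breaks[-length(breaks)]
    seg_len <- diff(breaks)
    status <- matrix(0L, length(idx), length(seg_start),
                     dimnames = list(masks$isoform_id[idx], NULL))
    for (m in seq_along(idx)) {
      mm <- miss[[idx[m]]]
      hit <- findInterval(seg_start, mm$start)
      inside <- hit > 0L &
        seg_start <= (mm$start + mm$length - 1L)[pmax(hit, 1L)]
      status[m, inside] <- 1L
    }
    list(id = cid, members = masks$isoform_id[idx],
         region = as.integer(region),
         segments = tibble(start = seg_start, length = seg_len),
         status = status)
  })
}

# pulsed missing-derived intervals of one group draw (control i)
group_missing_intervals <- function(sizes_row, start, any_missing) {
  offs <- start + cumsum(c(0L, sizes_row[-length(sizes_row)]))
  j <- which(any_missing & sizes_row > 0L)
  cbind(offs[j], offs[j] + sizes_row[j] - 1L)
}

#' Generate an all-isoforms control set for one protein
#'
#' Each control is a group of decoy isoforms, one per real isoform,
#' preserving the overlap structure of their missing stretches: per overlap
#' group, every segment size is Poisson-pulsed and a fresh uniform start is
#' drawn for the pulsed overlapping variable region; each isoform's decoy is
#' rebuilt by marking the pulsed segments it is missing in. A control is
#' accepted only if (a) pulsed missing-derived segments of different overlap
#' groups never share a protein position, and (b) when there is more than one
#' group, the total pulsed missing size is at least 90 percent of the total
#' real missing size; otherwise the whole control is redrawn.
#'
#' @param masks Mask tibble for one protein (`isoform_id`, `bits`); every
#'   mask needs at least one missing stretch.
#' @param n_controls Number of control groups (default 1000).
#' @param max_attempts Redraw bound per control. The joint cross-group
#'   constraints can have acceptance rates well below a percent when one
#'   isoform's variable region spans most of the protein, so the bound is
#'   much larger than for the single-isoform sampler.
#' @param min_missing_ratio Acceptance bound of constraint (b), default 0.9.
#' @param protein_id Used in the error message when attempts are exhausted.
#' @return A `control_set` object (mode `"all"`).
#' @export
control_set_all <- function(masks, n_controls = 1000, max_attempts = 1e5,
                            min_missing_ratio = 0.9, protein_id = "?") {
  stopifnot(n_controls >= 1)
  L <- length(masks$bits[[1]])
  groups <- build_overlap_groups(masks)
  ng <- length(groups)
  real_missing_total <- sum(map_dbl(groups, function(g) {
    sum(g$segments$length[colSums(g$status) > 0])
  }))
  draws <- map(groups, function(g) {
    d <- sample_decoy_layouts(g$segments$length, L, n_controls, max_attempts)
    list(sizes = d$sizes, starts = d$starts)
  })
  if (ng > 1) {
    any_missing <- map(groups, function(g) colSums(g$status) > 0)
    seg_lens <- map(groups, function(g) g$segments$length)
    # cross-group constraint (a): sweep intervals by start with a running
    # maximum end; same-group intervals never overlap by construction, so
    # any hit is a cross-group hit and rejects the candidate
    no_cross_overlap <- function(sizes_rows, starts_row) {
      ivls <- map(seq_len(ng), function(gi) {
        group_missing_intervals(sizes_rows[[gi]], starts_row[gi],
                                any_missing[[gi]])
      })
      all_iv <- do.call(rbind, ivls)
      if (nrow(all_iv) < 2) return(TRUE)
      grp <- rep(seq_len(ng), map_int(ivls, nrow))
      ord <- order(all_iv[, 1])
      all_iv <- all_iv[ord, , drop = FALSE]; grp <- grp[ord]
      max_end <- all_iv[1, 2]; max_grp <- grp[1]
      for (r in seq(2, nrow(all_iv))) {
        if (all_iv[r, 1] <= max_end && grp[r] != max_grp) return(FALSE)
        if (all_iv[r, 2] >= max_end) { max_end <- all_iv[r, 2]; max_grp <- grp[r] }
      }
      TRUE
    }
    i <- 1L; att <- 0L; batch <- 512L
    while (i <= n_controls) {
      cand <- map(seq_len(ng), function(gi) {
        k <- length(seg_lens[[gi]])
        S <- matrix(rpois(batch * k, rep(seg_lens[[gi]], each = batch)),
                    nrow = batch)
        v <- rowSums(S)
        st <- runif_int(batch, pmax(L - v + 1L, 1L))
        list(S = S, v = v, st = st)
      })
      valid <- Reduce(`&`, map(cand, function(cc) cc$v >= 1L & cc$v <= L))
      pulsed <- Reduce(`+`, map(seq_len(ng), function(gi) {
        rowSums(cand[[gi]]$S[, any_missing[[gi]], drop = FALSE])
      }))
      valid <- valid & pulsed >= min_missing_ratio * real_missing_total
      for (b in seq_len(batch)) {
        att <- att + 1L
        if (!valid[b]) next
        sizes_rows <- map(cand, function(cc) cc$S[b, ])
        starts_row <- map_int(cand, function(cc) cc$st[b])
        if (!no_cross_overlap(sizes_rows, starts_row)) next
        for (gi in seq_len(ng)) {
          draws[[gi]]$sizes[i, ] <- sizes_rows[[gi]]
          draws[[gi]]$starts[i] <- starts_row[gi]
        }
        i <- i + 1L; att <- 0L
        if (i > n_controls) break
      }
      if (att >= max_attempts) {
        abort(paste0("max_attempts exhausted while building all-isoforms ",
                     "controls for protein ", protein_id))
      }
    }
  }
  structure(list(mode = "all", L = L, n_controls = n_controls,
                 isoform_ids = masks$isoform_id, groups = groups,
                 draws = draws, real_missing_total = real_missing_total,
                 min_missing_ratio = min_missing_ratio),
            class = "control_set")
}

#' Create one all-isoforms control (a group of decoy masks)
#'
#' Convenience wrapper drawing a single accepted control from
#' [control_set_all()].
#'
#' @inheritParams control_set_all
#' @return Mask tibble (`isoform_id`, `bits`) of the decoy group.
#' @export
make_all_isoforms_control <- function(masks, max_attempts = 1000,
                                      min_missing_ratio = 0.9,
                                      protein_id = "?") {
  cs <- control_set_all(masks, n_controls = 1, max_attempts = max_attempts,
                        min_missing_ratio = min_missing_ratio,
                        protein_id = protein_id)
  control_masks(cs)[[1]]
}
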
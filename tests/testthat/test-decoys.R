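test_that("pulsing preserves the Poisson moments and supports zero", {
  set.seed(31)
  x <- replicate(20000, pulse_sizes(c(10, 3))[1])
  expect_equal(mean(x), 10, tolerance = 0.01)
  expect_equal(var(x), 10, tolerance = 0.05)
  y <- replicate(20000, pulse_sizes(1))
  expect_equal(mean(y == 0), exp(-1), tolerance = 0.03)
  set.seed(99); a <- pulse_sizes(c(5, 5, 5))
  set.seed(99); expect_identical(pulse_sizes(c(5, 5, 5)), a)
  expect_error(pulse_sizes(c(3, 0)), "sizes")
})

test_that("single-isoform decoys preserve length, stretch order and zero flanks", {
  set.seed(32)
  mask1 <- make_mask(200, c(41, 60))
  for (i in 1:50) {
    d <- make_single_isoform_decoy(mask1)
    expect_length(d, 200)
    dec <- decompose_mask(d)
    expect_equal(nrow(dec$missing), 1)  # a single pulsed stretch stays single
  }
  mask2 <- make_mask(120, c(20, 30), c(45, 52))
  for (i in 1:50) {
    d <- make_single_isoform_decoy(mask2)
    dec <- decompose_mask(d)
    # pulsing can collapse a stretch to zero (merging), never add new ones
    expect_lte(nrow(dec$missing), 2)
    vr <- dec$variable_region
    expect_true(all(d[setdiff(seq_len(120), vr[1]:vr[2])] == 0L))
  }
  expect_error(make_single_isoform_decoy(integer(50)), "no missing stretch")
})

test_that("control sets are seed-reproducible byte for byte", {
  mask <- make_mask(150, c(30, 45), c(80, 90))
  set.seed(7); cs1 <- control_set_single(mask, 50)
  set.seed(7); cs2 <- control_set_single(mask, 50)
  m1 <- vapply(control_masks(cs1), encode_mask_rle, character(1))
  m2 <- vapply(control_masks(cs2), encode_mask_rle, character(1))
  expect_identical(m1, m2)
})

test_that("vectorized control fractions agree with materialized decoy masks", {
  set.seed(33)
  mask <- make_mask(150, c(30, 45), c(80, 90), c(100, 110))
  cs <- control_set_single(mask, 200)
  positions <- sort(sample(150, 25))
  direct <- vapply(control_masks(cs), missing_fraction, numeric(1),
                   positions = positions)
  expect_equal(control_fractions(cs, positions), direct)

  masks <- tibble(isoform_id = c("i1", "i2", "i3"),
                  bits = list(make_mask(150, c(10, 20)),
                              make_mask(150, c(15, 25), c(60, 70)),
                              make_mask(150, c(100, 130))))
  csa <- control_set_all(masks, 100)
  fr <- control_fractions(csa, positions)
  groups <- control_masks(csa)
  for (i in c(1, 50, 100)) {
    direct <- vapply(groups[[i]]$bits, missing_fraction, numeric(1),
                     positions = positions)
    expect_equal(unname(fr[i, ]), direct)
  }
})

test_that("decoy missing size is mean-preserving over many draws", {
  set.seed(34)
  mask <- make_mask(300, c(50, 69), c(100, 111))  # 32 missing residues
  cs <- control_set_single(mask, 5000)
  tot <- rowSums(cs$sizes[, cs$status == 1L, drop = FALSE])
  expect_equal(mean(tot), 32, tolerance = 0.01)
})

test_that("overlap groups match the junction-enumeration example", {
  masks <- tibble(isoform_id = c("A", "B"),
                  bits = list(make_mask(60, c(10, 20)), make_mask(60, c(15, 25))))
  og <- build_overlap_groups(masks)
  expect_length(og, 1)
  expect_equal(og[[1]]$region, c(10L, 25L))
  expect_equal(og[[1]]$segments,
               tibble(start = c(10L, 15L, 21L), length = c(5L, 6L, 5L)))
  expect_equal(unname(og[[1]]$status),
               matrix(c(1L, 0L, 1L, 1L, 0L, 1L), nrow = 2))

  # a distant third isoform forms its own singleton group whose segments are
  # its own stretches
  masks3 <- bind_rows(masks, tibble(isoform_id = "C",
                                    bits = list(make_mask(60, c(40, 50)))))
  og3 <- build_overlap_groups(masks3)
  expect_length(og3, 2)
  solo <- og3[[which(vapply(og3, function(g) "C" %in% g$members, logical(1)))]]
  expect_equal(solo$segments, tibble(start = 40L, length = 11L))
})

test_that("overlap-group decomposition equals a transitive-closure oracle", {
  set.seed(35)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    masks <- tibble(isoform_id = paste0("i", seq_len(n)),
                    bits = lapply(seq_len(n), function(i) {
                      b <- random_mask(60)
                      if (all(b == 0L)) b[5:8] <- 1L
                      b
                    }))
    og <- build_overlap_groups(masks)
    # oracle: direct overlap matrix, then transitive closure by powers
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- any(masks$bits[[i]] == 1L & masks$bits[[j]] == 1L)
    }
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach %*% adj > 0)
    got <- lapply(og, function(g) sort(g$members))
    want <- unique(lapply(seq_len(n), function(i) {
      sort(masks$isoform_id[reach[i, ]])
    }))
    expect_setequal(got, want)
  }
})

test_that("all-isoforms controls respect the cross-group and 90% constraints", {
  set.seed(36)
  masks <- tibble(isoform_id = c("i1", "i2", "i3"),
                  bits = list(make_mask(200, c(20, 40)),
                              make_mask(200, c(35, 55)),
                              make_mask(200, c(120, 150))))
  real_missing <- sum(vapply(build_overlap_groups(masks), function(g) {
    sum(g$segments$length[colSums(g$status) > 0])
  }, numeric(1)))
  cs <- control_set_all(masks, 100)
  groups <- control_masks(cs)
  for (ctl in groups) expect_true(all(lengths(ctl$bits) == 200))
  # check the stored draws directly: pulsed missing totals and disjointness
  for (i in seq_len(cs$n_controls)) {
    pulsed <- 0
    ivls <- list()
    for (gi in seq_along(cs$groups)) {
      am <- colSums(cs$groups[[gi]]$status) > 0
      sizes <- cs$draws[[gi]]$sizes[i, ]
      pulsed <- pulsed + sum(sizes[am])
      offs <- cs$draws[[gi]]$starts[i] + cumsum(c(0L, sizes[-length(sizes)]))
      j <- which(am & sizes > 0L)
      ivls[[gi]] <- cbind(offs[j], offs[j] + sizes[j] - 1L)
    }
    expect_gte(pulsed, 0.9 * real_missing)
    for (g1 in seq_along(ivls)) for (g2 in seq_along(ivls)) {
      if (g2 <= g1) next
      for (r1 in seq_len(nrow(ivls[[g1]]))) for (r2 in seq_len(nrow(ivls[[g2]]))) {
        expect_true(ivls[[g1]][r1, 1] > ivls[[g2]][r2, 2] ||
                      ivls[[g2]][r2, 1] > ivls[[g1]][r1, 2])
      }
    }
  }
})

test_that("a single isoform's all-isoforms control matches the single-isoform law", {
  mask <- make_mask(150, c(40, 59), c(70, 75))
  masks <- tibble(isoform_id = "only", bits = list(mask))
  set.seed(37)
  cs_all <- control_set_all(masks, 4000)
  set.seed(38)
  cs_single <- control_set_single(mask, 4000)
  p_all <- colMeans(do.call(rbind, map(control_masks(cs_all), function(g) g$bits[[1]])))
  p_single <- colMeans(do.call(rbind, control_masks(cs_single)))
  expect_lt(max(abs(p_all - p_single)), 0.035)
})
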
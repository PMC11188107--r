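test_that("dedup_exact keeps the first occurrence of each key", {
  mol <- molecule_assignments(c(1, 1), c(2, 2), c("AAAA", "AAAA"))
  r <- dedup_exact(mol)
  expect_identical(nrow(r$kept), 1L)
  expect_identical(r$removed, 1L)
  expect_identical(r$kept$order, 1L)

  mol <- molecule_assignments(c(1, 1, 2), c(1, 1, 1),
                              c("AAAA", "AAAT", "AAAA"))
  r <- dedup_exact(mol)
  expect_identical(r$removed, 0L)
  expect_identical(r$kept, mol)

  # same UMI under different tags: one key by default, two when the key
  # includes the tag
  mol <- molecule_assignments(c(1, 1), c(1, 2), c("AAAA", "AAAA"))
  expect_identical(dedup_exact(mol)$removed, 1L)
  expect_identical(dedup_exact(mol, dedup_policy(key_includes_tag = TRUE))$removed, 0L)
})

test_that("dedup_close collapses near UMIs greedily, keep-first", {
  mol <- molecule_assignments(c(1, 1), c(1, 1), c("AAAA", "AAAT"))
  r <- dedup_close(mol, dedup_policy(mode = "close", max_mismatch = 1))
  expect_identical(nrow(r$kept), 1L)
  expect_identical(r$kept$umi, "AAAA")
  expect_identical(r$removed, 1L)

  expect_error(
    dedup_close(molecule_assignments(c(1, 1), c(1, 1), c("AAAA", "AAATT")),
                dedup_policy(mode = "close")),
    "ragged")
  expect_error(dedup_policy(mode = "close", max_mismatch = 0), "max_mismatch")
})

test_that("close dedup with radius 0 degenerates to exact dedup", {
  set.seed(21)
  for (i in 1:10) {
    mol <- rand_molecules(200)
    r0 <- dedup_close(mol, close_policy_radius(0))
    re <- dedup_exact(mol)
    expect_identical(r0$kept, re$kept)
    expect_identical(r0$removed, re$removed)
  }
})

test_that("both dedup modes equal their quadratic oracles on random inputs", {
  set.seed(22)
  for (i in 1:25) {
    mol <- rand_molecules(sample(50:200, 1), n_cells = sample(2:8, 1))
    include_tag <- i %% 2 == 0
    keep_e <- oracle_dedup_exact(mol, include_tag)
    re <- dedup_exact(mol, dedup_policy(key_includes_tag = include_tag))
    expect_identical(re$kept, mol[keep_e, , drop = FALSE])

    radius <- sample(1:2, 1)
    keep_c <- oracle_dedup_close(mol, radius, include_tag)
    rc <- dedup_close(mol, dedup_policy(mode = "close", max_mismatch = radius,
                                        key_includes_tag = include_tag))
    expect_identical(rc$kept, mol[keep_c, , drop = FALSE])
  }
})

test_that("dedup satisfies conservation, idempotence, ordering and dominance", {
  set.seed(23)
  for (i in 1:15) {
    mol <- rand_molecules(sample(20:150, 1))
    pe <- dedup_policy()
    p1 <- dedup_policy(mode = "close", max_mismatch = 1)
    p2 <- dedup_policy(mode = "close", max_mismatch = 2)
    re <- dedup_exact(mol, pe); r1 <- dedup_close(mol, p1); r2 <- dedup_close(mol, p2)
    for (r in list(re, r1, r2)) {
      expect_identical(nrow(r$kept) + r$removed, nrow(mol))      # conservation
      expect_false(is.unsorted(r$kept$order, strictly = TRUE))   # ordering
    }
    expect_identical(dedup_exact(re$kept, pe)$removed, 0L)       # idempotence
    expect_identical(dedup_close(r1$kept, p1)$removed, 0L)
    expect_gte(r1$removed, re$removed)                           # dominance
    expect_gte(r2$removed, r1$removed)
  }
})

test_that("duplication_profile returns (c-1)/c per key", {
  # key seen once -> 0; key seen 4 times -> 0.75
  mol <- molecule_assignments(
    cell_index = c(1, 1, 1, 1, 1, 2),
    tag_index = rep(1L, 6),
    umi = c("AAAA", "AAAA", "AAAA", "AAAA", "GGGG", "TTTT"))
  p <- duplication_profile(mol)
  expect_equal(p$fractions, c(0.75, 0, 0))
  expect_equal(p$counts, c(4L, 1L, 1L))
  expect_equal(p$zero_duplicate_share, 2 / 3)
  expect_equal(sum(p$histogram$n_keys), 3L)
})

test_that("exact_vs_close_difference matches the hand computation", {
  # one cell, UMIs {AAAA, AAAA, AAAT}: exact removes 1, close(1) removes 2
  mol <- molecule_assignments(c(1, 1, 1), c(1, 1, 1),
                              c("AAAA", "AAAA", "AAAT"))
  d <- exact_vs_close_difference(mol, dedup_policy(mode = "close"))
  expect_identical(nrow(d), 1L)
  expect_equal(d$total, 3L)
  expect_equal(d$duplicates_exact, 1L)
  expect_equal(d$duplicates_close, 2L)
  expect_equal(d$normalized_difference, (2 - 1) / 3)

  # key with no near-neighbour UMIs -> difference 0
  mol <- molecule_assignments(c(1, 1), c(1, 1), c("AAAA", "TTTT"))
  d <- exact_vs_close_difference(mol, dedup_policy(mode = "close"))
  expect_equal(d$normalized_difference, c(0, 0))
})

test_that("exact_vs_close_difference recomposes from the two dedup oracles", {
  set.seed(24)
  for (i in 1:10) {
    mol <- rand_molecules(sample(30:120, 1), n_cells = 4)
    d <- exact_vs_close_difference(mol, dedup_policy(mode = "close"))
    expect_true(all(d$normalized_difference >= 0))
    expect_identical(sum(d$total), nrow(mol))
    expect_identical(sum(d$duplicates_close),
                     nrow(mol) - sum(oracle_dedup_close(mol, 1)))
    expect_identical(sum(d$duplicates_exact),
                     nrow(mol) - sum(oracle_dedup_exact(mol)))
  }
})

test_that("dedup stats export as TSV", {
  mol <- molecule_assignments(c(1, 1, 2), c(1, 1, 1), c("AAAA", "AAAA", "CCCC"))
  path <- tempfile(fileext = ".tsv")
  write_dedup_stats(duplication_profile(mol), path)
  tab <- read.delim(path)
  expect_equal(tab$duplicate_fraction, c(0.5, 0))
})
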
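test_that("RA algorithms retain what they promise, row by row", {
  set.seed(21)
  for (rep in 1:200) {
    n <- sample(3:10, 1)
    row <- sample(0:5, n, replace = TRUE)
    if (sum(row) == 0) row[sample.int(n, 1)] <- 1
    m <- toy_matrix(rbind(row, row + 1))
    P <- utilization(m, quiet = TRUE)

    r3 <- randomize(m, "RA3")$abundance
    expect_equal(sort(r3[1, ]), sort(P[1, ]), tolerance = 1e-15,
                 ignore_attr = TRUE)

    r2 <- randomize(m, "RA2")$abundance
    expect_identical(unname(r2[1, ] == 0), unname(P[1, ] == 0))

    r4 <- randomize(m, "RA4")$abundance
    expect_identical(unname(r4[1, ] == 0), unname(P[1, ] == 0))
    expect_equal(sort(r4[1, ]), sort(P[1, ]), tolerance = 1e-15,
                 ignore_attr = TRUE)

    r1 <- randomize(m, "RA1")$abundance
    expect_true(all(r1 > 0))   # open-interval draws: no zeros anywhere
    expect_equal(unname(rowSums(r1)), c(1, 1), tolerance = 1e-12)
  }
  expect_error(randomize(toy_matrix(diag(2) + 1), "RA9"), "unknown algorithm")
})

test_that("hand-checkable RA examples behave as documented", {
  m <- toy_matrix(rbind(c(3, 0, 2), c(0, 4, 1)))
  P <- utilization(m, quiet = TRUE)
  set.seed(5)
  r3 <- randomize(m, "RA3")$abundance
  # permutation of the multiset {3,0,2}/5
  expect_equal(sort(unname(r3[1, ])), sort(unname(P[1, ])))
  r4 <- randomize(m, "RA4")$abundance
  expect_equal(unname(r4[2, 1]), 0)             # zero position fixed
  # {4,1}/5 permuted in place
  expect_equal(sort(unname(r4[2, 2:3])), sort(unname(P[2, 2:3])))
})

test_that("null_model_test is reproducible and summarises its ensemble", {
  set.seed(1)
  m <- random_community(6, 5)
  a <- null_model_test(m, "RA3", iterations = 50, seed = 99)
  b <- null_model_test(m, "RA3", iterations = 50, seed = 99)
  expect_identical(a, b)
  expect_true(a$p_ge >= 0 && a$p_ge <= 1)
  expect_gte(a$null_variance, 0)

  one <- null_model_test(m, "RA2", iterations = 1, seed = 2)
  expect_equal(one$expected_mean, one$null_means[1])
  expect_equal(one$null_variance, 0)

  raw <- null_model_test(m, "RA3", iterations = 40, seed = 3)
  pc <- null_model_test(m, "RA3", iterations = 40, seed = 3,
                        pseudo_count = TRUE)
  expect_equal(pc$p_ge, (sum(raw$null_means >= raw$observed_mean) + 1) / 41)
})

test_that("identical utilisation rows give maximal observed overlap", {
  m <- toy_matrix(matrix(rep(c(4, 1, 2, 3), 3), nrow = 3, byrow = TRUE))
  nt <- null_model_test(m, "RA3", iterations = 200, seed = 8)
  expect_equal(nt$observed_mean, 1, tolerance = 1e-12)
  expect_lte(nt$p_ge, 0.05)   # nulls rarely reach complete overlap
})

test_that("category subsetting matches running on the subsetted matrix", {
  set.seed(14)
  m <- random_community(8, 6)
  meta <- species_metadata(species_ids(m),
                           rep(c("stygobite", "non_stygobite"), each = 4))
  via_meta <- null_model_test(m, "RA3", iterations = 30, seed = 5,
                              meta = meta, category = "stygobite")
  manual <- null_model_test(subset_community(m, species_ids(m)[1:4]),
                            "RA3", iterations = 30, seed = 5)
  expect_equal(via_meta$null_means, manual$null_means)
  expect_equal(via_meta$p_ge, manual$p_ge)
})

test_that("segregation and aggregation pull the tail probability apart", {
  # disjoint one-site blocks: observed overlap below a random-placement null
  seg <- generate_community(synthetic_config(
    n_species = 8, n_stygobites = 4, n_sites = 8, segregation = 1,
    block_size = 1, total_abundance = 400, dispersion = 50, seed = 31))
  p_seg <- null_model_test(seg$matrix, "RA3", iterations = 200, seed = 31,
                           quiet = TRUE)$p_ge
  expect_gt(p_seg, 0.9)
  # all species on one shared block: observed overlap above the null
  agg <- generate_community(synthetic_config(
    n_species = 8, n_stygobites = 4, n_sites = 8, segregation = 1,
    block_size = 2, blocks = rep(1, 8), total_abundance = 400,
    dispersion = 50, seed = 32))
  p_agg <- null_model_test(agg$matrix, "RA3", iterations = 200, seed = 32,
                           quiet = TRUE)$p_ge
  expect_lt(p_agg, 0.1)
})
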
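make_meta <- function(ids, n_styg) {
  species_metadata(ids, rep(c("stygobite", "non_stygobite"),
                            c(n_styg, length(ids) - n_styg)))
}

test_that("pair classification is symmetric and total", {
  meta <- species_metadata(c("a", "b", "c"),
                           c("stygobite", "stygobite", "non_stygobite"))
  expect_identical(classify_pair("a", "b", meta), "ss")
  expect_identical(classify_pair("a", "c", meta), "sn")
  expect_identical(classify_pair("c", "a", meta), "sn")
  expect_identical(classify_pair("c", "c", meta), "nn")
  expect_error(classify_pair("a", "zz", meta), "missing from metadata")
})

test_that("the pair table keeps only pairs present in every year", {
  set.seed(41)
  cfg <- synthetic_config(n_species = 6, n_stygobites = 3, n_sites = 5,
                          total_abundance = 300, dispersion = 50)
  sc <- generate_scenario(list(y1 = cfg, y2 = cfg, y3 = cfg),
                          absent = list(y2 = "sp05"), seed = 41)
  res <- lapply(sc$matrices, niche_overlap, quiet = TRUE)
  tab <- build_pair_table(res, sc$metadata)
  expect_false(any(tab$species_a == "sp05" | tab$species_b == "sp05"))
  expect_equal(nrow(tab), choose(5, 2))
  expect_identical(attr(tab, "years"), c("y1", "y2", "y3"))
  # values come from each year's O matrix
  expect_equal(tab$y1[tab$subject == "sp01:sp02"],
               res$y1$O["sp01", "sp02"])
  # 18 shared species give C(18,2) = 153 records
  cfg18 <- synthetic_config(n_species = 18, n_stygobites = 7,
                            total_abundance = 300, dispersion = 50)
  sc18 <- generate_scenario(list(y1 = cfg18, y2 = cfg18), seed = 43)
  tab18 <- build_pair_table(lapply(sc18$matrices, niche_overlap, quiet = TRUE),
                            sc18$metadata)
  expect_equal(nrow(tab18), 153L)
})

test_that("the species table carries per-year O_sp from the full assemblage", {
  set.seed(47)
  cfg <- synthetic_config(n_species = 5, n_stygobites = 2, n_sites = 4,
                          total_abundance = 300, dispersion = 50)
  sc <- generate_scenario(list(y1 = cfg, y2 = cfg), seed = 47)
  res <- lapply(sc$matrices, niche_overlap, quiet = TRUE)
  tab <- build_species_table(res, sc$metadata)
  expect_equal(tab$y2[tab$subject == "sp03"], unname(res$y2$O_sp["sp03"]))
  expect_identical(tab$specialisation[tab$subject == "sp01"], "stygobite")
})

test_that("rm_anova reproduces the brute-force Type III decomposition", {
  # balanced toy: 2 groups x 3 subjects x 3 years
  set.seed(53)
  Yb <- matrix(rnorm(18, mean = rep(c(0, 1), each = 3)), nrow = 6)
  gb <- rep(c("s", "n"), each = 3)
  tab <- data.frame(subject = paste0("u", 1:6), pair_type = gb,
                    y1 = Yb[, 1], y2 = Yb[, 2], y3 = Yb[, 3])
  attr(tab, "years") <- c("y1", "y2", "y3")
  class(tab) <- c("pair_table", "data.frame")
  fit <- rm_anova(tab, between = "pair_type")
  orc <- oracle_rm_anova(Yb, gb)
  expect_equal(fit$SS, with(orc, c(ss_group, ss_err_between, ss_year,
                                   ss_interaction, ss_err_within)),
               tolerance = 1e-8)
  expect_equal(fit$df, c(1, 4, 2, 2, 8))
  expect_equal(fit$MS, fit$SS / fit$df, tolerance = 1e-12)
  expect_equal(fit$F[1], fit$MS[1] / fit$MS[2], tolerance = 1e-10)
  expect_equal(fit$F[3], fit$MS[3] / fit$MS[5], tolerance = 1e-10)
  # stratum totals are conserved
  m <- rowMeans(Yb)
  expect_equal(fit$SS[1] + fit$SS[2], 3 * sum((m - mean(m))^2),
               tolerance = 1e-8)

  # unbalanced groups: Type III still matches the projection oracle
  set.seed(59)
  Yu <- matrix(rnorm(36), nrow = 12)
  gu <- rep(c("ss", "sn", "nn"), c(3, 4, 5))
  tabu <- data.frame(subject = paste0("p", 1:12), pair_type = gu,
                     y1 = Yu[, 1], y2 = Yu[, 2], y3 = Yu[, 3])
  attr(tabu, "years") <- c("y1", "y2", "y3")
  class(tabu) <- c("pair_table", "data.frame")
  fitu <- rm_anova(tabu, between = "pair_type")
  orcu <- oracle_rm_anova(Yu, gu)
  expect_equal(fitu$SS, with(orcu, c(ss_group, ss_err_between, ss_year,
                                     ss_interaction, ss_err_within)),
               tolerance = 1e-8)
})

test_that("rm_anova recovers injected effects with the right direction", {
  set.seed(61)
  n_per <- 20
  g <- rep(c("s", "n"), each = n_per)
  shift <- ifelse(g == "s", 0, 0.8)         # group effect, no year effect
  Y <- matrix(rnorm(3 * 2 * n_per, mean = shift, sd = 0.2), ncol = 3)
  tab <- data.frame(subject = seq_len(2 * n_per), pair_type = g,
                    y1 = Y[, 1], y2 = Y[, 2], y3 = Y[, 3])
  attr(tab, "years") <- c("y1", "y2", "y3")
  class(tab) <- c("pair_table", "data.frame")
  fit <- rm_anova(tab, between = "pair_type")
  expect_lt(fit$P[1], 0.001)                 # group detected
  expect_gt(fit$P[3], 0.05)                  # no spurious year effect
  expect_lt(fit$SS[3], 0.05 * fit$SS[1])
  # now inject a year effect instead
  Y2 <- Y + matrix(rep(c(0, 0.5, 1), each = 2 * n_per), ncol = 3)
  tab2 <- tab; tab2$y1 <- Y2[, 1]; tab2$y2 <- Y2[, 2]; tab2$y3 <- Y2[, 3]
  fit2 <- rm_anova(tab2, between = "pair_type")
  expect_lt(fit2$P[3], 1e-6)
  yr_means <- colMeans(Y2)
  expect_true(all(diff(yr_means) > 0))       # direction of the injected trend
})

test_that("degenerate and invalid rm_anova inputs are handled", {
  tab <- data.frame(subject = 1:6, pair_type = rep(c("a", "b"), each = 3),
                    y1 = 1, y2 = 1, y3 = 1)
  attr(tab, "years") <- c("y1", "y2", "y3")
  class(tab) <- c("pair_table", "data.frame")
  fit <- suppressWarnings(rm_anova(tab, between = "pair_type"))
  expect_equal(fit$SS[c(1, 3, 4)], c(0, 0, 0), tolerance = 1e-12)
  tab$y2[2] <- NA
  expect_error(rm_anova(tab, between = "pair_type"), "missing year")
  tab2 <- data.frame(subject = 1:3, pair_type = c("a", "a", "b"),
                     y1 = rnorm(3), y2 = rnorm(3))
  attr(tab2, "years") <- c("y1", "y2")
  class(tab2) <- c("pair_table", "data.frame")
  expect_error(rm_anova(tab2, between = "pair_type"), "at least 2 subjects")
})

test_that("Bonferroni adjustment multiplies and caps raw P values", {
  set.seed(67)
  tab <- data.frame(subject = 1:10, pair_type = rep(c("a", "b"), 5),
                    y1 = rnorm(10), y2 = rnorm(10) + 0.5, y3 = rnorm(10))
  attr(tab, "years") <- c("y1", "y2", "y3")
  class(tab) <- c("pair_table", "data.frame")
  res <- bonferroni_pairwise(tab, "year")
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_adj, pmin(1, res$p_raw * 3), tolerance = 1e-12)
  # identical groups compare with adjusted P = 1
  tabg <- tab; tabg$y1 <- 1; tabg$y2 <- 2; tabg$y3 <- 3
  resg <- bonferroni_pairwise(tabg, "group", between = "pair_type")
  expect_equal(resg$p_adj, 1)
})

test_that("paired t matches the textbook formula and degrades gracefully", {
  tab <- data.frame(subject = 1:4, pair_type = "ss",
                    y1 = c(1, 2, 3, 4), y2 = c(1.4, 2.1, 3.6, 4.3))
  attr(tab, "years") <- c("y1", "y2")
  class(tab) <- c("pair_table", "data.frame")
  d <- tab$y2 - tab$y1
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  res <- paired_t(tab, "y1", "y2", pair_type = "ss")
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3L)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
  # identical years: degenerate, P = 1
  tab$y2 <- tab$y1
  res0 <- paired_t(tab, "y1", "y2", pair_type = "ss")
  expect_true(res0$degenerate)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # constant positive shift with tiny noise: P near 0
  set.seed(71)
  tab$y2 <- tab$y1 + 1 + rnorm(4, sd = 1e-4)
  expect_lt(paired_t(tab, "y1", "y2", pair_type = "ss")$p, 1e-6)
})

test_that("year_report populates every section reproducibly", {
  cfgs <- list(y1 = synthetic_config(n_species = 10, n_stygobites = 4,
                                     segregation = 0.9, seed = 81),
               y2 = synthetic_config(n_species = 10, n_stygobites = 4,
                                     segregation = 0.9, seed = 82),
               y3 = synthetic_config(n_species = 10, n_stygobites = 4,
                                     segregation = 0.1, seed = 83))
  sc <- generate_scenario(cfgs)
  rep1 <- suppressWarnings(year_report(sc$matrices, sc$metadata,
                                       iterations = 50, seed = 2))
  rep2 <- suppressWarnings(year_report(sc$matrices, sc$metadata,
                                       iterations = 50, seed = 2))
  expect_identical(rep1, rep2)
  expect_s3_class(rep1$anova_O, "rm_anova")
  expect_s3_class(rep1$anova_Osp, "rm_anova")
  expect_s3_class(rep1$anova_C, "rm_anova")
  expect_true(all(c("RA2.all", "RA3.all", "RA3.stygobite") %in%
                    names(rep1$null$y1)))
  expect_equal(nrow(rep1$bonferroni$O_years), 3L)
  expect_true(length(rep1$paired_t) > 0)
})
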
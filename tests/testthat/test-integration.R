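make_blups <- function(n_geno = 40, groups = c("g1", "g2"), seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(genotype = sprintf("G%03d", seq_len(n_geno)),
                     treatment = c("plusN", "minusN"),
                     group_id = groups) |>
    dplyr::mutate(blup = rnorm(dplyr::n()))
}

test_that("Pearson correlations match the textbook formula and handle edge cases", {
  b <- make_blups(groups = "g1")
  plant <- dplyr::distinct(b, genotype, treatment) |>
    dplyr::mutate(value = b$blup[match(paste(genotype, treatment),
                                       paste(b$genotype, b$treatment))])
  res <- correlate_traits(b, plant)
  expect_true(all(abs(res$r - 1) < 1e-12))
  expect_true(all(res$p < 1e-10))

  # 5-point hand computation
  x <- c(1, 2, 4, 5, 9); y <- c(2, 1, 5, 4, 8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  b5 <- tibble::tibble(genotype = letters[1:5], treatment = "plusN",
                       group_id = "g", blup = x)
  p5 <- tibble::tibble(genotype = letters[1:5], treatment = "plusN", value = y)
  res5 <- correlate_traits(b5, p5)
  expect_equal(res5$r, r_hand, tolerance = 1e-10)

  # fewer than 3 matched genotypes: suppressed with flag
  res2 <- correlate_traits(b5[1:2, ], p5[1:2, ])
  expect_equal(res2$flag, "suppressed")
  expect_true(is.na(res2$r))
})

test_that("the count-of-significant permutation null is calibrated and powered", {
  # null: independent plant trait, observed count should sit inside the null
  b <- make_blups(n_geno = 50, groups = sprintf("g%d", 1:10), seed = 2)
  set.seed(3)
  plant <- dplyr::distinct(b, genotype, treatment) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  res <- count_significant_permutation(b, plant, B = 99, seed = 4)
  expect_lte(res$count_obs, quantile(res$null_counts, 1))
  expect_gt(res$p, 0.05)

  # coupled traits: many groups correlate, permutation p small
  b2 <- make_blups(n_geno = 50, groups = sprintf("g%d", 1:10), seed = 5)
  latent <- rnorm(50)
  b2$blup <- latent[match(b2$genotype, sprintf("G%03d", 1:50))] +
    rnorm(nrow(b2), 0, 0.4)
  plant2 <- dplyr::distinct(b2, genotype, treatment) |>
    dplyr::mutate(value = latent[match(genotype, sprintf("G%03d", 1:50))] +
                    rnorm(dplyr::n(), 0, 0.4))
  res2 <- count_significant_permutation(b2, plant2, B = 99, seed = 6)
  expect_gt(res2$count_obs, 5)
  expect_lte(res2$p, 0.05)
  # minimum attainable p
  expect_gte(res2$p, 1 / 100)
})

test_that("heritability vs fitness-correlation relation detects shared structure", {
  h2 <- tibble::tibble(group_id = rep(sprintf("g%d", 1:20), 2),
                       treatment = rep(c("plusN", "minusN"), each = 20),
                       h2 = runif(40))
  ct <- dplyr::mutate(h2, r = h2 * 0.8 + rnorm(40, 0, 0.05))[, c(1, 2, 4)]
  rel <- heritability_correlation_relation(h2, ct)
  expect_equal(nrow(rel), 2)
  expect_true(all(rel$r > 0.5))
  expect_true(all(rel$p < 0.01))
  # constant h2: suppressed
  h2c <- dplyr::mutate(h2, h2 = 0.5)
  relc <- heritability_correlation_relation(h2c, ct)
  expect_true(all(relc$flag == "suppressed"))
})

test_that("expression set test is tissue-specific and rejects degenerate sets", {
  e <- simulate_expression(3000, sprintf("gene%05d", 1:80), root_boost = 1.2,
                           seed = 7)
  res <- expression_set_test(e, sprintf("gene%05d", 1:80))
  expect_lt(res$p[res$tissue == "germinating_root"], 0.01)
  expect_gt(res$effect[res$tissue == "germinating_root"], 0.5)
  expect_gt(min(res$p[res$tissue != "germinating_root"]), 0.01)
  expect_error(expression_set_test(e, character()), "empty")
  tiny <- e[e$gene_id %in% sprintf("gene%05d", 1:3), ]
  expect_error(expression_set_test(tiny, sprintf("gene%05d", 1:3)), "disjoint")
})

test_that("the summary ledger joins all assays and re-derives its counts", {
  h2 <- tibble::tibble(group_id = rep(c("g1", "g2"), each = 2),
                       treatment = rep(c("plusN", "minusN"), 2),
                       h2 = c(0.7, 0.6, 0.1, 0.2),
                       p = c(0.01, 0.02, 0.5, 0.6))
  sel <- tibble::tibble(group_id = c("g1", "g2"), treatment = "plusN",
                        s = c(0.2, 0.01), c = 0,
                        p_s = c(0.01, 0.8), p_c = c(0.5, 0.9))
  mapls <- tibble::tibble(chrom = "chr1", window = 3L, start = 30000L,
                          end = 40000L, n_signals = 2L, n_traits = 1L,
                          group_ids = "g1", treatments = "plusN")
  ct <- tibble::tibble(group_id = c("g1", "g2"), plant_trait = "cc",
                       treatment = "plusN", r = c(0.5, 0.1),
                       p = c(0.001, 0.6), n = 50, flag = "")
  smry <- build_summary(h2, sel, mapls, ct)
  expect_equal(nrow(smry), 2)
  g1 <- smry[smry$group_id == "g1", ]
  expect_true(g1$heritable_plusN && g1$under_selection && g1$has_mapl &&
                g1$cc_correlated)
  counts <- attr(smry, "counts")
  expect_equal(counts$n_all_assays, 1)
  expect_equal(counts$n_cc, 1)
  # orphan group ids across tables are an error
  sel_bad <- dplyr::mutate(sel, group_id = c("g1", "gX"))
  expect_error(build_summary(h2, sel_bad, mapls, ct), "gX")
})
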
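test_that("Bray-Curtis hits its boundary cases", {
  counts <- rbind(c(10, 20, 0, 0), c(10, 20, 0, 0), c(0, 0, 7, 3))
  tab <- toy_asv_table(n_samp = 3, n_asv = 4, counts = counts)
  d <- as.matrix(bray_curtis(tab))
  expect_equal(d["s01", "s02"], 0)          # identical composition
  expect_equal(d["s01", "s03"], 1)          # disjoint supports
})

test_that("weighted UniFrac equals the hand computation on a star tree", {
  counts <- rbind(c(50, 50, 0), c(0, 50, 50))
  tab <- toy_asv_table(n_samp = 2, n_asv = 3, counts = counts)
  tree <- ape::read.tree(text = "(ASV1:1,ASV2:2,ASV3:3);")
  d <- weighted_unifrac(tab, tree)
  # branches: l=(1,2,3); A=(.5,.5,0), B=(0,.5,.5)
  # num = 1*.5 + 2*0 + 3*.5 = 2 ; den = 1*.5 + 2*1 + 3*.5 = 4
  expect_equal(as.numeric(d), 0.5, tolerance = 1e-12)

  # identical samples -> 0
  counts2 <- rbind(c(10, 20, 30), c(10, 20, 30))
  tab2 <- toy_asv_table(n_samp = 2, n_asv = 3, counts = counts2)
  expect_equal(as.numeric(weighted_unifrac(tab2, tree)), 0)

  # missing tip is an error naming the ASV
  tree2 <- ape::read.tree(text = "(ASV1:1,ASV2:2);")
  expect_error(weighted_unifrac(tab, tree2), "ASV3")
})

test_that("weighted UniFrac agrees with phyloseq on star trees", {
  skip_if_not_installed("phyloseq")
  set.seed(6)
  counts <- matrix(rpois(5 * 6, 30), 5, 6)
  tab <- toy_asv_table(n_samp = 5, n_asv = 6, counts = counts)
  tree <- ape::read.tree(text = "(ASV1:1,ASV2:0.5,ASV3:2,ASV4:1.5,ASV5:0.2,ASV6:1);")
  mine <- weighted_unifrac(tab, tree)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(tab$counts, taxa_are_rows = FALSE),
    phyloseq::phy_tree(tree)
  )
  ref <- phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE)
  expect_equal(as.vector(mine), as.vector(ref), tolerance = 1e-10)
})

test_that("PCoA recovers planar configurations and obeys the Gower identity", {
  set.seed(3)
  pts <- matrix(rnorm(20), 10, 2)
  d <- dist(pts)
  pc <- suppressWarnings(pcoa(d, k = 2))
  rec <- as.matrix(pc$coordinates[, c("PCo1", "PCo2")])
  proc <- vegan::procrustes(pts, rec)
  expect_lt(proc$ss, 1e-8)
  # Gower: sum of eigenvalues = sum d^2 / n
  expect_equal(sum(pc$eigenvalues), sum(as.matrix(d)[upper.tri(as.matrix(d))]^2) / 10,
               tolerance = 1e-8)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("constrained ordination separates a real treatment shift and not a fake one", {
  g <- simulate_genotypes(30, 40, seed = 61)
  dsg <- simulate_design(rownames(g$dosage), samples_per_plot = 1, seed = 62)
  sim <- simulate_group_traits(g, dsg, h2_targets = 0, n_groups = 8,
                               treat_effect_sd = 3, seed = 63)
  d <- bray_curtis(sim$asv)
  cap <- cap_ordination(d, sim$asv$sample_meta, "treatment", n_perm = 99)
  r <- cor(cap$scores$CAP1, as.numeric(cap$scores$treatment == "plusN"))
  expect_gt(abs(r), 0.9)
  expect_lt(cap$factor_tests$p[1], 0.05)

  # a factor orthogonal to all variation: tiny constrained eigenvalue
  meta2 <- sim$asv$sample_meta
  set.seed(1); meta2$fake <- sample(c("a", "b"), nrow(meta2), replace = TRUE)
  cap2 <- cap_ordination(d, meta2, "fake", n_perm = 99)
  expect_lt(cap2$eigenvalues[1] / sum(pcoa(d)$eigenvalues), 0.05)
})

test_that("PERMANOVA pseudo-F matches vegan and exact enumeration", {
  set.seed(13)
  counts <- matrix(rpois(6 * 8, 40), 6, 8)
  counts[4:6, 1:4] <- counts[4:6, 1:4] + 60
  tab <- toy_asv_table(n_samp = 6, n_asv = 8, counts = counts)
  f <- rep(c("a", "b"), each = 3)
  d <- bray_curtis(tab)
  got <- suppressWarnings(permanova(d, f, n_perm = 999, seed = 1))
  ref <- vegan::adonis2(d ~ f, permutations = 99)
  expect_equal(got$pseudo_F, ref$F[1], tolerance = 1e-10)

  # exhaustive oracle, written independently of the implementation
  d2 <- as.matrix(d)^2
  fstat <- function(lab) {
    n <- 6; sst <- sum(d2[upper.tri(d2)]) / n
    ssw <- 0
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ((sst - ssw) / 1) / (ssw / 4)
  }
  perms <- gtools_style_perms <- NULL
  # enumerate all 6! orderings via recursion
  enum <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in enum(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_f <- vapply(enum(1:6), function(ord) fstat(f[ord]), numeric(1))
  p_oracle <- mean(all_f >= fstat(f) - 1e-12)
  got_exact <- permanova(d, f, exact = TRUE)
  expect_equal(got_exact$p, p_oracle, tolerance = 1e-12)

  # identical samples: error
  same <- toy_asv_table(n_samp = 4, n_asv = 3,
                        counts = matrix(rep(c(5, 6, 7), each = 4), 4, 3))
  expect_error(permanova(bray_curtis(same), c("a", "a", "b", "b"), n_perm = 99),
               "identical")
})

test_that("PERMANOVA p-values are seed-deterministic and on the permutation grid", {
  set.seed(14)
  counts <- matrix(rpois(12 * 6, 30), 12, 6)
  tab <- toy_asv_table(n_samp = 12, n_asv = 6, counts = counts)
  d <- bray_curtis(tab)
  f <- rep(c("a", "b"), 6)
  p1 <- permanova(d, f, n_perm = 199, seed = 4)
  p2 <- permanova(d, f, n_perm = 199, seed = 4)
  expect_identical(p1, p2)
  expect_gte(p1$p, 1 / 200)
  expect_lte(p1$p, 1)
})
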
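test_that("profiled REML agrees with lme4 on unbalanced data", {
  set.seed(2)
  n_i <- sample(2:8, 40, replace = TRUE)
  g <- rep(seq_along(n_i), n_i)
  y <- rnorm(40, 0, 1)[g] + rnorm(length(g), 0, 1.5)
  fit <- fit_variance_components(y, g)
  ref <- lme4::lmer(y ~ (1 | g), REML = TRUE,
                    data = data.frame(y = y, g = factor(g)))
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$vg, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$ve, vc$vcov[2], tolerance = 1e-4)
})

test_that("REML equals the balanced one-way ANOVA estimator", {
  for (i in 1:20) {
    dat <- oneway_data(n_geno = sample(10:40, 1), n_rep = sample(2:8, 1),
                       vg = runif(1, 0.2, 2), ve = runif(1, 0.5, 3), seed = i)
    fit <- fit_variance_components(dat$y, dat$g)
    oracle <- anova_oneway(dat$y, dat$g)
    if (oracle$msb >= oracle$msw) {
      expect_equal(fit$vg, oracle$vg, tolerance = 1e-6)
      expect_equal(fit$ve, oracle$ve, tolerance = 1e-6)
    } else {
      expect_equal(fit$vg, 0)
    }
  }
})

test_that("degenerate inputs and transformations behave as REML theory says", {
  # constant y
  fit <- fit_variance_components(rep(2, 20), rep(1:5, each = 4))
  expect_equal(c(fit$vg, fit$ve), c(0, 0))
  # shift invariance and c^2 scaling
  dat <- oneway_data(seed = 10)
  f1 <- fit_variance_components(dat$y, dat$g)
  f2 <- fit_variance_components(dat$y + 100, dat$g)
  f3 <- fit_variance_components(3 * dat$y, dat$g)
  expect_equal(f1$vg, f2$vg, tolerance = 1e-8)
  expect_equal(f1$vg * 9, f3$vg, tolerance = 1e-6)
  expect_error(fit_variance_components(rnorm(5), rep(1, 5)), "genotypes")
})

test_that("heritability statistic follows its definition", {
  expect_equal(heritability(1, 6, n = 6), 0.5)
  expect_equal(heritability(0, 3), 0)
  expect_equal(heritability(2, 0), 1)
  expect_equal(heritability(0, 0), 0)
  expect_error(heritability(-1, 1), ">= 0")
})

test_that("permutation p-value is 1 at the boundary and well-calibrated in shape", {
  dat <- oneway_data(n_geno = 20, n_rep = 3, vg = 0, ve = 1, seed = 3)
  # force a boundary estimate by using pure noise with few groups
  res <- permutation_heritability(rnorm(60), rep(1:20, each = 3), B = 99, seed = 1)
  if (res$h2_obs == 0) expect_equal(res$p, 1)
  expect_gte(res$p, 1 / 100)
  # strong signal: tiny p
  dat2 <- oneway_data(n_geno = 100, n_rep = 6, vg = 2, ve = 1, seed = 4)
  res2 <- permutation_heritability(dat2$y, dat2$g, B = 199, seed = 2)
  expect_equal(res2$p, 1 / 200)
})

test_that("BLUPs shrink, center, and approach genotype means as Ve -> 0", {
  set.seed(5)
  n_geno <- 40
  d <- simulate_design(n_geno, treatments = "plusN", seed = 6)
  u <- rnorm(n_geno, 0, 1)
  g_idx <- match(d$genotype, sprintf("G%04d", 1:n_geno))
  # near-zero residual: BLUPs equal centered genotype means
  y0 <- u[g_idx] + rnorm(nrow(d), 0, 1e-4)
  fit0 <- fit_blup(y0, d)
  means <- tapply(y0, d$genotype, mean)
  expect_lt(max(abs(fit0$blups$blup -
                      (means[fit0$blups$genotype] - mean(means)))), 1e-3)
  # realistic noise: centered and shrunk
  y1 <- u[g_idx] + rnorm(nrow(d), 0, 1)
  fit1 <- fit_blup(y1, d)
  expect_lt(abs(sum(fit1$blups$blup)), 1e-6 * nrow(d) * sd(y1))
  means1 <- tapply(y1, d$genotype, mean)
  expect_lt(var(fit1$blups$blup), var(means1 - mean(means1)))
  expect_equal(nrow(glance(fit1)), 1)
  # single genotype and aliased factors are errors
  expect_error(fit_blup(rnorm(6), d[d$genotype == d$genotype[1], ]), "genotypes")
  d_bad <- d; d_bad$block <- d_bad$genotype
  expect_error(fit_blup(y1, d_bad), "aliased")
})

test_that("BLUP accuracy increases with heritability", {
  g <- simulate_genotypes(100, 100, seed = 71)
  d <- simulate_design(rownames(g$dosage), treatments = "plusN", seed = 72)
  cors <- vapply(c(0.2, 0.5, 0.8), function(h2) {
    sim <- simulate_group_traits(g, d, h2_targets = h2, n_groups = 12,
                                 seed = 73 + round(100 * h2))
    # mean correlation between BLUP and true genotype effect across groups
    mean(vapply(sim$truth$group_id, function(k) {
      fb <- fit_blup(sim$traits$values[, k], sim$traits$sample_meta)
      if (sd(fb$blups$blup) == 0) return(0)  # Vg boundary: no accuracy
      snps <- sim$truth$causal_snps[[k]]
      b <- sim$truth$causal_effects[[k]]
      tru <- as.vector(g$dosage[, match(snps, colnames(g$dosage))] %*% b)
      cor(fb$blups$blup, tru[match(fb$blups$genotype, rownames(g$dosage))])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.7)
})

test_that("kinship and genotype PCA have the estimator's textbook properties", {
  g <- simulate_genotypes(60, 500, seed = 81)
  # duplicate an individual
  dose <- rbind(g$dosage, dup = g$dosage[1, ])
  rownames(dose) <- c(rownames(g$dosage), "dup")
  g2 <- genotype_matrix(dose, g$snp_map)
  K <- grm(g2)
  expect_equal(K["dup", rownames(g$dosage)[1]], K["dup", "dup"], tolerance = 1e-10)
  expect_equal(max(abs(K - t(K))), 0)
  # HWE panel: mean diagonal near 1
  expect_equal(mean(diag(grm(g))), 1, tolerance = 0.05)
  expect_error(genotype_pca(g, k = 60), "n - 1")
})

test_that("PC1 separates two simulated subpopulations", {
  set.seed(9)
  g1 <- simulate_genotypes(40, 300, maf_dist = function(n) runif(n, 0.05, 0.3),
                           seed = 91)
  g2 <- simulate_genotypes(40, 300, maf_dist = function(n) runif(n, 0.3, 0.5),
                           seed = 92)
  dose <- rbind(g1$dosage, g2$dosage)
  rownames(dose) <- sprintf("I%03d", 1:80)
  maf <- pmin(colMeans(dose) / 2, 1 - colMeans(dose) / 2)
  keep <- maf > 0
  gm <- genotype_matrix(dose[, keep], dplyr::mutate(g1$snp_map[keep, ], maf = maf[keep]))
  pcs <- genotype_pca(gm, k = 2)
  r <- cor(pcs[, 1], rep(c(0, 1), each = 40))
  expect_gt(abs(r), 0.9)
})

test_that("estimate_heritability returns a tidy per-trait, per-treatment table", {
  g <- simulate_genotypes(40, 60, seed = 95)
  d <- simulate_design(rownames(g$dosage), seed = 96)
  sim <- simulate_group_traits(g, d, h2_targets = c(0, 0.6), n_groups = 4, seed = 97)
  h <- estimate_heritability(sim$traits, B = 99, seed = 98)
  expect_equal(nrow(h), 8)
  expect_true(all(h$h2 >= 0 & h$h2 <= 1))
  expect_true(all(h$p >= 1 / 100 & h$p <= 1))
  expect_equal(unique(h$n), 6L)
})
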
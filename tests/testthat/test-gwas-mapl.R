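test_that("with identity kinship the mixed-model scan reduces to OLS", {
  g <- simulate_genotypes(100, 150, seed = 1)
  set.seed(2)
  y <- rnorm(100); names(y) <- rownames(g$dosage)
  K <- diag(100); dimnames(K) <- list(names(y), names(y))
  gw <- lmm_gwas(y, g, K = K, n_pcs = 0)
  idx <- sample(nrow(gw), 10)
  ols <- vapply(gw$snp_id[idx], function(s) {
    summary(lm(y ~ g$dosage[names(y), s]))$coefficients[2, 4]
  }, numeric(1))
  expect_equal(gw$p[idx], unname(ols), tolerance = 1e-8)
})

test_that("p3d and exact modes agree closely on simulated data", {
  sim <- planted_gwas_sim(n = 120, m = 250, h2_snp = 0.15, seed = 3)
  K <- grm(sim$geno)
  p3d <- lmm_gwas(sim$y, sim$geno, K = K)
  exact <- lmm_gwas(sim$y, sim$geno, K = K, mode = "exact")
  agree <- mean(abs(p3d$neg_log10_p - exact$neg_log10_p) <= 0.2)
  expect_gte(agree, 0.99)
})

test_that("kinship + PCs calibrate a structured null that inflates naive OLS", {
  set.seed(4)
  # two drifted subpopulations, phenotype = subpop shift + noise
  gA <- simulate_genotypes(125, 1500, maf_dist = function(n) runif(n, 0.05, 0.35),
                           seed = 5)
  gB <- simulate_genotypes(125, 1500, maf_dist = function(n) runif(n, 0.2, 0.5),
                           seed = 6)
  dose <- rbind(gA$dosage, gB$dosage)
  rownames(dose) <- sprintf("I%03d", 1:250)
  frq <- colMeans(dose) / 2
  keep <- frq > 0 & frq < 1
  maf <- pmin(frq, 1 - frq)[keep]
  gm <- genotype_matrix(dose[, keep], dplyr::mutate(gA$snp_map[keep, ], maf = maf))
  y <- rep(c(0, 1), each = 125) + rnorm(250, 0, 1)
  names(y) <- rownames(dose)
  gw <- lmm_gwas(y, gm)
  expect_gt(attr(gw, "lambda_gc"), 0.9)
  expect_lt(attr(gw, "lambda_gc"), 1.1)
  # naive OLS on the same data is inflated
  set.seed(7)
  idx <- sample(ncol(gm$dosage), 400)
  p_ols <- vapply(idx, function(j) {
    summary(lm(y ~ gm$dosage[, j]))$coefficients[2, 4]
  }, numeric(1))
  lambda_ols <- median(qchisq(1 - p_ols, 1)) / qchisq(0.5, 1)
  expect_gt(lambda_ols, 1.2)
})

test_that("effective SNP number tracks redundancy", {
  g <- simulate_genotypes(600, 300, ld_rho = 0, seed = 8)
  meff <- effective_snp_number(g)
  expect_gt(meff, 0.95 * 300)
  expect_lte(meff, 300)
  # duplicating every SNP halves the effective number
  dose <- cbind(g$dosage, g$dosage)
  ids <- c(g$snp_map$snp_id, paste0(g$snp_map$snp_id, "_dup"))
  colnames(dose) <- ids
  map <- dplyr::bind_rows(g$snp_map,
                          dplyr::mutate(g$snp_map,
                                        snp_id = paste0(snp_id, "_dup"),
                                        pos = pos + 1L))
  map <- dplyr::arrange(map, chrom, pos)
  # pair-sized blocks isolate each duplicate pair, whose correlation block is
  # exactly singular; the estimator must then count one test per pair
  g2 <- genotype_matrix(dose[, map$snp_id], map)
  meff2 <- effective_snp_number(g2, block_size = 2)
  expect_lt(abs(meff2 - 300) / 300, 0.1)
  # user-supplied passthrough
  expect_equal(effective_snp_number(g, method = "user_supplied", meff = 769690),
               769690)
})

test_that("the Bonferroni threshold is plain arithmetic", {
  expect_equal(significance_threshold(0.05, 1), -log10(0.05), tolerance = 1e-10)
  expect_equal(significance_threshold(1, 1), 0)
  expect_equal(significance_threshold(0.05, 100), log10(100 / 0.05))
})

test_that("MAPL windowing follows the fixed 10-kb grid and tallies per association", {
  base <- tibble::tibble(
    group_id = "g1", treatment = "plusN", chrom = "chr1",
    pos = c(5L, 9999L, 10000L), neg_log10_p = 9
  )
  m <- call_mapls(base, window_bp = 10000, threshold = 7.2, min_signals = 1)
  expect_equal(m$window, c(0L, 1L))
  expect_equal(m$n_signals, c(2L, 1L))
  expect_equal(m$start, c(0L, 10000L))
  expect_equal(m$end, c(10000L, 20000L))
  m2 <- call_mapls(base, window_bp = 10000, threshold = 7.2, min_signals = 2)
  expect_equal(nrow(m2), 1)

  # the same SNP significant for two traits counts twice
  two <- dplyr::bind_rows(base[1, ], dplyr::mutate(base[1, ], group_id = "g2"))
  m3 <- call_mapls(two, window_bp = 10000, threshold = 7.2)
  expect_equal(m3$n_signals, 2L)
  expect_equal(m3$n_traits, 2L)

  # nothing significant -> empty; order invariance
  expect_equal(nrow(call_mapls(base, threshold = 20, window_bp = 10000)), 0)
  shuffled <- two[sample(nrow(two)), ]
  expect_identical(call_mapls(two, window_bp = 10000, threshold = 7.2),
                   call_mapls(shuffled, window_bp = 10000, threshold = 7.2))
})

test_that("gene containment within the flank matches a brute-force interval check", {
  mapls <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"), window = c(0L, 5L, 2L),
    start = c(0L, 50000L, 20000L), end = c(10000L, 60000L, 30000L),
    n_signals = 2L, n_traits = 1L, group_ids = "g1", treatments = "plusN"
  )
  set.seed(9)
  genes <- tibble::tibble(
    gene_id = sprintf("gene%03d", 1:60),
    chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
    start = sample.int(80000, 60),
    strand = "+"
  ) |> dplyr::mutate(end = start + sample.int(15000, 60))
  got <- annotate_mapl_genes(mapls, genes, flank = 10000)
  for (i in 1:3) {
    oracle <- genes$gene_id[
      genes$chrom == mapls$chrom[i] &
        (genes$start - 1) >= (mapls$start[i] - 10000) &
        genes$end <= (mapls$end[i] + 10000)
    ]
    mine <- setdiff(strsplit(got$genes[i], ",")[[1]], "")
    expect_setequal(mine, oracle)
  }
  # boundary: fully inside kept, straddling excluded
  g2 <- tibble::tibble(gene_id = c("in", "out"), chrom = "chr1",
                       start = c(1L, 15000L), end = c(100L, 25000L), strand = "+")
  got2 <- annotate_mapl_genes(mapls[1, ], g2, flank = 10000)
  expect_equal(got2$genes, "in")
  # chromosome mismatch warns
  g3 <- dplyr::mutate(g2, chrom = "10")
  expect_warning(annotate_mapl_genes(mapls[1, ], g3), "chromosome")
})

test_that("allele stratification compares major homozygotes to minor carriers", {
  set.seed(10)
  g <- simulate_genotypes(200, 50, seed = 11)
  snp <- g$snp_map$snp_id[which(g$snp_map$maf > 0.2)[1]]
  dose <- g$dosage[, snp]
  vals <- rnorm(200) + (dose > 0) * 1.0   # 1 SD shift for carriers
  names(vals) <- rownames(g$dosage)
  res <- allele_stratified_comparison(g, snp, vals)
  expect_equal(res$allele_group, c("major", "minor"))
  expect_lt(res$p[1], 0.01)
  expect_gt(res$mean[res$allele_group == "minor"],
            res$mean[res$allele_group == "major"])
  # monomorphic SNP errors
  g$dosage[, 2] <- 0
  mono <- genotype_matrix(g$dosage,
                          dplyr::mutate(g$snp_map,
                                        maf = pmax(pmin(colMeans(g$dosage) / 2, 0.5), 1e-6)))
  expect_error(allele_stratified_comparison(mono, mono$snp_map$snp_id[2], vals),
               "monomorphic")
  # tiny group suppresses p but keeps means
  rare_vals <- vals[1:5]
  res2 <- suppressWarnings(tryCatch(
    allele_stratified_comparison(g, snp, rare_vals, min_group = 4),
    error = function(e) NULL
  ))
  if (!is.null(res2)) expect_true(all(!is.na(res2$mean)))
})

test_that("an LD r2 matrix is available for locus zoom plots", {
  g <- simulate_genotypes(100, 50, ld_rho = 0.9, block_len = 10, n_chrom = 1,
                          seed = 12)
  r2 <- ld_matrix(g, "chr1", 1, 50000)
  expect_equal(dim(r2), c(50, 50))
  expect_equal(diag(r2), rep(1, 50), ignore_attr = TRUE)
  expect_error(ld_matrix(g, "chr1", 1, 1500), "fewer than two")
})
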
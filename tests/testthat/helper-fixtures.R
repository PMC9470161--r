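# Small in-code fixtures shared across test files.

# minimal valid ASV table: n_samp samples x n_asv ASVs with a 2-year,
# 2-treatment design
toy_asv_table <- function(n_samp = 8, n_asv = 4, seed = 1, counts = NULL) {
  set.seed(seed)
  if (is.null(counts)) {
    counts <- matrix(rpois(n_samp * n_asv, 50), n_samp, n_asv)
  }
  rownames(counts) <- sprintf("s%02d", seq_len(n_samp))
  colnames(counts) <- sprintf("ASV%d", seq_len(ncol(counts)))
  meta <- tibble::tibble(
    sample_id = rownames(counts),
    genotype = rep(sprintf("G%d", 1:2), length.out = n_samp),
    treatment = rep(c("plusN", "minusN"), each = ceiling(n_samp / 2))[seq_len(n_samp)],
    year = rep(c(2018, 2019), length.out = n_samp),
    block = "b1", sp = "sp1", spb = "spb1", replicate = 1
  )
  tax <- tibble::tibble(
    asv_id = colnames(counts),
    kingdom = "Bacteria", phylum = "P", class = "C", order = "O",
    family = paste0("Fam", rep(1:2, length.out = ncol(counts))),
    genus = paste0("Gen", seq_len(ncol(counts))),
    species = "Unknown"
  )
  asv_table(counts, meta, tax)
}

# balanced one-way layout with known variance components
oneway_data <- function(n_geno = 30, n_rep = 6, vg = 1, ve = 2, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_geno), each = n_rep)
  y <- rnorm(n_geno, 0, sqrt(vg))[g] + rnorm(n_geno * n_rep, 0, sqrt(ve))
  list(y = y, g = g)
}

# balanced one-way ANOVA (method-of-moments) estimator: the closed-form
# REML oracle for balanced data
anova_oneway <- function(y, g) {
  n <- as.integer(table(g)[1])
  a <- length(unique(g))
  means <- tapply(y, g, mean)
  msb <- n * sum((means - mean(y))^2) / (a - 1)
  msw <- sum((y - means[as.character(g)])^2) / (a * n - a)
  list(vg = max(0, (msb - msw) / n), msb = msb, msw = msw, ve = msw)
}

# standard normal trait with a planted causal SNP
planted_gwas_sim <- function(n = 250, m = 2000, h2_snp = 0.2, seed = 1) {
  geno <- simulate_genotypes(n, m, ld_rho = 0.8, block_len = 20, seed = seed)
  set.seed(seed + 5000)
  cs <- sample(m, 1)
  x <- geno$dosage[, cs]
  while (stats::sd(x) == 0) {
    cs <- sample(m, 1); x <- geno$dosage[, cs]
  }
  y <- scale(x)[, 1] * sqrt(h2_snp) + rnorm(n, 0, sqrt(1 - h2_snp))
  names(y) <- rownames(geno$dosage)
  list(geno = geno, y = y, causal = geno$snp_map[cs, ])
}
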
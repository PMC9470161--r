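#' Simulate a SNP panel with block LD
#'
#' Haplotypes are built by a first-order copying chain: within blocks of
#' `block_len` SNPs, each site copies the previous site's allele with
#' probability `ld_rho`, otherwise draws a fresh Bernoulli(p) allele; blocks
#' (and chromosomes) are independent. Dosage is the sum of two haplotypes,
#' oriented to the cohort minor allele. Monomorphic sites are resampled.
#'
#' @param n_ind number of individuals (inbred-line analogues), >= 2.
#' @param n_snp number of SNPs.
#' @param maf_dist function `n -> p` sampling allele frequencies in
#'   (0.01, 0.5]; default uniform on (0.05, 0.5).
#' @param ld_rho within-block copying probability in `[0, 1)`.
#' @param block_len SNPs per LD block.
#' @param n_chrom chromosomes; SNPs are split evenly.
#' @param spacing_bp distance between adjacent SNPs (bp).
#' @param seed RNG seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_ind, n_snp, maf_dist = function(n) runif(n, 0.05, 0.5),
                               ld_rho = 0, block_len = 20, n_chrom = 2,
                               spacing_bp = 1000, seed = 1) {
  if (n_ind < 2) abort("n_ind must be >= 2.")
  stopifnot(ld_rho >= 0, ld_rho < 1)
  set.seed(seed)
  p <- maf_dist(n_snp)
  n_hap <- 2L * n_ind
  draw_block <- function(p_block) {
    len <- length(p_block)
    fresh <- matrix(rbinom(n_hap * len, 1L, rep(p_block, each = n_hap)), n_hap, len)
    if (ld_rho == 0 || len == 1) return(fresh)
    h <- fresh
    copy <- matrix(runif(n_hap * len) < ld_rho, n_hap, len)
    for (j in 2:len) {
      h[, j] <- ifelse(copy[, j], h[, j - 1L], fresh[, j])
    }
    h
  }
  per_chrom <- diff(round(seq(0, n_snp, length.out = n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per_chrom)
  block <- unlist(lapply(per_chrom, function(m) rep(seq_len(ceiling(m / block_len)), each = block_len)[seq_len(m)]))
  block_id <- paste(chrom, block)
  hap <- matrix(0L, n_hap, n_snp)
  for (b in unique(block_id)) {
    idx <- which(block_id == b)
    hap[, idx] <- draw_block(p[idx])
  }
  dosage <- hap[seq_len(n_ind), , drop = FALSE] + hap[n_ind + seq_len(n_ind), , drop = FALSE]
  # resample monomorphic sites as fresh independent draws
  mono <- which(apply(dosage, 2, function(x) length(unique(x)) == 1))
  for (j in mono) {
    repeat {
      x <- rbinom(n_ind, 2L, p[j])
      if (length(unique(x)) > 1) break
    }
    dosage[, j] <- x
  }
  freq <- colMeans(dosage) / 2
  flip <- freq > 0.5
  dosage[, flip] <- 2L - dosage[, flip]
  maf <- pmin(freq, 1 - freq)
  pos <- unlist(lapply(per_chrom, function(m) seq_len(m) * spacing_bp))
  snp_id <- paste0(chrom, "_", pos)
  rownames(dosage) <- sprintf("G%04d", seq_len(n_ind))
  colnames(dosage) <- snp_id
  genotype_matrix(dosage, tibble(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
    allele_major = "A", allele_minor = "B", maf = maf
  ))
}

#' Simulate the split-plot field design
#'
#' Each genotype appears once per replicate quadrant of each nitrogen
#' treatment, with `samples_per_plot` rhizosphere samples per plot (the
#' field default of 2 replicates x 3 samples gives n = 6 per
#' genotype-treatment). Within a quadrant, genotypes are laid out in an
#' incomplete-block arrangement: seeded shuffle, then nested chunking into
#' blocks, split plots, and split-plot blocks.
#'
#' @param genotypes character vector of genotype ids (or an integer count).
#' @param treatments treatment labels.
#' @param reps_per_treatment replicate quadrants per treatment.
#' @param samples_per_plot rhizosphere samples per plot.
#' @param block_size genotypes per incomplete block.
#' @param year year label carried into the metadata.
#' @param seed RNG seed (layout shuffle).
#' @return tibble of sample rows: `sample_id`, `genotype`, `treatment`,
#'   `year`, `block`, `sp`, `spb`, `replicate`.
#' @export
simulate_design <- function(genotypes, treatments = c("plusN", "minusN"),
                            reps_per_treatment = 2, samples_per_plot = 3,
                            block_size = 30, year = 2019, seed = 1) {
  if (is.numeric(genotypes) && length(genotypes) == 1) {
    genotypes <- sprintf("G%04d", seq_len(genotypes))
  }
  set.seed(seed)
  rows <- list()
  for (trt in treatments) {
    for (rep_i in seq_len(reps_per_treatment)) {
      quad <- paste0(trt, "_q", rep_i)
      ord <- sample(genotypes)
      idx <- seq_along(ord)
      blk <- ceiling(idx / block_size)
      sp <- ceiling((idx - (blk - 1) * block_size) / max(1, block_size %/% 2))
      spb <- ceiling((idx - (blk - 1) * block_size) / max(1, block_size %/% 4))
      rows[[quad]] <- tibble(
        genotype = ord, treatment = trt, year = year,
        block = paste0(quad, "_b", blk),
        sp = paste0(quad, "_b", blk, "_s", sp),
        spb = paste0(quad, "_b", blk, "_sb", spb),
        replicate = rep_i
      )
    }
  }
  plots <- list_rbind(rows)
  out <- plots[rep(seq_len(nrow(plots)), each = samples_per_plot), ]
  out$sample_rep <- rep(seq_len(samples_per_plot), nrow(plots))
  out$sample_id <- sprintf(
    "S_%s_%s_r%d_%d", out$genotype, out$treatment, out$replicate, out$sample_rep
  )
  select(out, "sample_id", "genotype", "treatment", "year", "block",
         "sp", "spb", "replicate")
}

#' Simulate rhizobiome traits as overdispersed counts with known heritability
#'
#' Builds a latent sample-level value per microbial group,
#' `y = mu + treatment + g(genotype) + block + sp + spb + e`, with the
#' genotype effect a sum over causal SNPs whose effect variances follow the
#' BayesS generative law (proportional to `(2 p (1-p))^S`), scaled so that
#' the repeatability-style heritability `Vg / (Vg + Vng/n)` hits the target
#' (with `Vng` the total non-genetic sample-level variance, which is what the
#' downstream single-term estimator sees as error). Counts are realised by
#' drawing each group's count from a negative binomial whose mean is
#' `depth * softmax(y)` across groups, then splitting the group count across
#' its member ASVs multinomially.
#'
#' @param geno [genotype_matrix()]; rownames are the genotype ids of the design.
#' @param design design tibble from [simulate_design()].
#' @param h2_targets per-trait target heritability in `[0, 1)` (recycled).
#' @param n_groups number of microbial groups (traits); defaults to
#'   `length(h2_targets)`.
#' @param n_causal causal SNPs per trait.
#' @param s_arch architecture parameter S of the effect-variance law.
#' @param treat_effect_sd SD of the per-group nitrogen-treatment shift on the
#'   latent log scale.
#' @param v_design variance of each design component (block, sp, spb).
#' @param v_e residual latent variance.
#' @param depth sequencing depth per sample (total expected counts).
#' @param nb_size negative-binomial size (inverse overdispersion).
#' @param asvs_per_group member ASVs per group are drawn uniformly from this set.
#' @param seed RNG seed.
#' @return list with `asv` ([asv_table()]), `traits` ([trait_matrix()] of ln
#'   relative abundances), and `truth` (a `sim_truth` list: targets, causal
#'   sets and effects, variance components, seeds).
#' @export
simulate_group_traits <- function(geno, design, h2_targets, n_groups = NULL,
                                  n_causal = 20, s_arch = 0,
                                  treat_effect_sd = 0.5,
                                  v_design = c(block = 0, sp = 0, spb = 0),
                                  v_e = 0.5, depth = 30000, nb_size = 25,
                                  asvs_per_group = 1:4, seed = 1) {
  if (any(h2_targets >= 1 | h2_targets < 0)) abort("h2 targets must lie in [0, 1).")
  set.seed(seed)
  n_groups <- n_groups %||% length(h2_targets)
  h2 <- rep_len(h2_targets, n_groups)
  X <- geno$dosage
  genos <- rownames(X)
  miss <- setdiff(unique(design$genotype), genos)
  if (length(miss) > 0) abort("design genotypes absent from the genotype matrix.")
  n_samp <- nrow(design)
  n_per <- sum(design$genotype == design$genotype[1] &
                 design$treatment == design$treatment[1])
  v_ng <- sum(v_design) + v_e
  maf <- geno$snp_map$maf
  arch_w <- (2 * maf * (1 - maf))^s_arch

  groups <- sprintf("grp%03d", seq_len(n_groups))
  mu <- rnorm(n_groups, 0, 1)
  treat_delta <- rnorm(n_groups, 0, treat_effect_sd)
  causal <- list(); betas <- list()
  g_mat <- matrix(0, n_samp, n_groups)  # genotype effect per sample
  vg_true <- numeric(n_groups)
  geno_idx <- match(design$genotype, genos)
  for (k in seq_len(n_groups)) {
    vg <- if (h2[k] == 0) 0 else h2[k] / (1 - h2[k]) * v_ng / n_per
    vg_true[k] <- vg
    cs <- sort(sample(ncol(X), n_causal))
    b <- rnorm(n_causal, 0, sqrt(arch_w[cs]))
    g <- as.vector(X[, cs, drop = FALSE] %*% b)
    g <- g - mean(g)
    sdg <- sd(g)
    if (vg == 0 || sdg == 0) {
      b <- b * 0; g <- g * 0
    } else {
      scl <- sqrt(vg) / sdg
      b <- b * scl; g <- g * scl
    }
    causal[[k]] <- geno$snp_map$snp_id[cs]
    betas[[k]] <- b
    g_mat[, k] <- g[geno_idx]
  }
  # design random effects, shared across groups only through their labels
  ran_col <- function(labels, v) {
    u <- rnorm(length(unique(labels)), 0, sqrt(v))
    u[match(labels, unique(labels))]
  }
  y <- matrix(0, n_samp, n_groups)
  trt_sign <- ifelse(design$treatment == design$treatment[1], 0.5, -0.5)
  for (k in seq_len(n_groups)) {
    y[, k] <- mu[k] + trt_sign * treat_delta[k] + g_mat[, k] +
      ran_col(design$block, v_design[["block"]]) +
      ran_col(design$sp, v_design[["sp"]]) +
      ran_col(design$spb, v_design[["spb"]]) +
      rnorm(n_samp, 0, sqrt(v_e))
  }
  # counts: NB around depth * softmax(y), split over member ASVs
  prop <- exp(y - apply(y, 1, function(r) log(sum(exp(r)))))
  grp_counts <- matrix(
    rnbinom(n_samp * n_groups, size = nb_size, mu = depth * prop),
    n_samp, n_groups
  )
  n_asv <- sample(asvs_per_group, n_groups, replace = TRUE)
  asv_group <- rep(groups, n_asv)
  asv_ids <- sprintf("ASV%04d", seq_along(asv_group))
  split_w <- lapply(n_asv, function(m) {
    w <- rgamma_pos(m)
    w / sum(w)
  })
  counts <- matrix(0L, n_samp, length(asv_ids))
  col0 <- c(0, cumsum(n_asv))
  for (k in seq_len(n_groups)) {
    cols <- (col0[k] + 1):col0[k + 1]
    if (length(cols) == 1) {
      counts[, cols] <- grp_counts[, k]
    } else {
      counts[, cols] <- t(vapply(
        grp_counts[, k],
        function(n) as.integer(rmultinom(1, n, split_w[[k]])),
        integer(length(cols))
      ))
    }
  }
  rownames(counts) <- design$sample_id
  colnames(counts) <- asv_ids
  taxonomy <- tibble(
    asv_id = asv_ids,
    kingdom = "Bacteria", phylum = "SimPhylum", class = "SimClass",
    order = "SimOrder",
    family = paste0("Family", ceiling(match(asv_group, groups) / 5)),
    genus = paste0("Genus", match(asv_group, groups)),
    species = "Unknown"
  )
  tab <- asv_table(counts, design, taxonomy)
  gmap <- tibble(asv_id = asv_ids, group_id = asv_group)
  traits <- transform_abundance(tab, gmap)
  truth <- structure(list(
    group_id = groups, h2_target = h2, vg = vg_true,
    v_design = v_design, v_e = v_e, v_ng = v_ng, n_per = n_per,
    mu = mu, treat_delta = treat_delta,
    causal_snps = setNames(causal, groups), causal_effects = setNames(betas, groups),
    s_true = s_arch, pi_true = n_causal / ncol(X),
    group_map = gmap, seed = seed
  ), class = "sim_truth")
  list(asv = tab, traits = traits, truth = truth)
}

# gamma(2,1) weights, strictly positive, for within-group ASV proportions
rgamma_pos <- function(m) stats::rgamma(m, shape = 2, rate = 1) + 1e-6

#' Simulate a fitness proxy (canopy coverage) under known selection
#'
#' Relative fitness is generated on the mean-one scale,
#' `w_i = 1 + sum_k s_k z_ik + 0.5 * sum_k c_k z_ik^2 + eps_i`, so the
#' generating `s` and `c` are directly the linear and quadratic
#' Lande-Arnold differentials of the standardized traits. Canopy coverage is
#' `w * cc_mean`. Non-positive fitness values are floored at a small
#' positive value with a logged count.
#'
#' @param z matrix of standardized trait values (genotypes x traits) or a
#'   vector for a single trait.
#' @param s_vec,c_vec linear and quadratic differentials per trait.
#' @param noise_sd SD of the fitness noise.
#' @param cc_mean mean canopy coverage (percent) used to scale w.
#' @param seed RNG seed.
#' @return list with `cc` (named vector), `w`, and `truth`
#'   (`s_true`, `c_true`, `noise_sd`, number of floored values).
#' @export
simulate_fitness <- function(z, s_vec, c_vec = 0, noise_sd = 0, cc_mean = 50,
                             seed = 1) {
  z <- as.matrix(z)
  s_vec <- rep_len(s_vec, ncol(z))
  c_vec <- rep_len(c_vec, ncol(z))
  set.seed(seed)
  w <- 1 + as.vector(z %*% s_vec) + 0.5 * as.vector(z^2 %*% c_vec) +
    rnorm(nrow(z), 0, noise_sd)
  n_floor <- sum(w <= 0)
  if (n_floor > 0) {
    warn(sprintf("flooring %d non-positive fitness values at 1e-6", n_floor))
    w[w <= 0] <- 1e-6
  }
  cc <- w * cc_mean
  names(cc) <- rownames(z)
  list(cc = cc, w = w,
       truth = list(s_true = s_vec, c_true = c_vec, noise_sd = noise_sd,
                    n_floored = n_floor, seed = seed))
}

#' Simulate a gene expression table with a root-tissue shift for MAPL genes
#'
#' Log-normal expression per (gene, tissue); genes in `mapl_gene_ids` get a
#' log-scale mean shift of `root_boost` in the designated root tissues only.
#'
#' @param n_genes total genes (ids `gene00001`...), including the MAPL set.
#' @param mapl_gene_ids character ids of the MAPL gene set (subset of all).
#' @param tissues tissue labels.
#' @param root_tissues tissues receiving the boost.
#' @param root_boost log2-scale mean shift, >= 0.
#' @param seed RNG seed.
#' @return tibble `gene_id`, `tissue`, `expression` (raw scale).
#' @export
simulate_expression <- function(n_genes, mapl_gene_ids = character(),
                                tissues = c("germinating_root", "germinating_shoot", "leaf"),
                                root_tissues = "germinating_root",
                                root_boost = 0, seed = 1) {
  stopifnot(root_boost >= 0)
  set.seed(seed)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  if (!all(mapl_gene_ids %in% gene_ids)) {
    gene_ids <- unique(c(gene_ids, mapl_gene_ids))
  }
  base <- rnorm(length(gene_ids), 5, 1.5)
  out <- tidyr::expand_grid(gene_id = gene_ids, tissue = tissues)
  out$log2_expr <- base[match(out$gene_id, gene_ids)] +
    rnorm(nrow(out), 0, 0.8) +
    ifelse(out$gene_id %in% mapl_gene_ids & out$tissue %in% root_tissues,
           root_boost, 0)
  out$expression <- 2^out$log2_expr - 1
  out$expression[out$expression < 0] <- 0
  select(out, "gene_id", "tissue", "expression")
}
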
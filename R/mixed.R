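# Profiled REML for the one-way random-intercept model y = mu + g + e.
# Group-wise sufficient statistics make one likelihood evaluation O(#groups),
# which is what lets the permutation null refit the model 10^5 times.
# lambda = Vg/Ve; profiled criterion (-2 restricted loglik up to a constant):
#   f(lambda) = (N-1) log sigma_e^2(lambda) + sum log(1 + lambda n_i)
#               + log sum w_i,   w_i = n_i/(1 + lambda n_i)
# with sigma_e^2(lambda) = [SSW + sum w_i (ybar_i - mu)^2] / (N - 1)
# and mu the GLS mean sum(w_i ybar_i)/sum(w_i).
reml_oneway <- function(y, g) {
  g <- as.integer(factor(g))
  N <- length(y)
  n_i <- tabulate(g)
  sum_i <- rowsum(y, g)[, 1]
  ybar <- sum_i / n_i
  ssw <- sum(y^2) - sum(sum_i^2 / n_i)
  crit <- function(log_lambda) {
    lambda <- exp(log_lambda)
    w <- n_i / (1 + lambda * n_i)
    mu <- sum(w * ybar) / sum(w)
    q <- ssw + sum(w * (ybar - mu)^2)
    s2 <- q / (N - 1)
    (N - 1) * log(s2) + sum(log1p(lambda * n_i)) + log(sum(w))
  }
  if (var(y) == 0) {
    return(list(vg = 0, ve = 0, lambda = 0, boundary = TRUE))
  }
  opt <- optimize(crit, interval = c(-25, 25), tol = 1e-10)
  # boundary Vg = 0: iid model with REML variance SST/(N-1)
  sst <- sum((y - mean(y))^2)
  crit0 <- (N - 1) * log(sst / (N - 1)) + log(N)
  if (crit0 <= opt$objective) {
    return(list(vg = 0, ve = sst / (N - 1), lambda = 0, boundary = TRUE))
  }
  lambda <- exp(opt$minimum)
  w <- n_i / (1 + lambda * n_i)
  mu <- sum(w * ybar) / sum(w)
  ve <- (ssw + sum(w * (ybar - mu)^2)) / (N - 1)
  list(vg = lambda * ve, ve = ve, lambda = lambda, boundary = FALSE)
}

#' REML variance components for a random-intercept genotype model
#'
#' Fits `y = mu + (1|genotype) [+ extras] + e` by REML. With genotype as the
#' only random term the profiled one-dimensional likelihood is optimised
#' directly (fast enough to sit inside permutation loops); with extra random
#' terms the fit is delegated to [lme4::lmer()]. Variance estimates are
#' constrained to the boundary (>= 0).
#'
#' @param y numeric response (sample level).
#' @param genotype genotype labels, one per sample.
#' @param extra_random optional named list of additional grouping vectors
#'   (e.g. `list(block = ...)`).
#' @return list with `vg`, `ve`, `extras` (named numeric), `boundary`.
#' @export
fit_variance_components <- function(y, genotype, extra_random = NULL) {
  if (length(unique(genotype)) < 2) abort("need >= 2 genotypes.")
  if (min(tabulate(factor(genotype))) < 2 && length(extra_random) == 0) {
    warn("some genotypes have a single observation; Vg weakly identified.")
  }
  if (is.null(extra_random) || length(extra_random) == 0) {
    fit <- reml_oneway(y, genotype)
    return(list(vg = fit$vg, ve = fit$ve, extras = numeric(0),
                boundary = fit$boundary))
  }
  df <- data.frame(y = y, genotype = genotype, extra_random,
                   check.names = TRUE, stringsAsFactors = FALSE)
  terms <- c("(1|genotype)", paste0("(1|", setdiff(names(df), c("y", "genotype")), ")"))
  fml <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
  m <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(m))
  vg <- vc$vcov[vc$grp == "genotype"]
  ve <- vc$vcov[vc$grp == "Residual"]
  extras <- setNames(
    vc$vcov[!vc$grp %in% c("genotype", "Residual")],
    vc$grp[!vc$grp %in% c("genotype", "Residual")]
  )
  list(vg = vg, ve = ve, extras = extras, boundary = vg < 1e-10)
}

#' Repeatability-style heritability
#'
#' `h2 = Vg / (Vg + Ve / n)`, the variance among genotype means attributable
#' to genotype, where `n` is the number of samples per genotype entering the
#' mean (field default n = 6: 2 replicate plots x 3 samples). Defined as 0
#' when both components are 0.
#'
#' @param vg,ve genotype and error variance components (>= 0).
#' @param n samples per genotype in the denominator.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(vg, ve, n = 6) {
  if (any(vg < 0) || any(ve < 0)) abort("variance components must be >= 0.")
  ifelse(vg == 0 & ve == 0, 0, vg / (vg + ve / n))
}

#' Permutation test for heritability
#'
#' Shuffles the genotype labels across samples `B` times, re-estimates h2
#' for each shuffle, and reports
#' `p = (#\{h2_perm >= h2_obs\} + 1) / (B + 1)`.
#'
#' @param y numeric response.
#' @param genotype genotype labels.
#' @param n samples per genotype for the h2 denominator.
#' @param B number of permutations (>= 99).
#' @param seed RNG seed.
#' @return list with `h2_obs`, `p`, `B`, `h2_perm`.
#' @export
permutation_heritability <- function(y, genotype, n = 6, B = 1000, seed = 1) {
  if (B < 99) warn("B < 99 gives coarse p-value resolution.")
  fit <- reml_oneway(y, genotype)
  h2_obs <- heritability(fit$vg, fit$ve, n)
  set.seed(seed)
  h2_perm <- vapply(seq_len(B), function(b) {
    f <- reml_oneway(y, sample(genotype))
    heritability(f$vg, f$ve, n)
  }, numeric(1))
  p <- (sum(h2_perm >= h2_obs - 1e-12) + 1) / (B + 1)
  list(h2_obs = h2_obs, p = p, B = B, h2_perm = h2_perm)
}

#' Heritability of every rhizobiome trait, per treatment
#'
#' Runs the single-term REML fit and the permutation null for each trait
#' group within each nitrogen treatment.
#'
#' @param traits [trait_matrix()].
#' @param n samples per genotype (default inferred as the modal count).
#' @param B permutations per trait.
#' @param seed RNG seed (one stream, advanced per trait).
#' @return tibble: `group_id`, `treatment`, `vg`, `ve`, `n`, `h2`, `p`, `B`.
#' @export
estimate_heritability <- function(traits, n = NULL, B = 1000, seed = 1) {
  stopifnot(inherits(traits, "trait_matrix"))
  meta <- traits$sample_meta
  out <- list()
  for (trt in unique(meta$treatment)) {
    idx <- which(meta$treatment == trt)
    geno <- meta$genotype[idx]
    n_trt <- n %||% as.integer(names(sort(-table(table(geno))))[1])
    for (g in colnames(traits$values)) {
      pt <- permutation_heritability(
        traits$values[idx, g], geno, n = n_trt, B = B,
        seed = seed + length(out)
      )
      fitc <- reml_oneway(traits$values[idx, g], geno)
      out[[length(out) + 1]] <- tibble(
        group_id = g, treatment = trt, vg = fitc$vg, ve = fitc$ve,
        n = n_trt, h2 = pt$h2_obs, p = pt$p, B = B
      )
    }
  }
  list_rbind(out)
}

#' Multi-term BLUPs for the field design
#'
#' Fits `y ~ (1|genotype) + (1|block) + (1|sp) + (1|spb)` by REML
#' ([lme4::lmer()]) and returns the genotype BLUPs (which shrink noisy
#' genotype means toward zero) plus variance components.
#'
#' @param y numeric response (sample level).
#' @param design tibble with `genotype`, `block`, `sp`, `spb`.
#' @return list of class `blup_fit`: `blups` (tibble `genotype`, `blup`),
#'   `varcomp` (named numeric), `model`.
#' @export
fit_blup <- function(y, design) {
  need <- c("genotype", "block", "sp", "spb")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0("design is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (length(unique(design$genotype)) < 2) abort("need >= 2 genotypes.")
  for (f in c("block", "sp", "spb")) {
    tab <- table(design$genotype, design[[f]])
    one_to_one <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    if (one_to_one && length(unique(design[[f]])) == length(unique(design$genotype))) {
      abort(sprintf("design factor '%s' is aliased with genotype.", f))
    }
  }
  df <- data.frame(y = y, design[need])
  m <- suppressMessages(lme4::lmer(
    y ~ (1 | genotype) + (1 | block) + (1 | sp) + (1 | spb),
    data = df, REML = TRUE
  ))
  re <- lme4::ranef(m)$genotype
  vc <- as.data.frame(lme4::VarCorr(m))
  structure(list(
    blups = tibble(genotype = rownames(re), blup = re[, 1]),
    varcomp = setNames(vc$vcov, vc$grp),
    model = m
  ), class = "blup_fit")
}

#' @method tidy blup_fit
#' @export
tidy.blup_fit <- function(x, ...) x$blups

#' @method glance blup_fit
#' @export
glance.blup_fit <- function(x, ...) {
  as_tibble(as.list(x$varcomp)) %>%
    rename_with(~ paste0("v_", tolower(.x)))
}

#' BLUPs of every rhizobiome trait, per treatment
#'
#' @param traits [trait_matrix()].
#' @return tibble `genotype`, `treatment`, `group_id`, `blup`.
#' @export
compute_blups <- function(traits) {
  stopifnot(inherits(traits, "trait_matrix"))
  meta <- traits$sample_meta
  out <- list()
  for (trt in unique(meta$treatment)) {
    idx <- which(meta$treatment == trt)
    for (g in colnames(traits$values)) {
      fit <- fit_blup(traits$values[idx, g], meta[idx, ])
      out[[length(out) + 1]] <- fit$blups %>%
        mutate(treatment = trt, group_id = g)
    }
  }
  list_rbind(out) %>% select("genotype", "treatment", "group_id", "blup")
}

#' Genomic relationship (kinship) matrix
#'
#' Centered (VanRaden) estimator `K = W W' / (2 sum p_j (1 - p_j))` with `W`
#' the column-centered dosage matrix; missing dosages are mean-imputed.
#'
#' @param geno [genotype_matrix()].
#' @return symmetric n x n matrix with individual ids as dimnames.
#' @export
grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosage
  mu <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  p <- mu / 2
  W <- sweep(X, 2, mu)
  denom <- 2 * sum(p * (1 - p))
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

#' Top principal components of the genotype panel
#'
#' Eigenvectors of the kinship matrix scaled by the square root of their
#' eigenvalues (the usual GWAS population-structure covariates).
#'
#' @param geno [genotype_matrix()] (or a precomputed kinship via `K`).
#' @param k number of components (must be < n).
#' @param K optional kinship matrix to reuse.
#' @return matrix n x k with columns `PC1..k`.
#' @export
genotype_pca <- function(geno, k = 3, K = NULL) {
  K <- K %||% grm(geno)
  n <- nrow(K)
  if (k > n - 1) abort("k must be <= n - 1.")
  eg <- eigen(K, symmetric = TRUE)
  pcs <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  dimnames(pcs) <- list(rownames(K), paste0("PC", seq_len(k)))
  pcs
}
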
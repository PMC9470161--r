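#' Greedy windowed LD pruning
#'
#' Keeps an approximately LD-independent SNP set: after a MAF filter,
#' windows of width `window_kb` (anchored at every `step_snps`-th surviving
#' SNP within each chromosome) are scanned and, for any pair with
#' `r^2 >= r2_max`, the lower-MAF SNP is removed (ties: the larger position
#' goes).
#'
#' @param geno [genotype_matrix()] with `snp_map` sorted by (chrom, pos).
#' @param window_kb window width in kb.
#' @param step_snps window advance in SNPs.
#' @param r2_max squared-correlation threshold at or above which one of a
#'   pair is pruned.
#' @param maf_min MAF filter applied first.
#' @return Pruned [genotype_matrix()].
#' @export
ld_prune <- function(geno, window_kb = 100, step_snps = 100, r2_max = 0.1,
                     maf_min = 0.01) {
  stopifnot(inherits(geno, "genotype_matrix"))
  keep_maf <- geno$snp_map$maf >= maf_min
  geno <- subset_genotypes(geno, snps = which(keep_maf))
  X <- geno$dosage
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  map <- geno$snp_map
  keep <- rep(TRUE, ncol(X))
  win_bp <- window_kb * 1000
  for (ch in unique(map$chrom)) {
    idx_ch <- which(map$chrom == ch)
    anchors <- idx_ch[seq(1, length(idx_ch), by = step_snps)]
    for (a in anchors) {
      win <- idx_ch[map$pos[idx_ch] >= map$pos[a] &
                      map$pos[idx_ch] < map$pos[a] + win_bp]
      win <- win[keep[win]]
      if (length(win) < 2) next
      repeat {
        r2 <- suppressWarnings(cor(X[, win, drop = FALSE]))^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        off <- which(r2 >= r2_max, arr.ind = TRUE)
        if (nrow(off) == 0) break
        pair <- win[off[1, ]]
        drop <- if (map$maf[pair[1]] < map$maf[pair[2]]) pair[1]
                else if (map$maf[pair[2]] < map$maf[pair[1]]) pair[2]
                else pair[which.max(map$pos[pair])]
        keep[drop] <- FALSE
        win <- win[win != drop]
        if (length(win) < 2) break
      }
    }
  }
  inform(sprintf("ld_prune: %d -> %d SNPs", ncol(X), sum(keep)))
  subset_genotypes(geno, snps = which(keep))
}

#' BayesS: spike-slab regression with MAF-dependent effect variance
#'
#' Gibbs sampler for `y = mu + X beta + e` where each SNP effect is zero
#' with probability `1 - pi` and otherwise drawn from
#' `N(0, sigma2_b * (2 p_j (1 - p_j))^S)`. S couples effect size to minor
#' allele frequency: S < 0 means larger effects at rarer alleles (the
#' signature of purifying selection), S > 0 the reverse, S = 0 neutrality.
#' Conditional updates: residual-update spike-slab per SNP, conjugate Beta
#' for pi, scaled-inverse-chi-squared for the variances, and random-walk
#' Metropolis for S with step adaptation during burn-in (then frozen).
#'
#' Default priors: `pi ~ Beta(1, n_snp / 100)`; variances
#' scaled-inv-chi2(nu = 4) with scales set from the data variance;
#' `S ~ N(0, 1)` truncated to `[-5, 5]`.
#'
#' @param y one value per individual (typically genotype BLUPs), named by
#'   individual id.
#' @param geno [genotype_matrix()] (an LD-pruned panel); missing dosages are
#'   mean-imputed.
#' @param chain_length,burnin,thin MCMC configuration. Desk-scale default
#'   25,000 / 5,000 / 10; full-scale runs use longer chains via these
#'   arguments.
#' @param priors optional overrides: `pi_a`, `pi_b`, `nu0`, `s_prior_sd`,
#'   `s_max`, `s_step_init`.
#' @param seed RNG seed (the chain is bit-reproducible given the seed).
#' @return object of class `bayess_fit`: `samples` (tibble of kept draws of
#'   S, pi, sigma2_b, sigma2_e, nnz), `snp` (tibble `snp_id`, `maf`, `pip`,
#'   `beta_mean`), `acceptance`, `config`.
#' @export
bayess <- function(y, geno, chain_length = 25000, burnin = 5000, thin = 10,
                   priors = list(), seed = 1) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (chain_length <= burnin) abort("chain_length must exceed burnin.")
  X <- geno$dosage
  if (!is.null(names(y))) {
    common <- intersect(names(y), rownames(X))
    if (length(common) < 2) abort("no shared individual ids between y and geno.")
    y <- y[common]
    X <- X[common, , drop = FALSE]
  }
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  p <- geno$snp_map$maf
  het <- 2 * p * (1 - p)
  vy <- var(y)
  pi_a_def <- 1; pi_b_def <- ncol(X) / 100
  expected_nnz <- ncol(X) * pi_a_def / (pi_a_def + pi_b_def)
  pr <- utils::modifyList(list(
    pi_a = pi_a_def, pi_b = pi_b_def, nu0 = 4,
    # prior guess: the trait variance spread over the prior-expected number
    # of non-zero SNPs at their average heterozygosity; a deliberately
    # generous slab acts as an Occam factor against spurious inclusions
    scale_b0 = vy / (mean(het) * max(1, expected_nnz)),
    scale_e0 = vy / 2,
    s_prior_sd = 1, s_max = 5, s_step_init = 0.3
  ), priors)
  set.seed(seed)
  res <- bayess_mcmc(
    as.numeric(y), X, het, as.integer(chain_length), as.integer(burnin),
    as.integer(thin), pr$pi_a, pr$pi_b, pr$nu0, pr$scale_b0, pr$scale_e0,
    pr$s_prior_sd, pr$s_max, pr$s_step_init
  )
  structure(list(
    samples = tibble(
      iter = burnin + thin * (seq_along(res$S) - 1) + 1,
      S = as.vector(res$S), pi = as.vector(res$pi),
      sigma2_b = as.vector(res$sigma2_b), sigma2_e = as.vector(res$sigma2_e),
      nnz = as.vector(res$nnz)
    ),
    snp = tibble(
      snp_id = geno$snp_map$snp_id, maf = geno$snp_map$maf,
      pip = as.vector(res$pip), beta_mean = as.vector(res$beta_mean)
    ),
    acceptance = res$acceptance,
    config = list(chain_length = chain_length, burnin = burnin, thin = thin,
                  priors = pr, seed = seed, n = nrow(X), n_snp = ncol(X))
  ), class = "bayess_fit")
}

#' @export
print.bayess_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<bayess_fit> %d kept draws (chain %d, burn-in %d); S = %.3f [%.3f, %.3f]; NNZ = %.1f; acc(S) = %.2f\n",
    nrow(x$samples), x$config$chain_length, x$config$burnin,
    g$S_mean, g$S_low, g$S_high, g$nnz_mean, x$acceptance
  ))
  invisible(x)
}

#' Posterior summaries of a BayesS fit
#'
#' @param x `bayess_fit`.
#' @param level credible level for the intervals.
#' @param ... unused.
#' @return `tidy()`: one row per model parameter with posterior mean, sd and
#'   credible bounds. `glance()`: a one-row summary (S and pi means, CI for
#'   S, NNZ, acceptance rate).
#' @method tidy bayess_fit
#' @export
tidy.bayess_fit <- function(x, level = 0.95, ...) {
  a <- (1 - level) / 2
  sm <- x$samples
  map(c("S", "pi", "sigma2_b", "sigma2_e", "nnz"), function(par) {
    v <- sm[[par]]
    tibble(term = par, estimate = mean(v), std.error = sd(v),
           conf.low = unname(quantile(v, a)), conf.high = unname(quantile(v, 1 - a)))
  }) %>% list_rbind()
}

#' @rdname tidy.bayess_fit
#' @method glance bayess_fit
#' @export
glance.bayess_fit <- function(x, level = 0.95, ...) {
  a <- (1 - level) / 2
  tibble(
    S_mean = mean(x$samples$S),
    S_low = unname(quantile(x$samples$S, a)),
    S_high = unname(quantile(x$samples$S, 1 - a)),
    pi_mean = mean(x$samples$pi),
    nnz_mean = mean(x$samples$nnz),
    sigma2_b = mean(x$samples$sigma2_b),
    sigma2_e = mean(x$samples$sigma2_e),
    acceptance = x$acceptance,
    n_draws = nrow(x$samples)
  )
}

#' Classify the selection mode from the posterior of S
#'
#' `purifying` if the credible interval lies entirely below zero,
#' `positive` if entirely above, `neutral` otherwise.
#'
#' @param fit `bayess_fit`.
#' @param level credible level.
#' @return character scalar.
#' @export
s_significance <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  ci <- quantile(fit$samples$S, c(a, 1 - a))
  if (ci[2] < 0) "purifying" else if (ci[1] > 0) "positive" else "neutral"
}

#' MAF vs effect-size table for architecture plots
#'
#' SNPs with posterior inclusion probability >= `pip_min`, with their MAF,
#' absolute posterior-mean effect, and allele-1 (major-allele) frequency.
#' The reported skew statistic is the sample skewness of the allele-1
#' frequency: purifying architectures (S < 0) pile non-zero SNPs at low MAF
#' (major-allele frequency near 1, left tail), giving negative skew;
#' positive selection gives the reverse.
#'
#' @param fit `bayess_fit`.
#' @param pip_min inclusion-probability cutoff.
#' @return tibble `snp_id`, `maf`, `abs_effect`, `allele1_freq` with
#'   attribute `skew`.
#' @export
maf_effect_table <- function(fit, pip_min = 0.5) {
  tab <- fit$snp %>%
    filter(.data$pip >= pip_min) %>%
    mutate(abs_effect = abs(.data$beta_mean), allele1_freq = 1 - .data$maf) %>%
    select("snp_id", "maf", "abs_effect", "allele1_freq")
  if (nrow(tab) == 0) {
    warn("no SNPs pass pip_min; empty table.")
    attr(tab, "skew") <- NA_real_
    return(tab)
  }
  x <- tab$allele1_freq
  skew <- if (length(x) < 3 || sd(x) == 0) NA_real_ else {
    mean((x - mean(x))^3) / sd(x)^3
  }
  attr(tab, "skew") <- skew
  tab
}

#' @method autoplot bayess_fit
#' @export
autoplot.bayess_fit <- function(object, pip_min = 0.5, ...) {
  tab <- maf_effect_table(object, pip_min)
  ggplot2::ggplot(tab, ggplot2::aes(.data$allele1_freq, .data$abs_effect)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "allele 1 (major) frequency", y = "|posterior mean effect|") +
    ggplot2::theme_minimal()
}
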
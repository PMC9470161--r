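#' Relative fitness from a fitness proxy
#'
#' `w = CC / mean(CC)`; mean(w) is exactly 1, so linear and quadratic
#' differentials computed from w are on the Lande-Arnold relative-fitness
#' scale regardless of the proxy's units.
#'
#' @param cc fitness proxy per genotype (canopy coverage), >= 0 with at
#'   least one positive value.
#' @return numeric vector w with mean 1.
#' @export
relative_fitness <- function(cc) {
  if (all(cc == 0)) abort("all fitness-proxy values are zero.")
  cc / mean(cc)
}

#' Standardize a trait vector
#'
#' @param x numeric vector with positive variance.
#' @return `(x - mean) / sd`; zero mean, unit sd.
#' @export
standardize <- function(x) {
  s <- sd(x)
  if (s == 0) abort("zero-variance trait cannot be standardized.")
  (x - mean(x)) / s
}

#' Fit a smoothed fitness function w(z)
#'
#' Penalized cubic regression spline ([mgcv::gam()], basis `"cr"`) with an
#' unpenalized linear null space; the smoothing parameter is chosen by
#' generalized cross-validation. Exactly linear data therefore comes back
#' linear (the penalty does not touch the linear part).
#'
#' @param z standardized trait values (one trait; the fitness models are
#'   univariate).
#' @param w relative fitness values.
#' @param basis_df spline basis dimension; reduced with a warning when there
#'   are fewer points.
#' @return object of class `fitness_fn`: callable pieces `predict(z)`,
#'   plus the gam fit.
#' @export
fit_fitness_function <- function(z, w, basis_df = 10) {
  stopifnot(length(z) == length(w))
  k <- basis_df
  if (length(unique(z)) < k + 1) {
    k <- max(3, length(unique(z)) - 1)
    warn(sprintf("basis_df reduced to %d (too few distinct points)", k))
  }
  df <- data.frame(z = z, w = w)
  m <- mgcv::gam(w ~ s(z, bs = "cr", k = k), data = df, method = "GCV.Cp")
  structure(list(model = m, z = z, w = w, basis_df = k), class = "fitness_fn")
}

#' @method predict fitness_fn
#' @export
predict.fitness_fn <- function(object, newdata = NULL, ...) {
  z <- if (is.null(newdata)) object$z else newdata
  as.vector(predict(object$model, newdata = data.frame(z = z)))
}

#' @method glance fitness_fn
#' @export
glance.fitness_fn <- function(x, ...) {
  tibble(
    edf = sum(x$model$edf), gcv = x$model$gcv.ubre,
    r_squared = summary(x$model)$r.sq, n = length(x$z)
  )
}

# evaluate a fitness function (fitness_fn or plain function) at z
eval_fn <- function(fn, z) {
  if (inherits(fn, "fitness_fn")) predict(fn, newdata = z) else fn(z)
}

#' Linear and quadratic selection differentials by average derivatives
#'
#' Function-valued analogues of the Lande-Arnold differentials for a
#' standardized trait: `s = mean_i w'(z_i)` and `c = mean_i w''(z_i)`,
#' averaged over the observed z. Derivatives are central finite differences
#' of the smooth fit (exact for linear and quadratic fitness surfaces).
#' The quadratic differential is reported as the raw average second
#' derivative; no extra x2 or 1/2 convention is applied.
#'
#' @param fn a `fitness_fn` (from [fit_fitness_function()]) or any function
#'   of z.
#' @param z the observed standardized trait values to average over.
#' @param h finite-difference step.
#' @return tibble with `s` and `c`.
#' @export
selection_differentials <- function(fn, z, h = 1e-3 * max(sd(z), 1)) {
  up <- eval_fn(fn, z + h)
  mid <- eval_fn(fn, z)
  dn <- eval_fn(fn, z - h)
  tibble(
    s = mean((up - dn) / (2 * h)),
    c = mean((up - 2 * mid + dn) / h^2)
  )
}

#' Bootstrap significance of selection differentials
#'
#' Resamples genotypes (rows of (z, w)) with replacement, refits the
#' smoothed fitness function, and recomputes (s, c) for each resample.
#' Two-sided sign-crossing p-value with the +1/(B+1) correction:
#' `p = 2 min(frac(s_b <= 0), frac(s_b >= 0))`, capped at 1. Degenerate
#' resamples (zero variance in z or w) are redrawn with a logged count.
#'
#' @param z,w standardized trait and relative fitness, per genotype.
#' @param B bootstrap replicates.
#' @param seed RNG seed.
#' @param basis_df spline basis dimension passed through.
#' @return list of class `selection_boot`: `s`, `c` (point estimates from
#'   the full data), `p_s`, `p_c`, 95% percentile intervals, `B`,
#'   `boot` tibble of replicate estimates, `n_redrawn`.
#' @export
bootstrap_selection <- function(z, w, B = 1000, seed = 1, basis_df = 10) {
  n <- length(z)
  fit <- suppressWarnings(fit_fitness_function(z, w, basis_df))
  est <- selection_differentials(fit, z)
  set.seed(seed)
  s_b <- numeric(B); c_b <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample(n, n, replace = TRUE)
      if (sd(z[idx]) > 0 && sd(w[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    fb <- suppressWarnings(fit_fitness_function(z[idx], w[idx], basis_df))
    db <- selection_differentials(fb, z[idx])
    s_b[b] <- db$s; c_b[b] <- db$c
  }
  if (n_redrawn > 0) inform(sprintf("redrew %d degenerate resamples", n_redrawn))
  two_sided <- function(x) {
    min(1, 2 * min(sum(x <= 0) + 1, sum(x >= 0) + 1) / (B + 1))
  }
  structure(list(
    s = est$s, c = est$c,
    p_s = two_sided(s_b), p_c = two_sided(c_b),
    ci_s = unname(quantile(s_b, c(0.025, 0.975))),
    ci_c = unname(quantile(c_b, c(0.025, 0.975))),
    B = B, boot = tibble(s = s_b, c = c_b), n_redrawn = n_redrawn
  ), class = "selection_boot")
}

#' @method tidy selection_boot
#' @export
tidy.selection_boot <- function(x, ...) {
  tibble(
    term = c("linear", "quadratic"),
    estimate = c(x$s, x$c),
    p.value = c(x$p_s, x$p_c),
    conf.low = c(x$ci_s[1], x$ci_c[1]),
    conf.high = c(x$ci_s[2], x$ci_c[2])
  )
}

#' Selection differentials for every rhizobiome trait
#'
#' For each treatment and trait group: standardize the genotype BLUPs,
#' convert the fitness proxy to relative fitness, fit the univariate
#' smoothed fitness function, and report average-derivative differentials
#' with bootstrap significance. Zero-variance traits are excluded with a
#' warning.
#'
#' @param blups tibble `genotype`, `treatment`, `group_id`, `blup`
#'   (from [compute_blups()]).
#' @param fitness tibble `genotype`, `treatment`, `cc` (fitness proxy at
#'   the genotype level).
#' @param B bootstrap replicates per model.
#' @param seed RNG seed.
#' @param basis_df spline basis dimension.
#' @return tibble `group_id`, `treatment`, `s`, `c`, `p_s`, `p_c`, `n`, `B`.
#' @export
estimate_selection <- function(blups, fitness, B = 1000, seed = 1, basis_df = 10) {
  out <- list()
  combos <- distinct(blups, .data$group_id, .data$treatment)
  for (i in seq_len(nrow(combos))) {
    g <- combos$group_id[i]; trt <- combos$treatment[i]
    b <- filter(blups, .data$group_id == g, .data$treatment == trt)
    f <- filter(fitness, .data$treatment == trt)
    j <- inner_join(b, f, by = c("genotype", "treatment"))
    if (nrow(j) < 30) {
      warn(sprintf("skipping %s/%s: fewer than 30 genotypes", g, trt))
      next
    }
    if (sd(j$blup) == 0) {
      warn(sprintf("excluding zero-variance trait %s/%s", g, trt))
      next
    }
    z <- standardize(j$blup)
    w <- relative_fitness(j$cc)
    bs <- bootstrap_selection(z, w, B = B, seed = seed + i, basis_df = basis_df)
    out[[length(out) + 1]] <- tibble(
      group_id = g, treatment = trt, s = bs$s, c = bs$c,
      p_s = bs$p_s, p_c = bs$p_c, n = nrow(j), B = B
    )
  }
  list_rbind(out)
}
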
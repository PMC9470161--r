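#' Bray-Curtis dissimilarity between samples
#'
#' Counts are converted to relative abundance first; the Bray-Curtis
#' computation itself is delegated to [vegan::vegdist()].
#'
#' @param table [asv_table()].
#' @return `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  rel <- table$counts / rowSums(table$counts)
  d <- vegan::vegdist(rel, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Weighted UniFrac distance between samples
#'
#' Branch-length-weighted abundance difference normalised by total
#' branch-weighted abundance: for samples i, j with per-branch abundance
#' sums A and B (relative abundance of all tips descending from the
#' branch), `d = sum_b l_b |A_b - B_b| / sum_b l_b (A_b + B_b)`.
#'
#' @param table [asv_table()]; every ASV must be a tip of `tree`.
#' @param tree `ape::phylo` with branch lengths.
#' @return `dist` object with attribute `metric = "weighted_unifrac"`.
#' @export
weighted_unifrac <- function(table, tree) {
  stopifnot(inherits(table, "asv_table"), inherits(tree, "phylo"))
  missing_tips <- setdiff(colnames(table$counts), tree$tip.label)
  if (length(missing_tips) > 0) {
    abort(paste0("ASVs absent from tree: ", paste(head(missing_tips, 5), collapse = ", ")))
  }
  rel <- table$counts / rowSums(table$counts)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  # per-node relative abundance of descendant tips, accumulated in postorder
  node_ab <- matrix(0, nrow(rel), n_node)
  tip_idx <- match(tree$tip.label, colnames(rel))
  present <- !is.na(tip_idx)
  node_ab[, which(present)] <- rel[, tip_idx[present], drop = FALSE]
  edges <- reorder(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    node_ab[, edges[e, 1]] <- node_ab[, edges[e, 1]] + node_ab[, edges[e, 2]]
  }
  # branch b = edge leading to child node edges[,2]
  child <- tree$edge[, 2]
  len <- tree$edge.length
  B <- node_ab[, child, drop = FALSE]  # samples x branches
  n <- nrow(B)
  D <- matrix(0, n, n, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(len * abs(B[i, ] - B[j, ]))
      den <- sum(len * (B[i, ] + B[j, ]))
      D[i, j] <- D[j, i] <- if (den == 0) 0 else num / den
    }
  }
  d <- stats::as.dist(D)
  attr(d, "metric") <- "weighted_unifrac"
  d
}

#' Principal coordinates analysis
#'
#' Classical metric MDS by double-centering and eigendecomposition.
#' Coordinates come from the non-negative eigenvalues; negative eigenvalues
#' are reported, not corrected.
#'
#' @param d `dist` or symmetric matrix.
#' @param k number of axes returned (default all positive).
#' @return list of class `pcoa_result`: `coordinates` (tibble with
#'   `sample_id` and `PCo1..k`), `eigenvalues`, `metric`.
#' @export
pcoa <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (max(abs(d - t(d))) > 1e-12) abort("distance matrix must be symmetric.")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = n - 1, eig = TRUE)
  eig <- fit$eig
  pos <- which(eig > 1e-10)
  k <- min(k %||% length(pos), length(pos))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(
    coordinates = as_tibble(coords) %>%
      mutate(sample_id = labels(d) %||% as.character(seq_len(n)), .before = 1),
    eigenvalues = eig,
    metric = attr(d, "metric") %||% "unknown"
  ), class = "pcoa_result")
}

#' Constrained ordination (distance-based RDA / CAP)
#'
#' Regresses principal coordinates on the field-design factors and
#' eigen-decomposes the fitted values; delegated to [vegan::capscale()],
#' with per-factor permutation significance from [vegan::anova.cca()].
#'
#' @param d `dist`.
#' @param sample_meta design tibble matching the distance labels.
#' @param factors character vector of metadata columns to constrain on.
#' @param n_perm permutations for the per-factor tests.
#' @param seed RNG seed for the permutation test.
#' @return list of class `cap_result`: `scores` (constrained sample scores),
#'   `eigenvalues` (constrained), `factor_tests` (per-factor pseudo-F, p),
#'   `model`.
#' @export
cap_ordination <- function(d, sample_meta, factors, n_perm = 199, seed = 1) {
  meta <- as.data.frame(sample_meta)
  rownames(meta) <- meta$sample_id
  meta <- meta[labels(d), , drop = FALSE]
  for (f in factors) meta[[f]] <- factor(meta[[f]])
  fml <- as.formula(paste("d ~", paste(factors, collapse = " + ")))
  fit <- vegan::capscale(fml, data = meta)
  set.seed(seed)
  at <- vegan::anova.cca(fit, by = "terms", permutations = n_perm)
  sc <- vegan::scores(fit, display = "sites", choices = seq_len(
    max(1, min(2, length(fit$CCA$eig)))
  ))
  colnames(sc) <- paste0("CAP", seq_len(ncol(sc)))
  structure(list(
    scores = as_tibble(sc) %>% mutate(sample_id = rownames(sc), .before = 1) %>%
      left_join(as_tibble(sample_meta), by = "sample_id"),
    eigenvalues = fit$CCA$eig,
    factor_tests = tibble(
      factor = rownames(at)[seq_along(factors)],
      pseudo_F = at$F[seq_along(factors)],
      p = at$`Pr(>F)`[seq_along(factors)]
    ),
    model = fit
  ), class = "cap_result")
}

permanova_f <- function(d2, f) {
  # Anderson's pseudo-F from squared dissimilarities
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  lv <- split(seq_len(n), f)
  ss_within <- sum(vapply(lv, function(idx) {
    if (length(idx) < 2) return(0)
    sub <- d2[idx, idx]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  a <- length(lv)
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

#' PERMANOVA for a single factor
#'
#' Anderson's pseudo-F from within/between sums of squared dissimilarities,
#' with significance from permutations of the factor labels (within strata
#' when given): `p = (#\{F_perm >= F_obs\} + 1) / (n_perm + 1)`. With
#' `exact = TRUE` every distinct label permutation is enumerated instead
#' and `p = #\{F_perm >= F_obs\} / N` (the identity included).
#'
#' @param d `dist`.
#' @param f factor (>= 2 levels), aligned with `d`.
#' @param n_perm number of permutations (warning below 99).
#' @param seed RNG seed.
#' @param strata optional factor restricting permutations.
#' @param exact enumerate all label permutations (small n only).
#' @return tibble with `pseudo_F`, `p`, `n_perm`, `method`.
#' @export
permanova <- function(d, f, n_perm = 999, seed = 1, strata = NULL, exact = FALSE) {
  f <- factor(f)
  if (nlevels(f) < 2) abort("factor must have >= 2 levels.")
  if (n_perm < 99 && !exact) warn("n_perm < 99 gives coarse p-value resolution.")
  d2 <- as.matrix(d)^2
  if (all(d2 == 0)) abort("all samples identical: pseudo-F undefined.")
  f_obs <- permanova_f(d2, f)
  n <- length(f)
  if (exact) {
    perms <- all_permutations(n)
    f_perm <- apply(perms, 1, function(ord) permanova_f(d2, f[ord]))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- nrow(perms)
    method <- "exact"
  } else {
    set.seed(seed)
    f_perm <- vapply(seq_len(n_perm), function(b) {
      ord <- if (is.null(strata)) sample(n) else strata_permute(strata)
      permanova_f(d2, f[ord])
    }, numeric(1))
    p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
    method <- "permutation"
  }
  tibble(pseudo_F = f_obs, p = p, n_perm = n_used, method = method)
}

strata_permute <- function(strata) {
  idx <- seq_along(strata)
  for (s in unique(strata)) {
    w <- which(strata == s)
    idx[w] <- sample(w)
  }
  idx
}

all_permutations <- function(n) {
  if (n > 8) abort("exact enumeration limited to n <= 8.")
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, meta = NULL, ...) {
  df <- object$coordinates
  if (!is.null(meta)) df <- left_join(df, as_tibble(meta), by = "sample_id")
  rel <- object$eigenvalues / sum(pmax(object$eigenvalues, 0))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PCo1, .data$PCo2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * rel[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * rel[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(colour) && colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), shape = 18, size = 2)
  } else {
    p + ggplot2::geom_point(shape = 18, size = 2)
  }
}

#' @method autoplot cap_result
#' @export
autoplot.cap_result <- function(object, colour = "treatment", ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$CAP1, .data$CAP2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "CAP1", y = "CAP2")
  if (colour %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]), shape = 18, size = 2)
  } else {
    p + ggplot2::geom_point(shape = 18, size = 2)
  }
}
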
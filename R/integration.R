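#' Correlate rhizobiome traits with a plant trait
#'
#' Pearson correlation of genotype-level BLUPs of each microbial group with
#' genotype-level plant-trait values, separately per treatment (per-genotype
#' quantities: sample-level correlation would inflate n). Pairs with fewer
#' than `min_n` matched genotypes are suppressed with a flag.
#'
#' @param blups tibble `genotype`, `treatment`, `group_id`, `blup`.
#' @param plant tibble `genotype`, `treatment`, `value` (one plant trait),
#'   or with a `trait` column for several.
#' @param min_n minimum matched genotypes.
#' @return tibble `group_id`, `plant_trait`, `treatment`, `r`, `p`, `n`,
#'   `flag`.
#' @export
correlate_traits <- function(blups, plant, min_n = 3) {
  if (!"trait" %in% names(plant)) plant$trait <- "plant_trait"
  combos <- tidyr::expand_grid(
    distinct(blups, .data$group_id, .data$treatment),
    trait = unique(plant$trait)
  )
  out <- pmap(combos, function(group_id, treatment, trait) {
    b <- blups[blups$group_id == group_id & blups$treatment == treatment, ]
    pv <- plant[plant$trait == trait & plant$treatment == treatment, ]
    j <- inner_join(b, pv, by = c("genotype", "treatment"))
    j <- j[complete.cases(j[c("blup", "value")]), ]
    if (nrow(j) < min_n || sd(j$blup) == 0 || sd(j$value) == 0) {
      return(tibble(group_id = group_id, plant_trait = trait,
                    treatment = treatment, r = NA_real_, p = NA_real_,
                    n = nrow(j), flag = "suppressed"))
    }
    ct <- cor.test(j$blup, j$value)
    tibble(group_id = group_id, plant_trait = trait, treatment = treatment,
           r = unname(ct$estimate), p = ct$p.value, n = nrow(j), flag = "")
  })
  list_rbind(out)
}

#' Permutation null for the count of significantly correlated groups
#'
#' Shuffles the genotype labels of the plant trait within each treatment,
#' recomputes every group correlation, and counts groups significant at
#' `p_cut` in either treatment per permutation;
#' `p = (#\{count_perm >= count_obs\} + 1) / (B + 1)`.
#'
#' @param blups tibble `genotype`, `treatment`, `group_id`, `blup`.
#' @param plant tibble `genotype`, `treatment`, `value` (one plant trait).
#' @param p_cut per-correlation significance cutoff.
#' @param B permutations.
#' @param seed RNG seed.
#' @return list: `count_obs`, `p`, `null_counts`, `B`, `correlations`
#'   (the observed table).
#' @export
count_significant_permutation <- function(blups, plant, p_cut = 0.01,
                                          B = 1000, seed = 1) {
  obs <- correlate_traits(blups, plant)
  count_sig <- function(tab) {
    length(unique(tab$group_id[!is.na(tab$p) & tab$p < p_cut]))
  }
  count_obs <- count_sig(obs)
  # precompute wide matrices per treatment for fast permutation
  set.seed(seed)
  null_counts <- vapply(seq_len(B), function(b) {
    perm <- plant %>%
      group_by(.data$treatment) %>%
      mutate(value = sample(.data$value)) %>%
      ungroup()
    count_sig(correlate_traits(blups, perm))
  }, numeric(1))
  p <- (sum(null_counts >= count_obs) + 1) / (B + 1)
  list(count_obs = count_obs, p = p, null_counts = null_counts, B = B,
       correlations = obs)
}

#' Relationship between heritability and fitness-trait correlation
#'
#' One Pearson correlation per treatment between each group's heritability
#' and its (signed) correlation with the plant trait.
#'
#' @param h2_table tibble from [estimate_heritability()].
#' @param cor_table tibble from [correlate_traits()].
#' @return tibble `treatment`, `r`, `p`, `n`, `flag`.
#' @export
heritability_correlation_relation <- function(h2_table, cor_table) {
  j <- inner_join(
    select(h2_table, "group_id", "treatment", "h2"),
    select(cor_table, "group_id", "treatment", "r"),
    by = c("group_id", "treatment")
  ) %>% filter(!is.na(.data$r))
  out <- j %>%
    group_by(.data$treatment) %>%
    group_modify(function(df, key) {
      if (nrow(df) < 3 || sd(df$h2) == 0 || sd(df$r) == 0) {
        return(tibble(r = NA_real_, p = NA_real_, n = nrow(df), flag = "suppressed"))
      }
      ct <- cor.test(df$h2, df$r)
      tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(df), flag = "")
    }) %>%
    ungroup()
  out
}

#' Expression set test: MAPL genes vs all other genes, per tissue
#'
#' Mann-Whitney U comparing log expression of the MAPL gene set against all
#' remaining genes within each tissue (gene expression is heavy-tailed, so
#' a rank test is used); the effect is the difference in mean log2
#' expression (MAPL minus others). Raw-scale expression is log2(x+1)
#' transformed first.
#'
#' @param expr tibble `gene_id`, `tissue`, `expression` (raw scale).
#' @param mapl_genes character vector of MAPL gene ids (must be a proper,
#'   non-empty subset of the table's genes).
#' @return tibble `tissue`, `n_mapl`, `n_other`, `effect`, `p`.
#' @export
expression_set_test <- function(expr, mapl_genes) {
  if (length(mapl_genes) == 0) abort("empty MAPL gene set.")
  all_genes <- unique(expr$gene_id)
  if (all(all_genes %in% mapl_genes)) {
    abort("MAPL set and background must be disjoint (set covers every gene).")
  }
  expr <- mutate(expr, log_expr = log2(.data$expression + 1),
                 in_set = .data$gene_id %in% mapl_genes)
  expr %>%
    group_by(.data$tissue) %>%
    group_modify(function(df, key) {
      a <- df$log_expr[df$in_set]; b <- df$log_expr[!df$in_set]
      wt <- wilcox.test(a, b)
      tibble(n_mapl = length(a), n_other = length(b),
             effect = mean(a) - mean(b), p = wt$p.value)
    }) %>%
    ungroup()
}

#' Per-group summary ledger across all assays
#'
#' Joins, per microbial group, the heritability flags (per treatment), the
#' selection classification, MAPL membership, and the fitness-trait
#' correlation, and re-derives the intersection counts (nothing is
#' hand-entered; rows are recomputed from the source tables).
#'
#' @param h2_table [estimate_heritability()] output.
#' @param sel_table [estimate_selection()] output.
#' @param mapls [call_mapls()] output (with `group_ids`).
#' @param cor_table [correlate_traits()] output for the fitness trait.
#' @param p_h2,p_sel,p_cor significance cutoffs for the flags.
#' @return tibble of class `group_summary`, one row per group, with logical
#'   flags `heritable_plusN`, `heritable_minusN`, `under_selection`,
#'   `has_mapl`, `cc_correlated`, plus `mapl_ids` and attribute `counts`.
#' @export
build_summary <- function(h2_table, sel_table, mapls, cor_table,
                          p_h2 = 0.05, p_sel = 0.05, p_cor = 0.01) {
  groups <- sort(unique(c(h2_table$group_id, sel_table$group_id,
                          cor_table$group_id)))
  known <- unique(h2_table$group_id)
  orphans <- setdiff(unique(c(sel_table$group_id, cor_table$group_id)), known)
  if (length(orphans) > 0 && length(known) > 0) {
    abort(paste0("group ids absent from the heritability table: ",
                 paste(head(orphans, 5), collapse = ", ")))
  }
  h2_flag <- function(trt) {
    ids <- h2_table$group_id[h2_table$treatment == trt & h2_table$p < p_h2]
    groups %in% ids
  }
  sel_ids <- sel_table$group_id[sel_table$p_s < p_sel | sel_table$p_c < p_sel]
  cor_ids <- cor_table$group_id[!is.na(cor_table$p) & cor_table$p < p_cor]
  mapl_of <- function(g) {
    if (nrow(mapls) == 0) return("")
    hit <- vapply(strsplit(mapls$group_ids, ","), function(v) g %in% v, logical(1))
    paste(paste0("MAPL_", mapls$chrom[hit], "_", mapls$window[hit]), collapse = ",")
  }
  out <- tibble(
    group_id = groups,
    heritable_plusN = h2_flag("plusN"),
    heritable_minusN = h2_flag("minusN"),
    under_selection = groups %in% sel_ids,
    cc_correlated = groups %in% cor_ids,
    mapl_ids = map_chr(groups, mapl_of)
  ) %>%
    mutate(has_mapl = .data$mapl_ids != "",
           heritable = .data$heritable_plusN | .data$heritable_minusN)
  counts <- list(
    n_groups = nrow(out),
    n_cc = sum(out$cc_correlated),
    n_cc_heritable = sum(out$cc_correlated & out$heritable),
    n_cc_selected = sum(out$cc_correlated & out$under_selection),
    n_cc_mapl = sum(out$cc_correlated & out$has_mapl),
    n_all_assays = sum(out$cc_correlated & out$heritable &
                         out$under_selection & out$has_mapl)
  )
  class(out) <- c("group_summary", class(out))
  attr(out, "counts") <- counts
  out
}
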
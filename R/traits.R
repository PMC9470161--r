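#' Filter ASVs by abundance and cross-group prevalence
#'
#' Keeps ASVs that are highly abundant and repeatedly observed in every
#' level of a grouping column (by default the sampling year, so that only
#' ASVs reproducible across years survive): mean relative abundance >=
#' `min_mean_rel_abund` overall AND prevalence (fraction of samples with a
#' non-zero count) >= `min_prevalence` within every level of
#' `require_groups`.
#'
#' @param table [asv_table()].
#' @param min_mean_rel_abund minimum mean relative abundance in `[0, 1]`.
#' @param min_prevalence minimum within-level prevalence in `[0, 1]`.
#' @param require_groups metadata column whose every level must meet the
#'   prevalence bar.
#' @return Filtered [asv_table()]; message logs before/after counts.
#' @export
filter_asvs <- function(table, min_mean_rel_abund = 1e-4, min_prevalence = 0.1,
                        require_groups = "year") {
  stopifnot(inherits(table, "asv_table"))
  counts <- table$counts
  totals <- rowSums(counts)
  rel <- counts / ifelse(totals == 0, 1, totals)
  keep_abund <- colMeans(rel) >= min_mean_rel_abund
  lv <- split(seq_len(nrow(counts)), table$sample_meta[[require_groups]])
  prev_ok <- Reduce(`&`, lapply(lv, function(idx) {
    colMeans(counts[idx, , drop = FALSE] > 0) >= min_prevalence
  }))
  keep <- keep_abund & prev_ok
  if (!any(keep)) {
    abort("all ASVs removed by the filters; lower min_mean_rel_abund / min_prevalence.")
  }
  inform(sprintf("filter_asvs: %d -> %d ASVs", ncol(counts), sum(keep)))
  asv_table(counts[, keep, drop = FALSE], table$sample_meta,
            table$taxonomy[keep, ], table$sequences[names(table$sequences) %in% colnames(counts)[keep]])
}

#' Cluster ASVs into rhizobiome trait groups
#'
#' Groups ASVs at the finest non-Unknown rank in `rank_priority` (default
#' genus, falling back to family with a label like
#' `"f_<Family> Unknown Genus"`; fully unknown taxonomy goes to an
#' `"Unclassified"` group, kept and flagged). When `split_by_n_response` is
#' on, a taxon whose member ASVs respond to the nitrogen treatment with
#' significantly opposite signs (per-ASV Welch t on ln relative abundance,
#' p < `p_split`, opposite t signs) is split into numbered subgroups
#' ("<taxon> 1", "<taxon> 2"). This taxonomy-plus-response rule approximates
#' sequence-similarity clustering and is labelled as such in the output.
#'
#' @param table [asv_table()] (filtered).
#' @param rank_priority taxonomy ranks tried finest-first.
#' @param split_by_n_response split taxa with opposite-signed treatment
#'   responses.
#' @param p_split per-ASV significance cutoff for the response split.
#' @return tibble `asv_id`, `group_id`, `label`, `flag`.
#' @export
cluster_asvs <- function(table, rank_priority = c("genus", "family"),
                         split_by_n_response = TRUE, p_split = 0.05) {
  stopifnot(inherits(table, "asv_table"))
  tax <- table$taxonomy
  n <- nrow(tax)
  label <- rep("Unclassified", n)
  for (i in seq_len(n)) {
    for (r in rank_priority) {
      v <- tax[[r]][i]
      if (!is.na(v) && !v %in% c("Unknown", "")) {
        label[i] <- if (r == "family") paste0("f_", v, " Unknown Genus") else v
        break
      }
    }
  }
  flag <- ifelse(label == "Unclassified", "unclassified", "")
  if (split_by_n_response && "treatment" %in% names(table$sample_meta) &&
      length(unique(table$sample_meta$treatment)) == 2) {
    totals <- rowSums(table$counts)
    ok <- totals > 0
    lnrel <- log((table$counts[ok, , drop = FALSE] + 1) / totals[ok])
    trt <- table$sample_meta$treatment[ok]
    lv <- unique(trt)
    tstat <- rep(NA_real_, n); pval <- rep(NA_real_, n)
    for (j in seq_len(n)) {
      a <- lnrel[trt == lv[1], j]; b <- lnrel[trt == lv[2], j]
      if (sd(a) == 0 && sd(b) == 0) next
      tt <- tryCatch(t.test(a, b), error = function(e) NULL)
      if (!is.null(tt)) { tstat[j] <- unname(tt$statistic); pval[j] <- tt$p.value }
    }
    for (lab in unique(label)) {
      idx <- which(label == lab)
      if (length(idx) < 2) next
      sig <- idx[!is.na(pval[idx]) & pval[idx] < p_split]
      signs <- sign(tstat[sig])
      if (length(unique(signs[signs != 0])) == 2) {
        # opposite significant responses: split by response sign
        sub <- rep(1L, length(idx))
        resp <- sign(tstat[idx])
        resp[is.na(resp)] <- 0
        dominant <- signs[which.max(abs(tstat[sig]))]
        sub[resp != dominant & resp != 0] <- 2L
        label[idx] <- paste(lab, sub)
      }
    }
  }
  ids <- match(label, unique(label))
  tibble(
    asv_id = tax$asv_id,
    group_id = sprintf("grp%03d", ids),
    label = label,
    flag = flag
  )
}

#' Transform grouped counts to ln relative abundance
#'
#' `value(sample, group) = ln((sum of member ASV counts + pseudocount) /
#' total sample count)`. The pseudocount is added to the group count (not
#' per ASV) so the plain formula is preserved for non-zero groups.
#' Zero-total samples are dropped with a warning.
#'
#' @param table [asv_table()].
#' @param group_map tibble `asv_id` -> `group_id` (and optional `label`).
#' @param pseudocount added to the group count before division.
#' @return A [trait_matrix()].
#' @export
transform_abundance <- function(table, group_map, pseudocount = 1) {
  stopifnot(inherits(table, "asv_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    warn(sprintf("dropping %d zero-total samples", sum(totals == 0)))
  }
  keep <- totals > 0
  counts <- table$counts[keep, , drop = FALSE]
  totals <- totals[keep]
  gm <- group_map[match(colnames(counts), group_map$asv_id), ]
  if (anyNA(gm$group_id)) abort("group_map does not cover all ASVs in the table.")
  groups <- unique(gm$group_id)
  agg <- vapply(groups, function(g) {
    rowSums(counts[, gm$group_id == g, drop = FALSE])
  }, numeric(nrow(counts)))
  if (!is.matrix(agg)) agg <- matrix(agg, nrow = nrow(counts))
  vals <- log((agg + pseudocount) / totals)
  rownames(vals) <- rownames(counts)
  colnames(vals) <- groups
  gmeta <- tibble(
    group_id = groups,
    label = if ("label" %in% names(gm)) gm$label[match(groups, gm$group_id)] else groups,
    n_asvs = as.integer(tabulate(match(gm$group_id, groups)))
  )
  trait_matrix(vals, table$sample_meta[match(rownames(vals), table$sample_meta$sample_id), ],
               gmeta, group_map = gm)
}

#' Differential abundance of trait groups between nitrogen treatments
#'
#' Welch two-sample t-test on ln relative abundance per group; classes are
#' `plusN_enriched` (p < `p_cut` and higher mean under +N),
#' `minusN_enriched` (reversed), otherwise `ns`. Groups constant in both
#' arms get class `ns` with a flag.
#'
#' @param traits [trait_matrix()].
#' @param p_cut significance cutoff.
#' @return tibble `group_id`, `t`, `p`, `mean_plusN`, `mean_minusN`,
#'   `class`, `flag`.
#' @export
differential_abundance <- function(traits, p_cut = 0.05) {
  stopifnot(inherits(traits, "trait_matrix"))
  trt <- traits$sample_meta$treatment
  if (!all(c("plusN", "minusN") %in% trt)) {
    abort("both treatment levels (plusN, minusN) must be present.")
  }
  plus <- trt == "plusN"
  res <- map(colnames(traits$values), function(g) {
    a <- traits$values[plus, g]; b <- traits$values[!plus, g]
    if (sd(a) == 0 && sd(b) == 0) {
      return(tibble(group_id = g, t = NA_real_, p = NA_real_,
                    mean_plusN = mean(a), mean_minusN = mean(b),
                    class = "ns", flag = "constant"))
    }
    tt <- t.test(a, b)
    cls <- if (tt$p.value < p_cut) {
      if (mean(a) > mean(b)) "plusN_enriched" else "minusN_enriched"
    } else "ns"
    tibble(group_id = g, t = unname(tt$statistic), p = tt$p.value,
           mean_plusN = mean(a), mean_minusN = mean(b), class = cls, flag = "")
  })
  list_rbind(res)
}
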
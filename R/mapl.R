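#' Call microbe-associated plant loci (MAPLs) from pooled GWAS results
#'
#' The genome is split into fixed, non-overlapping windows of `window_bp`
#' anchored at position 0 on each chromosome. Every significant SNP-trait
#' association (across all traits and both treatments) contributes one
#' signal to its window; the same SNP significant for two traits counts
#' twice. Windows with at least `min_signals` signals are reported (1 gives
#' the full MAPL set, 2 the stricter hotspot subset). Adjacent significant
#' windows are not merged.
#'
#' @param gwas_all tibble pooling per-trait GWAS results, with columns
#'   `group_id`, `treatment`, `chrom`, `pos`, `neg_log10_p`.
#' @param window_bp window size (bp).
#' @param threshold significance threshold on the -log10(p) scale
#'   (associations with `neg_log10_p > threshold` count).
#' @param min_signals minimum signal tally for a reported region.
#' @return tibble of class `mapl_regions`: `chrom`, `window`, `start`,
#'   `end` (0-based half-open), `n_signals`, `n_traits`, `group_ids`,
#'   `treatments`, sorted by (chrom, window).
#' @export
call_mapls <- function(gwas_all, window_bp = 10000, threshold,
                       min_signals = 1) {
  need <- c("group_id", "treatment", "chrom", "pos", "neg_log10_p")
  missing_cols <- setdiff(need, names(gwas_all))
  if (length(missing_cols) > 0) {
    abort(paste0("gwas_all is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  sig <- filter(gwas_all, .data$neg_log10_p > threshold)
  empty <- tibble(
    chrom = character(), window = integer(), start = integer(), end = integer(),
    n_signals = integer(), n_traits = integer(),
    group_ids = character(), treatments = character()
  )
  if (nrow(sig) == 0) {
    class(empty) <- c("mapl_regions", class(empty))
    return(empty)
  }
  out <- sig %>%
    mutate(window = as.integer(.data$pos %/% window_bp)) %>%
    group_by(.data$chrom, .data$window) %>%
    summarise(
      n_signals = dplyr::n(),
      n_traits = dplyr::n_distinct(.data$group_id),
      group_ids = paste(sort(unique(.data$group_id)), collapse = ","),
      treatments = paste(sort(unique(.data$treatment)), collapse = ","),
      .groups = "drop"
    ) %>%
    mutate(
      start = .data$window * as.integer(window_bp),
      end = (.data$window + 1L) * as.integer(window_bp)
    ) %>%
    filter(.data$n_signals >= min_signals) %>%
    arrange(.data$chrom, .data$window) %>%
    select("chrom", "window", "start", "end", "n_signals", "n_traits",
           "group_ids", "treatments")
  class(out) <- c("mapl_regions", class(out))
  out
}

#' Attach genes completely contained within a flank of each MAPL
#'
#' A gene is attached to a MAPL window only when its transcribed span
#' (1-based inclusive) lies entirely inside
#' `[window_start - flank, window_end + flank)` (0-based half-open);
#' partially overlapping genes are excluded.
#'
#' @param mapls tibble from [call_mapls()].
#' @param genes gene annotation tibble (from [read_gene_annotation()]).
#' @param flank flank width in bp on each side of the window.
#' @return `mapls` with added `genes` (comma-separated gene ids) and
#'   `n_genes`.
#' @export
annotate_mapl_genes <- function(mapls, genes, flank = 10000) {
  shared <- intersect(unique(mapls$chrom), unique(genes$chrom))
  if (nrow(mapls) > 0 && length(shared) == 0 && nrow(genes) > 0) {
    warn(paste0(
      "no shared chromosome names; MAPLs: ",
      paste(unique(mapls$chrom), collapse = ","), " vs genes: ",
      paste(unique(genes$chrom), collapse = ",")
    ))
  }
  hits <- map_chr(seq_len(nrow(mapls)), function(i) {
    lo <- mapls$start[i] - flank
    hi <- mapls$end[i] + flank
    g <- genes[genes$chrom == mapls$chrom[i] &
                 (genes$start - 1) >= lo & genes$end <= hi, ]
    paste(g$gene_id, collapse = ",")
  })
  mapls %>%
    mutate(genes = hits,
           n_genes = lengths(strsplit(hits, ",")) * (hits != ""))
}

#' Compare trait values between major-allele and minor-carrier genotypes
#'
#' Partitions genotypes at one SNP into major-allele homozygotes vs
#' carriers of the minor allele (heterozygote placement configurable;
#' inbred panels have few hets so the default sends them to the minor
#' group) and runs a Welch t-test on the supplied genotype-level values
#' (a rhizobiome trait, or canopy coverage).
#'
#' @param geno [genotype_matrix()].
#' @param snp_id SNP to stratify on.
#' @param values named numeric vector (genotype id -> value).
#' @param het_policy where heterozygotes go: `"minor"`, `"major"`, `"drop"`.
#' @param min_group groups smaller than this suppress the p-value (means
#'   still reported).
#' @return tibble with one row per allele group (`allele_group`, `n`,
#'   `mean`) plus columns `t` and `p` (identical across rows).
#' @export
allele_stratified_comparison <- function(geno, snp_id, values,
                                         het_policy = c("minor", "major", "drop"),
                                         min_group = 3) {
  het_policy <- match.arg(het_policy)
  stopifnot(inherits(geno, "genotype_matrix"))
  j <- match(snp_id, geno$snp_map$snp_id)
  if (is.na(j)) abort(sprintf("unknown SNP '%s'", snp_id))
  dose <- geno$dosage[, j]
  common <- intersect(names(values), names(dose)[!is.na(dose)])
  dose <- dose[common]; v <- values[common]
  if (length(unique(dose)) < 2) abort("SNP is monomorphic in the analysed genotypes.")
  grp <- dplyr::case_when(
    dose == 0 ~ "major",
    dose == 2 ~ "minor",
    het_policy == "minor" ~ "minor",
    het_policy == "major" ~ "major",
    TRUE ~ NA_character_
  )
  keep <- !is.na(grp)
  grp <- grp[keep]; v <- v[keep]
  ns <- table(factor(grp, levels = c("major", "minor")))
  if (any(ns == 0)) abort("one allele group is empty under this het policy.")
  means <- tapply(v, grp, mean)
  if (min(ns) < min_group) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- t.test(v[grp == "major"], v[grp == "minor"])
  }
  tibble(
    allele_group = c("major", "minor"),
    n = as.integer(ns[c("major", "minor")]),
    mean = as.numeric(means[c("major", "minor")]),
    t = unname(tt$statistic), p = tt$p.value
  )
}

#' Pairwise LD (r-squared) matrix for a genomic interval
#'
#' Plot-support output for zoomed locus views: squared correlation between
#' dosages of all SNPs in `[from, to]` on one chromosome.
#'
#' @param geno [genotype_matrix()].
#' @param chrom chromosome.
#' @param from,to positions (1-based, inclusive).
#' @return symmetric matrix of r-squared values with SNP ids as dimnames.
#' @export
ld_matrix <- function(geno, chrom, from, to) {
  idx <- which(geno$snp_map$chrom == chrom &
                 geno$snp_map$pos >= from & geno$snp_map$pos <= to)
  if (length(idx) < 2) abort("fewer than two SNPs in the interval.")
  X <- geno$dosage[, idx, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }
  r2 <- suppressWarnings(cor(X))^2
  r2[is.na(r2)] <- 0
  diag(r2) <- 1
  r2
}
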
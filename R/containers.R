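#' ASV count table with field design and taxonomy
#'
#' Bundles a samples x ASVs integer count matrix with the per-sample field
#' design (genotype, nitrogen treatment, year, block, split plot, split-plot
#' block, replicate) and per-ASV taxonomy. This is the entry container for
#' everything downstream: community analysis, trait construction, and the
#' heritability / selection / GWAS stack.
#'
#' @param counts integer matrix, samples in rows, ASVs in columns; dimnames
#'   required (sample ids, ASV ids).
#' @param sample_meta data frame keyed by `sample_id` with columns `genotype`,
#'   `treatment` (`"plusN"`/`"minusN"`), `year`, `block`, `sp` (split plot),
#'   `spb` (split-plot block) and `replicate`.
#' @param taxonomy data frame keyed by `asv_id` with rank columns
#'   `kingdom`..`species`; missing ranks encoded as `"Unknown"`.
#' @param sequences optional named character vector, ASV id -> nucleotide
#'   string.
#'
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(counts, sample_meta, taxonomy, sequences = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry sample ids (rownames) and ASV ids (colnames).")
  }
  sample_meta <- as_tibble(sample_meta)
  taxonomy <- as_tibble(taxonomy)
  if (anyDuplicated(rownames(counts))) {
    abort("duplicate sample ids in `counts`.")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("duplicate ASV ids in `counts`.")
  }
  if (anyDuplicated(sample_meta$sample_id)) {
    abort("duplicate sample ids in `sample_meta`.")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "counts must be non-negative integers; first offender: sample %s, ASV %s (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])
    ))
  }
  design_cols <- c("sample_id", "genotype", "treatment", "year", "block", "sp", "spb", "replicate")
  missing_cols <- setdiff(design_cols, names(sample_meta))
  if (length(missing_cols) > 0) {
    abort(paste0("sample_meta is missing design columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(sample_meta[design_cols])) {
    abort("sample_meta design columns contain missing values.")
  }
  # drop count rows without metadata (field samples that failed design lookup)
  keep <- rownames(counts) %in% sample_meta$sample_id
  if (!all(keep)) {
    warn(sprintf("dropping %d samples present in counts but absent from metadata", sum(!keep)))
    counts <- counts[keep, , drop = FALSE]
  }
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ]
  missing_tax <- setdiff(colnames(counts), taxonomy$asv_id)
  if (length(missing_tax) > 0) {
    abort(paste0("ASVs without taxonomy rows: ", paste(head(missing_tax, 5), collapse = ", ")))
  }
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$asv_id), ]
  structure(
    list(counts = counts, sample_meta = sample_meta, taxonomy = taxonomy,
         sequences = sequences),
    class = "asv_table"
  )
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf(
    "<asv_table> %d samples x %d ASVs (total count %.3g)\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts)
  ))
  cat(sprintf(
    "  treatments: %s; years: %s; genotypes: %d\n",
    paste(unique(x$sample_meta$treatment), collapse = "/"),
    paste(unique(x$sample_meta$year), collapse = "/"),
    length(unique(x$sample_meta$genotype))
  ))
  invisible(x)
}

#' @export
dim.asv_table <- function(x) dim(x$counts)

#' Genotype dosage matrix with SNP map
#'
#' Individuals x SNPs minor-allele dosages in \{0, 1, 2, NA\} plus a SNP map
#' (chromosome, position, alleles, minor allele frequency). The minor allele
#' is defined cohort-wise and the chosen orientation is recorded per SNP so
#' major-vs-minor stratification downstream is reproducible.
#'
#' @param dosage numeric matrix (individuals x SNPs) of minor-allele counts;
#'   dimnames required.
#' @param snp_map data frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `allele_major`, `allele_minor`, `maf`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snp_map) {
  dosage <- as.matrix(dosage)
  snp_map <- as_tibble(snp_map)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    abort("`dosage` must carry individual ids (rownames) and SNP ids (colnames).")
  }
  if (!identical(colnames(dosage), snp_map$snp_id)) {
    abort("snp_map rows must match dosage columns (same SNP ids, same order).")
  }
  if (any(snp_map$maf <= 0 | snp_map$maf > 0.5)) {
    abort("maf must lie in (0, 0.5].")
  }
  ord_ok <- snp_map %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ord_ok$ok)) {
    abort("pos must be strictly increasing within each chromosome.")
  }
  structure(list(dosage = dosage, snp_map = snp_map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d SNPs on %d chromosome(s); MAF range [%.3f, %.3f]\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$snp_map$chrom)),
    min(x$snp_map$maf), max(x$snp_map$maf)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x genotype_matrix.
#' @param individuals,snps character or logical/integer selectors; `NULL`
#'   keeps everything.
#' @return genotype_matrix restricted to the selection, with MAF recomputed
#'   for the retained cohort when individuals change.
#' @export
subset_genotypes <- function(x, individuals = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  dosage <- x$dosage
  snp_map <- x$snp_map
  if (!is.null(snps)) {
    idx <- if (is.character(snps)) match(snps, colnames(dosage)) else seq_len(ncol(dosage))[snps]
    if (anyNA(idx)) abort("unknown SNP ids in selection.")
    dosage <- dosage[, idx, drop = FALSE]
    snp_map <- snp_map[idx, ]
  }
  if (!is.null(individuals)) {
    idx <- if (is.character(individuals)) match(individuals, rownames(dosage)) else seq_len(nrow(dosage))[individuals]
    if (anyNA(idx)) abort("unknown individual ids in selection.")
    dosage <- dosage[idx, , drop = FALSE]
    snp_map$maf <- colMeans(dosage, na.rm = TRUE) / 2
    # after subsetting the minor allele may flip; keep orientation but record freq
    snp_map$maf <- pmin(snp_map$maf, 1 - snp_map$maf)
    snp_map$maf[snp_map$maf == 0] <- NA_real_
  }
  structure(list(dosage = dosage, snp_map = snp_map), class = "genotype_matrix")
}

#' Rhizobiome trait matrix (ln relative abundance)
#'
#' Samples x microbial-group values on the natural-log relative-abundance
#' scale, with the sample design carried along and per-group metadata
#' (taxonomy label, member ASV count, nitrogen-response class).
#'
#' @param values numeric matrix samples x groups, finite.
#' @param sample_meta sample design tibble (as in [asv_table()]).
#' @param group_meta tibble keyed by `group_id` with at least `label` and
#'   `n_asvs`.
#' @param group_map tibble mapping `asv_id` -> `group_id`.
#'
#' @return Object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, sample_meta, group_meta, group_map = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) abort("trait values must be finite.")
  if (!identical(rownames(values), sample_meta$sample_id)) {
    abort("rownames(values) must equal sample_meta$sample_id.")
  }
  if (!identical(colnames(values), group_meta$group_id)) {
    abort("colnames(values) must equal group_meta$group_id.")
  }
  structure(
    list(values = values, sample_meta = as_tibble(sample_meta),
         group_meta = as_tibble(group_meta), group_map = group_map),
    class = "trait_matrix"
  )
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf(
    "<trait_matrix> %d samples x %d rhizobiome traits (ln relative abundance)\n",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Long-format view of a trait matrix
#'
#' @param x trait_matrix.
#' @param ... unused.
#' @return tibble with one row per (sample, group) carrying the design columns.
#' @method tidy trait_matrix
#' @export
tidy.trait_matrix <- function(x, ...) {
  as_tibble(x$values, rownames = "sample_id") %>%
    pivot_longer(-"sample_id", names_to = "group_id", values_to = "value") %>%
    left_join(x$sample_meta, by = "sample_id")
}
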
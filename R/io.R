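#' Read an ASV count table from TSV files
#'
#' Reads the three tab-separated files that make up an amplicon survey —
#' counts, taxonomy, and sample metadata — and assembles a validated
#' [asv_table()]. Count orientation (samples-in-rows vs ASVs-in-rows) is
#' auto-detected from id overlap with the metadata.
#'
#' @param counts_path TSV with a header row; first column holds ids.
#' @param taxonomy_path TSV keyed by `asv_id` with rank columns.
#' @param metadata_path TSV keyed by `sample_id` with the design columns.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(counts_path, taxonomy_path, metadata_path) {
  raw <- readr::read_tsv(counts_path, show_col_types = FALSE)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  tax <- readr::read_tsv(taxonomy_path, show_col_types = FALSE)
  if (!"sample_id" %in% names(meta)) {
    abort("metadata must contain a sample_id column.")
  }
  design_cols <- c("genotype", "treatment", "year", "block", "sp", "spb", "replicate")
  missing_cols <- setdiff(design_cols, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) abort("duplicate row ids in counts file.")
  mat <- as.matrix(raw[, -1])
  rownames(mat) <- ids
  bad <- which(is.na(suppressWarnings(mat * 1)) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-integer count at row '%s', column '%s'",
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ))
  }
  storage.mode(mat) <- "integer"
  # orientation: whichever margin shares more ids with the sample metadata
  row_hits <- mean(rownames(mat) %in% meta$sample_id)
  col_hits <- mean(colnames(mat) %in% meta$sample_id)
  if (col_hits > row_hits) mat <- t(mat)
  if (!"asv_id" %in% names(tax)) names(tax)[1] <- "asv_id"
  asv_table(mat, meta, tax)
}

#' Read SNP genotypes into minor-allele dosages
#'
#' Supports VCF (biallelic SNPs; multiallelic records skipped with a logged
#' count) and a PLINK-style transposed text dialect (columns `snp_id`,
#' `chrom`, `pos`, `allele1`, `allele2`, then one dosage-of-allele1 column
#' per individual). Dosages are recoded to count the cohort-wise minor
#' allele, sites below `maf_min` are dropped, and missing calls are either
#' preserved or mean-imputed on request.
#'
#' @param path file path.
#' @param format `"vcf"` or `"plink_text"`.
#' @param maf_min minimum minor-allele frequency retained (sites with
#'   `maf < maf_min` are removed).
#' @param impute_missing impute missing dosages to the site mean
#'   (standard practice for kinship/GWAS/BayesS inputs); default keeps NA.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "plink_text"), maf_min = 0,
                           impute_missing = FALSE) {
  format <- match.arg(format)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1
    n_skip <- sum(!biallelic)
    if (n_skip > 0) inform(sprintf("skipping %d multiallelic/non-SNP records", n_skip))
    gt <- vcfR::extract.gt(vcf, element = "GT")[biallelic, , drop = FALSE]
    fix <- fix[biallelic, , drop = FALSE]
    alt_count <- function(g) {
      g <- sub("\\|", "/", g)
      out <- rep(NA_real_, length(g))
      out[g %in% c("0/0")] <- 0
      out[g %in% c("0/1", "1/0")] <- 1
      out[g %in% c("1/1")] <- 2
      out
    }
    dos_alt <- t(apply(gt, 1, alt_count))  # snp x ind, ALT counts
    dosage <- t(dos_alt)                   # ind x snp
    rownames(dosage) <- colnames(gt)
    snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                     paste0(fix$CHROM, "_", fix$POS), fix$ID)
    colnames(dosage) <- snp_id
    map <- tibble(
      snp_id = snp_id, chrom = fix$CHROM, pos = as.integer(fix$POS),
      allele_ref = fix$REF, allele_alt = fix$ALT
    )
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
    need <- c("snp_id", "chrom", "pos", "allele1", "allele2")
    if (!all(need %in% names(raw))) {
      abort(paste0("plink_text requires columns: ", paste(need, collapse = ", ")))
    }
    ind_cols <- setdiff(names(raw), need)
    dosage <- t(as.matrix(raw[, ind_cols]))  # ind x snp, counts of allele1
    colnames(dosage) <- raw$snp_id
    map <- tibble(
      snp_id = raw$snp_id, chrom = as.character(raw$chrom),
      pos = as.integer(raw$pos), allele_ref = raw$allele1, allele_alt = raw$allele2
    )
    # dosage counts allele1 == "alt" slot for orientation below
    dosage <- 2 - dosage  # convert to counts of allele2 so slots align with VCF ALT
  }
  # orient to cohort-wise minor allele
  p_alt <- unname(colMeans(dosage, na.rm = TRUE) / 2)
  flip <- p_alt > 0.5
  dosage[, flip] <- 2 - dosage[, flip]
  maf <- pmin(p_alt, 1 - p_alt)
  map <- map %>%
    mutate(
      allele_minor = ifelse(flip, .data$allele_ref, .data$allele_alt),
      allele_major = ifelse(flip, .data$allele_alt, .data$allele_ref),
      maf = maf
    ) %>%
    select("snp_id", "chrom", "pos", "allele_major", "allele_minor", "maf")
  keep <- !is.na(map$maf) & map$maf > 0 & map$maf >= maf_min
  if (!any(keep)) abort("no polymorphic sites remain after the MAF filter.")
  dosage <- dosage[, keep, drop = FALSE]
  map <- map[keep, ]
  if (impute_missing && anyNA(dosage)) {
    mu <- colMeans(dosage, na.rm = TRUE)
    na_idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[na_idx] <- mu[na_idx[, 2]]
  }
  ord <- order(map$chrom, map$pos)
  genotype_matrix(dosage[, ord, drop = FALSE], map[ord, ])
}

#' Read a gene annotation from GFF3
#'
#' Keeps gene-type features with their 1-based inclusive transcribed spans
#' (the GFF native convention, preserved internally; conversion to BED
#' happens only in [write_bed()]).
#'
#' @param path GFF3 file.
#' @param chrom_alias optional named character vector mapping GFF chromosome
#'   names to the genotype panel's names.
#' @param feature_types GFF `type` values treated as genes.
#' @return tibble with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   sorted by (chrom, start).
#' @export
read_gene_annotation <- function(path, chrom_alias = NULL,
                                 feature_types = "gene") {
  gff <- ape::read.gff(path)
  genes <- gff[gff$type %in% feature_types, , drop = FALSE]
  id <- sub('.*ID=([^;]+).*', "\\1", genes$attributes)
  chrom <- as.character(genes$seqid)
  if (!is.null(chrom_alias)) {
    hit <- chrom %in% names(chrom_alias)
    chrom[hit] <- chrom_alias[chrom[hit]]
  }
  out <- tibble(
    gene_id = id, chrom = chrom,
    start = as.integer(genes$start), end = as.integer(genes$end),
    strand = as.character(genes$strand)
  )
  if (any(out$start > out$end)) abort("GFF records with start > end.")
  arrange(out, .data$chrom, .data$start)
}

#' Write MAPL regions as BED
#'
#' Emits BED6 (0-based half-open): internal 1-based inclusive starts are
#' decremented only here, at write time.
#'
#' @param mapls tibble of MAPL regions (from [call_mapls()]).
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mapls, path, seed = NULL) {
  hdr <- result_header(seed)
  lines <- hdr
  if (nrow(mapls) > 0) {
    bed <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t.",
      mapls$chrom, mapls$start, mapls$end,
      paste0("MAPL_", mapls$chrom, "_", mapls$window),
      mapls$n_signals
    )
    lines <- c(lines, bed)
  }
  writeLines(lines, path)
  invisible(path)
}

result_header <- function(seed = NULL) {
  sprintf(
    "# rhizotrait %s%s",
    as.character(utils::packageVersion("rhizotrait")),
    if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed))
  )
}

#' Write / read a result table as TSV
#'
#' Writers emit a header comment with the tool version (and seed, when
#' given); numeric columns round-trip at 12 significant digits.
#'
#' @param x data frame.
#' @param path output path.
#' @param seed optional seed recorded in the header comment.
#' @return `path` (write) or a tibble (read).
#' @export
write_result_table <- function(x, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(result_header(seed), con)
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) format(v, digits = 12, trim = TRUE, scientific = NA))
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}
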
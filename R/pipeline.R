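#' Run the full synthetic-to-summary demonstration pipeline
#'
#' Generates a seeded synthetic field study (genotypes, split-plot design,
#' overdispersed counts, fitness proxy) and runs every analysis stage over
#' it: trait construction and differential abundance, heritability with the
#' permutation null, BLUPs, selection differentials, LD pruning and BayesS,
#' mixed-model GWAS, MAPL calling with gene annotation, and the
#' microbe-phenotype integration summary. All stage parameters live in a
#' single config list (unknown keys rejected); results are returned and,
#' when `out_dir` is given, written as TSVs alongside a JSON manifest
#' (resolved config, seed, package version).
#'
#' @param config named list overriding the defaults below.
#' @param seed master seed; every stage draws from it deterministically.
#' @param out_dir optional output directory.
#' @return named list with every stage's result tables.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = NULL) {
  defaults <- list(
    n_geno = 60, n_snp = 800, n_groups = 12,
    h2_targets = c(0, 0.2, 0.4, 0.6), n_causal = 10,
    ld_rho = 0.5, block_len = 10,
    s_true = c(0.2), c_true = c(0), fitness_noise = 0.3,
    herit_B = 199, boot_B = 199, perm_B = 99,
    bayess_chain = 4000, bayess_burnin = 1000,
    gwas_traits = 2, window_bp = 10000, min_signals = 1,
    flank = 10000, alpha = 0.05
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  set.seed(seed)

  geno <- simulate_genotypes(cfg$n_geno, cfg$n_snp, ld_rho = cfg$ld_rho,
                             block_len = cfg$block_len, seed = seed)
  design <- simulate_design(rownames(geno$dosage), seed = seed + 1)
  sim <- simulate_group_traits(
    geno, design, h2_targets = cfg$h2_targets, n_groups = cfg$n_groups,
    n_causal = cfg$n_causal, seed = seed + 2
  )
  da <- differential_abundance(sim$traits)
  h2 <- estimate_heritability(sim$traits, B = cfg$herit_B, seed = seed + 3)
  blups <- compute_blups(sim$traits)

  # fitness generated from the standardized BLUPs of the most heritable trait
  # (null traits have all-zero BLUPs at the Vg = 0 boundary)
  focal <- h2 %>%
    group_by(.data$group_id) %>%
    summarise(h2 = mean(.data$h2)) %>%
    arrange(dplyr::desc(.data$h2)) %>%
    slice(1) %>% pull("group_id")
  wide <- blups %>%
    filter(.data$group_id == focal) %>%
    group_by(.data$treatment) %>%
    mutate(z = standardize(.data$blup)) %>%
    ungroup()
  fit_parts <- wide %>%
    group_by(.data$treatment) %>%
    group_modify(function(df, key) {
      fs <- simulate_fitness(matrix(df$z, ncol = 1), cfg$s_true, cfg$c_true,
                             noise_sd = cfg$fitness_noise, seed = seed + 4)
      tibble(genotype = df$genotype, cc = unname(fs$cc))
    }) %>% ungroup()
  sel <- estimate_selection(blups, fit_parts, B = cfg$boot_B, seed = seed + 5)

  pruned <- ld_prune(geno)
  y1 <- blups %>% filter(.data$group_id == focal,
                         .data$treatment == "plusN")
  bay <- bayess(setNames(y1$blup, y1$genotype), pruned,
                chain_length = cfg$bayess_chain, burnin = cfg$bayess_burnin,
                seed = seed + 6)

  K <- grm(geno)
  meff <- effective_snp_number(geno)
  thr <- significance_threshold(cfg$alpha, meff)
  gwas_groups <- unique(c(focal, head(unique(blups$group_id), cfg$gwas_traits)))[seq_len(cfg$gwas_traits)]
  gwas_all <- list()
  for (g in gwas_groups) {
    for (trt in unique(blups$treatment)) {
      b <- filter(blups, .data$group_id == g, .data$treatment == trt)
      res <- lmm_gwas(setNames(b$blup, b$genotype), geno, K = K)
      gwas_all[[paste(g, trt)]] <- mutate(as_tibble(res), group_id = g, treatment = trt)
    }
  }
  gwas_all <- list_rbind(gwas_all)
  mapls <- call_mapls(gwas_all, window_bp = cfg$window_bp, threshold = thr,
                      min_signals = cfg$min_signals)
  # synthetic gene models tiled over the simulated chromosomes
  genes <- tibble(
    gene_id = sprintf("gene%05d", seq_len(50)),
    chrom = rep(unique(geno$snp_map$chrom), length.out = 50),
    start = rep(seq(1000, 200000, length.out = 25), length.out = 50),
    end = NA_real_, strand = "+"
  ) %>% mutate(start = as.integer(.data$start), end = .data$start + 2999L)
  mapls <- annotate_mapl_genes(mapls, genes, flank = cfg$flank)

  plant <- fit_parts %>% rename(value = "cc")
  corr <- correlate_traits(blups, plant)
  perm <- count_significant_permutation(blups, plant, B = cfg$perm_B,
                                        seed = seed + 7)
  h2rel <- heritability_correlation_relation(h2, corr)
  summary_tbl <- build_summary(h2, sel, mapls, corr)

  results <- list(
    truth = sim$truth, differential_abundance = da, heritability = h2,
    blups = blups, selection = sel, bayess = glance(bay), gwas = gwas_all,
    meff = meff, threshold = thr, mapls = mapls, correlations = corr,
    cc_permutation = list(count_obs = perm$count_obs, p = perm$p),
    h2_correlation = h2rel, summary = summary_tbl
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tabs <- c("differential_abundance", "heritability", "blups", "selection",
              "gwas", "mapls", "correlations", "h2_correlation", "summary")
    for (nm in tabs) {
      write_result_table(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         seed = seed)
    }
    write_bed(results$mapls, file.path(out_dir, "mapls.bed"), seed = seed)
    manifest <- list(
      package_version = as.character(utils::packageVersion("rhizotrait")),
      seed = seed, config = cfg,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results
}

#' Scatter plot of per-trait heritability across treatments
#'
#' @param h2_table tibble from [estimate_heritability()] with both
#'   treatments present.
#' @param p_cut permutation significance cutoff for the colour classes.
#' @return ggplot object.
#' @export
plot_heritability <- function(h2_table, p_cut = 0.05) {
  wide <- h2_table %>%
    mutate(sig = .data$p < p_cut) %>%
    select("group_id", "treatment", "h2", "sig") %>%
    pivot_wider(names_from = "treatment", values_from = c("h2", "sig"))
  wide$class <- dplyr::case_when(
    wide$sig_plusN & wide$sig_minusN ~ "both",
    wide$sig_plusN ~ "plusN only",
    wide$sig_minusN ~ "minusN only",
    TRUE ~ "ns"
  )
  ggplot2::ggplot(wide, ggplot2::aes(.data$h2_plusN, .data$h2_minusN,
                                     colour = .data$class)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(h^2 ~ "(+N)"), y = expression(h^2 ~ "(-N)")) +
    ggplot2::theme_minimal()
}
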
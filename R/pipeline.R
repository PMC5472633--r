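# End-to-end orchestration: simulate (or load) a genus, infer orthologous
# groups, pan-genome statistics, recombination screen, partitioned trees,
# ANI/gANI-AF delineation, marker and trait analyses, one summary.

#' Recompute the headline ledger from raw counts
#'
#' Percentages are always recomputed from the counts (round-half-even, one
#' decimal), never copied, and the internal consistency of the counts is
#' asserted.
#'
#' @param n_ogs orthologous groups (multi-member clusters).
#' @param n_singletons unclustered genes.
#' @param core_size OGs present in every strain.
#' @param scc_size single-copy core OGs.
#' @param n_recombinant SCC genes with evidence of recombination.
#' @param n_incongruent recombinant genes with species-level incongruent
#'   gene trees (optional).
#' @param avg_gene_count mean genes per genome (optional).
#' @return list of class `run_counts` with all derived quantities.
#' @export
summarize_counts <- function(n_ogs, n_singletons, core_size, scc_size,
                             n_recombinant, n_incongruent = NA_integer_,
                             avg_gene_count = NA_real_) {
  if (scc_size > core_size) stop("inconsistent counts: scc > core")
  if (core_size > n_ogs) stop("inconsistent counts: core > OGs")
  if (n_recombinant > scc_size) stop("inconsistent counts: recombinant > SCC")
  if (!is.na(n_incongruent) && n_incongruent > n_recombinant)
    stop("inconsistent counts: incongruent > recombinant")
  pan <- n_ogs + n_singletons
  out <- list(
    n_ogs = n_ogs, n_singletons = n_singletons, pan_size = pan,
    core_size = core_size, scc_size = scc_size,
    n_recombinant = n_recombinant,
    n_minimum_core = scc_size - n_recombinant,
    pct_recombinant = pct1(n_recombinant, scc_size),
    core_pct_of_pan = round(100 * core_size / pan),
    n_incongruent = n_incongruent,
    pct_incongruent_of_recombinant =
      if (is.na(n_incongruent)) NA_real_ else pct1(n_incongruent, n_recombinant),
    pct_incongruent_of_scc =
      if (is.na(n_incongruent)) NA_real_ else pct1(n_incongruent, scc_size),
    avg_gene_count = avg_gene_count,
    core_pct_of_avg_gene_count =
      if (is.na(avg_gene_count)) NA_real_ else round(100 * core_size / avg_gene_count))
  class(out) <- "run_counts"
  out
}

#' Run the full pipeline on a simulated genus
#'
#' simulate -> orthologous groups -> core/SCC -> pan-genome statistics ->
#' recombination screen -> partitioned concatenated trees -> ANI and gANI/AF
#' delineation -> 16S marker regression -> accessory trait clustering ->
#' summary. Fully deterministic for a fixed config and seed; stage failures
#' abort with the stage name.
#'
#' @param config path to a JSON config, or a list with elements `pipeline`
#'   (a [pipeline_config()]) and `simulation` (a [sim_params()]).
#' @param out_dir optional artifact directory (written when given).
#' @param seed optional override of both seeds.
#' @param n_perm_rarefaction permutations for the rarefaction curves.
#' @return list of class `run_summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         n_perm_rarefaction = 50L) {
  if (is.character(config)) config <- read_config(config)
  cfg <- config$pipeline %||% pipeline_config()
  sim <- config$simulation %||% sim_params()
  if (!is.null(seed)) {
    cfg$rng_seed <- as.integer(seed)
    sim$seed <- as.integer(seed)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pd_log("simulating genus", verbose = cfg$verbose)
  genus <- stage("simulate", simulate_genus(sim))
  if (!is.null(out_dir)) stage("emit", emit_genus(genus, out_dir))

  pd_log("orthology", verbose = cfg$verbose)
  gene_seqs <- stage("orthology", extract_gene_seqs(genus$genomes,
                                                    genus$gene_tables))
  gene_strains <- stats::setNames(genus$gene_tables$strain,
                                  genus$gene_tables$gene_id)
  hits <- stage("orthology", all_vs_all_similarity(
    gene_seqs, cutoff = cfg$similarity_cutoff,
    min_coverage = cfg$min_coverage))
  om <- stage("orthology", mcl_cluster(hits, inflation = cfg$inflation,
                                       genes = names(gene_seqs),
                                       gene_strains = gene_strains))
  core <- stage("orthology", extract_core(om))
  ostats <- stage("orthology", og_stats(om, core))

  pd_log("pan-genome statistics", verbose = cfg$verbose)
  spectrum <- stage("pangenome", occupancy_spectrum(om,
                                                    exclude_singletons = FALSE))
  rare <- stage("pangenome", rarefy(om, n_perm = n_perm_rarefaction,
                                    seed = cfg$rng_seed))
  richness <- stage("pangenome", list(s_obs = sum(spectrum),
                                      chao = chao_estimate(spectrum),
                                      ace = ace_estimate(spectrum)))

  pd_log("recombination screen", verbose = cfg$verbose)
  scc_aln <- stage("recombination", scc_alignments(om, core, gene_seqs,
                                                   gene_strains))
  report <- stage("recombination", screen_genes(
    scc_aln, alpha = cfg$alpha, n_perm = cfg$n_permutations,
    seed = cfg$rng_seed, phi_window = cfg$phi_window))

  pd_log("trees", verbose = cfg$verbose)
  trees <- stage("trees", {
    out <- list(scc = midpoint_root(nj_tree(jc69_distances(
      concatenate_alignments(scc_aln)))))
    if (length(report$recombinant_set))
      out$recombinant <- midpoint_root(nj_tree(jc69_distances(
        concatenate_alignments(scc_aln, report$recombinant_set))))
    if (length(report$minimum_core_set))
      out$minimum_core <- midpoint_root(nj_tree(jc69_distances(
        concatenate_alignments(scc_aln, report$minimum_core_set))))
    out
  })

  pd_log("ANI", verbose = cfg$verbose)
  gene_sets <- split(gene_seqs, gene_strains[names(gene_seqs)])
  ani_res <- stage("ani", ani_matrix(genus$genomes, cfg,
                                     gene_sets = gene_sets))
  part_ani <- stage("ani", delineate_species(ani_res, "ani95", cfg))
  part_gani <- stage("ani", delineate_species(ani_res, "gani_af", cfg))

  pd_log("markers and traits", verbose = cfg$verbose)
  markers <- stage("markers", marker_set(genus$marker_seqs))
  snp_fit <- stage("markers", tryCatch(snp_vs_ani(markers, ani_res),
                                       error = function(e) NULL))
  traits <- stage("traits", if (ncol(genus$presence) >= 1)
    trait_cluster(1 * genus$presence) else NULL)

  pd_log("congruence", verbose = cfg$verbose)
  assignment <- part_ani$assignment
  tree_cmp <- stage("congruence",
                    partition_tree_comparison(trees, assignment))
  incong <- stage("congruence", {
    flags <- vapply(report$recombinant_set, function(g) {
      gt <- nj_tree(jc69_distances(scc_aln[[g]]))
      species_monophyly(gt, assignment)$incongruent
    }, logical(1))
    names(which(flags))
  })

  counts <- summarize_counts(
    n_ogs = ostats$n_ogs, n_singletons = ostats$n_singletons,
    core_size = ostats$core_size, scc_size = length(scc_aln),
    n_recombinant = length(report$recombinant_set),
    n_incongruent = length(incong),
    avg_gene_count = ostats$avg_gene_count)
  stopifnot(counts$n_recombinant + counts$n_minimum_core == counts$scc_size,
            counts$pan_size == counts$n_ogs + counts$n_singletons)

  summary <- structure(list(
    n_strains = length(genus$strains), counts = counts,
    richness = richness, rarefaction = rare, spectrum = spectrum,
    recomb = report$summary,
    n_candidate_species_ani = length(unique(part_ani$assignment)),
    n_candidate_species_gani_af = length(unique(part_gani$assignment)),
    species_level_congruent = tree_cmp$species_level_congruent,
    tree_comparison = tree_cmp,
    snp_fit = if (!is.null(snp_fit)) snp_fit$fit,
    truth_agreement_ani = partition_agreement(part_ani$assignment,
                                              genus$truth_species)),
    class = "run_summary")

  if (!is.null(out_dir)) {
    stage("write", {
      write_matrix_tsv(ani_res$ani, file.path(out_dir, "ani.tsv"))
      if (!is.null(ani_res$gani)) {
        write_matrix_tsv(ani_res$gani, file.path(out_dir, "gani.tsv"))
        write_matrix_tsv(ani_res$af, file.path(out_dir, "af.tsv"))
      }
      utils::write.table(report$results, file.path(out_dir, "recombination.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(report$recombinant_set, file.path(out_dir, "recombinant.txt"))
      writeLines(report$minimum_core_set, file.path(out_dir, "minimum_core.txt"))
      for (nm in names(trees))
        write_newick(trees[[nm]], file.path(out_dir, paste0(nm, ".nwk")))
      utils::write.table(as.data.frame(rare), file.path(out_dir, "rarefaction.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(strain = names(assignment),
                                    candidate_species = unname(assignment)),
                         file.path(out_dir, "species_partition.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary_df <- data.frame(field = names(unlist(counts)),
                               value = unname(unlist(counts)))
      utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  c0 <- x$counts
  cat("phylodelim run summary\n")
  cat(sprintf("  strains: %d\n", x$n_strains))
  cat(sprintf("  OGs: %d  singletons: %d  pan: %d\n",
              c0$n_ogs, c0$n_singletons, c0$pan_size))
  cat(sprintf("  core: %d  SCC: %d (core = %d%% of pan, %s%% of avg gene content)\n",
              c0$core_size, c0$scc_size, c0$core_pct_of_pan,
              format(c0$core_pct_of_avg_gene_count)))
  cat(sprintf("  recombinant: %d (%.1f%% of SCC)  minimum core: %d\n",
              c0$n_recombinant, c0$pct_recombinant, c0$n_minimum_core))
  if (!is.na(c0$n_incongruent))
    cat(sprintf("  incongruent gene trees: %d (%.1f%% of recombinant, %.1f%% of SCC)\n",
                c0$n_incongruent, c0$pct_incongruent_of_recombinant,
                c0$pct_incongruent_of_scc))
  cat(sprintf("  candidate species: ANI95 %d, gANI/AF %d\n",
              x$n_candidate_species_ani, x$n_candidate_species_gani_af))
  cat(sprintf("  richness: observed %d, Chao1 %.1f, ACE %.1f\n",
              x$richness$s_obs, x$richness$chao, x$richness$ace))
  cat(sprintf("  species-level congruent trees: %s\n",
              x$species_level_congruent))
  invisible(x)
}
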
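test_that("species tree has the stated shape and depths", {
  t1 <- simulate_species_tree(1, 2, 0.01, 0.06, seed = 1)
  expect_equal(length(t1$tip.label), 2L)

  tr <- simulate_species_tree(3, c(2, 2, 2), 0.01, 0.06, seed = 2)
  truth <- attr(tr, "truth_species")
  cong <- species_monophyly(tr, truth)
  expect_false(cong$incongruent)  # all species monophyletic by construction

  d <- ape::cophenetic.phylo(tr)
  within <- d["s01_01", "s01_02"]
  between <- d["s01_01", "s02_01"]
  expect_gt(between, within)
  expect_equal(between, 2 * 0.06, tolerance = 1e-8)
  expect_lte(within, 2 * 0.01 + 1e-8)

  expect_error(simulate_species_tree(2, c(2, 0), 0.01, 0.06), "strain")
})

test_that("evolve_family follows the JC expectation", {
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  anc <- rand_dna(10000, seed = 3)

  frozen <- evolve_family(tr, anc, 0, seed = 4)
  expect_identical(unname(frozen), c(anc, anc))  # rate 0: no change

  # closed-form JC: E[p] = 3/4 (1 - exp(-4 d / 3)) with d = 0.1 total path
  expect_error(evolve_family(ape::read.tree(text = "(x:-1,y:1);"), anc),
               "negative")
  p_exp <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  ps <- vapply(1:60, function(i) {
    a <- evolve_family(tr, anc, 1, seed = 1000 + i)
    mean(strsplit(a[[1]], "")[[1]] != strsplit(a[[2]], "")[[1]])
  }, numeric(1))
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - p_exp), 3 * se + 1e-4)

  # deeper pairs diverge at least as much, in expectation
  tr2 <- ape::read.tree(text = "((a:0.01,b:0.01):0.09,c:0.10);")
  dd <- rowMeans(vapply(1:40, function(i) {
    al <- evolve_family(tr2, rand_dna(2000, seed = i), 1, seed = 5000 + i)
    c(shallow = mean(strsplit(al[["a"]], "")[[1]] != strsplit(al[["b"]], "")[[1]]),
      deep = mean(strsplit(al[["a"]], "")[[1]] != strsplit(al[["c"]], "")[[1]]))
  }, numeric(2)))
  expect_gt(dd[["deep"]], dd[["shallow"]])
})

test_that("recombination events have the stated tract semantics", {
  p0 <- sim_params(n_species = 2, strains_per_species = 2, n_core_genes = 10,
                   n_accessory_genes = 0, paralog_rate = 0,
                   recomb_gene_fraction = 0, seed = 11)
  g0 <- simulate_genus(p0)
  expect_equal(nrow(g0$truth_events), 0L)

  # whole-allele replacement: recipient allele equals donor allele exactly
  p1 <- sim_params(n_species = 2, strains_per_species = 2, n_core_genes = 10,
                   n_accessory_genes = 0, paralog_rate = 0,
                   recomb_gene_fraction = 0.5, recomb_tract_fraction = 1.0,
                   seed = 11)
  g1 <- apply_recombination(g0, p1, seed = 12)
  expect_equal(nrow(g1$truth_events), 5L)
  for (i in seq_len(nrow(g1$truth_events))) {
    ev <- g1$truth_events[i, ]
    expect_false(g1$truth_species[[ev$donor_strain]] ==
                   g1$truth_species[[ev$recipient_strain]])
    expect_identical(g1$alignments[[ev$family_id]][[ev$recipient_strain]],
                     g1$alignments[[ev$family_id]][[ev$donor_strain]])
  }

  # partial tract: donor inside the tract, pre-event self outside
  p2 <- sim_params(n_species = 2, strains_per_species = 2, n_core_genes = 10,
                   n_accessory_genes = 0, paralog_rate = 0,
                   recomb_gene_fraction = 0.2, recomb_tract_fraction = 0.5,
                   seed = 11)
  g2 <- apply_recombination(g0, p2, seed = 13)
  ev <- g2$truth_events[1, ]
  new_seq <- g2$alignments[[ev$family_id]][[ev$recipient_strain]]
  old_seq <- g0$alignments[[ev$family_id]][[ev$recipient_strain]]
  don_seq <- g2$alignments[[ev$family_id]][[ev$donor_strain]]
  expect_identical(substr(new_seq, ev$tract_start + 1, ev$tract_end),
                   substr(don_seq, ev$tract_start + 1, ev$tract_end))
  outside <- c(substr(new_seq, 1, ev$tract_start),
               substr(new_seq, ev$tract_end + 1, nchar(new_seq)))
  expect_identical(outside, c(substr(old_seq, 1, ev$tract_start),
                              substr(old_seq, ev$tract_end + 1, nchar(old_seq))))

  expect_error(apply_recombination(
    simulate_genus(sim_params(n_species = 1, strains_per_species = 4,
                              n_core_genes = 5, n_accessory_genes = 0,
                              within_species_div = 0.01,
                              between_species_div = 0.05, seed = 3)),
    sim_params(n_species = 1, strains_per_species = 4, n_core_genes = 5,
               n_accessory_genes = 0, recomb_gene_fraction = 0.5,
               within_species_div = 0.01, between_species_div = 0.05,
               seed = 3)), ">= 2 species")
})

test_that("emitted genus round-trips and is byte-deterministic", {
  g <- tiny_genus()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_genus(g, d1)

  strains <- g$strains
  expect_length(list.files(file.path(d1, "genomes")), length(strains))
  expect_length(list.files(file.path(d1, "gene_tables")), length(strains))
  expect_true(file.exists(file.path(d1, "truth_species.tsv")))

  # re-read coordinates and slice: reproduces every gene sequence
  s <- strains[1]
  genome <- read_fasta(file.path(d1, "genomes", paste0(s, ".fna")))
  tab <- read.delim(file.path(d1, "gene_tables", paste0(s, ".tsv")))
  tab$strain <- s
  sliced <- extract_gene_seqs(stats::setNames(list(genome), s), tab)
  aln_dir <- file.path(d1, "alignments")
  for (i in seq_len(nrow(tab))) {
    fam <- tab$family_id[i]
    if (grepl("\\|p", tab$gene_id[i])) next   # paralog copies diverge by design
    fam_aln <- read_fasta(file.path(aln_dir, paste0(fam, ".fasta")))
    expect_identical(unname(sliced[i]), unname(fam_aln[[s]]))
  }

  # same params -> byte-identical emission
  g_again <- simulate_genus(g$params)
  emit_genus(g_again, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("marker copies are identical within strains, counts in range", {
  g <- tiny_genus()
  rng <- g$params$marker_copies_range
  for (s in g$strains) {
    cp <- g$marker_seqs[[s]]
    expect_gte(length(cp), rng[1])
    expect_lte(length(cp), rng[2])
    expect_length(unique(cp), 1L)
  }
  # slow marker: divergence well below core-gene divergence
  ms <- marker_set(g$marker_seqs)
  snps <- utils::combn(g$strains, 2, function(pr) snp_count(ms[[pr[1]]], ms[[pr[2]]]))
  expect_lte(max(snps), 14)
})

test_that("accessory occupancy spectrum has mass at both extremes", {
  p <- sim_params(n_species = 3, strains_per_species = 4, n_core_genes = 40,
                  n_accessory_genes = 60, paralog_rate = 0, seed = 23)
  g <- simulate_genus(p)
  n <- length(g$strains)
  occ <- colSums(g$presence)
  core_mass <- p$n_core_genes + sum(occ == n)
  rare_mass <- sum(occ <= 2)
  mid <- vapply(3:(n - 1), function(j) sum(occ == j), numeric(1))
  expect_gt(rare_mass, 0)
  expect_true(all(core_mass > mid))
})

test_that("without recombination and paralogs, gene trees respect species", {
  p <- sim_params(n_species = 3, strains_per_species = 2, n_core_genes = 4,
                  n_accessory_genes = 0, paralog_rate = 0, gene_len = 5000,
                  within_species_div = 0.01, between_species_div = 0.05,
                  seed = 31)
  g <- simulate_genus(p)
  for (f in g$core_ids) {
    gt <- nj_tree(jc69_distances(g$alignments[[f]]))
    expect_false(species_monophyly(gt, g$truth_species)$incongruent, label = f)
  }
})
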
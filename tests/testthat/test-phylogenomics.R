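test_that("JC69 distances match the closed form, with saturation capping", {
  a <- strrep("A", 1000)
  b <- paste0(strrep("C", 100), strrep("A", 900))     # p = 0.1
  d <- jc69_distances(c(x = a, y = b, z = a))
  expect_equal(d["x", "y"], -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-9)
  expect_equal(d["x", "y"], 0.10732, tolerance = 1e-4)
  expect_equal(d["x", "z"], 0)

  sat <- c(x = strrep("A", 100), y = paste0(strrep("C", 75), strrep("A", 25)))
  expect_warning(ds <- jc69_distances(sat), "saturated")
  expect_equal(ds["x", "y"], 5.0)

  # pairwise deletion skips gap/N columns
  g1 <- c(x = "ACGTN", y = "ACGT-")
  expect_equal(jc69_distances(g1)["x", "y"], 0)
})

test_that("NJ recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):1);")
  dm <- ape::cophenetic.phylo(tr)
  out <- nj_tree(dm)
  expect_equal(rf_distance(out, tr), 0L)
  expect_equal(sort(ape::cophenetic.phylo(out)[rownames(dm), colnames(dm)]),
               sort(dm), tolerance = 1e-9)

  # all 15 labelled 5-taxon topologies (oracle: phangorn's enumeration)
  all5 <- phangorn::allTrees(5, rooted = FALSE, tip.label = letters[1:5])
  for (i in seq_along(all5)) {
    t5 <- all5[[i]]
    t5$edge.length <- phylodelim:::with_seed(i, runif(nrow(t5$edge), 0.5, 3))
    d5 <- ape::cophenetic.phylo(t5)
    expect_equal(rf_distance(nj_tree(d5), t5), 0L, label = paste("topology", i))
  }
})

test_that("NJ is invariant to label order and handles small cases", {
  tr <- phylodelim:::with_seed(3, ape::rtree(8))
  dm <- ape::cophenetic.phylo(tr)
  perm <- phylodelim:::with_seed(4, sample(rownames(dm)))
  expect_setequal(tree_splits(nj_tree(dm)),
                  tree_splits(nj_tree(dm[perm, perm])))

  d3 <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  expect_equal(length(t3$tip.label), 3L)

  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_true(isTRUE(attr(t2, "degenerate")))
})

test_that("midpoint rooting places the root on the longest path", {
  t2 <- midpoint_root(ape::read.tree(text = "(a:1,b:3);"))
  dep <- ape::node.depth.edgelength(t2)
  expect_equal(dep[1:2], c(2, 2))     # 2.0 from each leaf

  sym <- ape::unroot(ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);"))
  ms <- midpoint_root(sym)
  expect_equal(unname(ape::node.depth.edgelength(ms)[1:4]), rep(2, 4))

  cat <- ape::read.tree(text = "(((a:1,b:2):1,c:1):1,d:5);")
  mc <- midpoint_root(ape::unroot(cat))
  # longest path: b..d = 2 + 1 + 1 + 5 = 9; root at 4.5 from each end
  dep_c <- ape::node.depth.edgelength(mc)
  names(dep_c)[1:4] <- mc$tip.label
  expect_equal(max(dep_c), 4.5)
  expect_equal(unname(dep_c["d"]), 4.5)
  expect_equal(unname(dep_c["b"]), 4.5)

  # midpoint property on random trees: the deepest tip depth = half the
  # longest leaf-leaf path
  for (s in 1:5) {
    tr <- phylodelim:::with_seed(s, ape::rtree(10))
    mr <- midpoint_root(ape::unroot(tr))
    half <- max(ape::cophenetic.phylo(tr)) / 2
    expect_equal(max(ape::node.depth.edgelength(mr)), half, tolerance = 1e-9)
  }
})

test_that("bootstrap supports behave at the extremes", {
  # one resolving pattern repeated: every replicate identical, support 100
  aln <- c(a = strrep("A", 60), b = strrep("A", 60),
           c = strrep("C", 60), d = strrep("C", 60))
  # the a/b vs c/d contrast saturates the JC correction by construction
  bt <- suppressWarnings(bootstrap_support(aln, n_boot = 50, seed = 1))
  labs <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(labs[!is.na(labs)] == 100))

  # 90% of columns for ab|cd, 10% for ac|bd: majority split wins
  cols_ab <- c("A", "A", "C", "C"); cols_ac <- c("A", "C", "A", "C")
  m <- cbind(matrix(rep(cols_ab, 90), 4), matrix(rep(cols_ac, 10), 4))
  aln2 <- stats::setNames(apply(m, 1, paste, collapse = ""),
                          c("a", "b", "c", "d"))
  bt2 <- suppressWarnings(bootstrap_support(aln2, n_boot = 200, seed = 2))
  sup <- as.numeric(bt2$node.label[nzchar(bt2$node.label)])
  expect_true(all(sup >= 0 & sup <= 100))
  expect_setequal(tree_splits(bt2), paste(c("c", "d"), collapse = "|"))
  expect_gt(max(sup), 50)
})

test_that("concatenation is additive with an exact partition map", {
  a1 <- c(s1 = strrep("A", 10), s2 = strrep("C", 10))
  a2 <- c(s1 = strrep("G", 20), s2 = strrep("T", 20))
  cc <- concatenate_alignments(list(g2 = a2, g1 = a1))
  expect_equal(unname(nchar(cc)), c(30, 30))
  pm <- attr(cc, "partition_map")
  expect_equal(pm$gene, c("g1", "g2"))      # sorted gene order
  expect_equal(pm$start, c(0, 10))
  expect_equal(pm$end, c(10, 30))

  expect_error(concatenate_alignments(list(g1 = a1), character(0)), "empty")
  a3 <- c(s1 = "AAAA", s3 = "CCCC")
  expect_error(concatenate_alignments(list(g1 = a1, g3 = a3)), "mismatch.*s2|s2.*mismatch")

  sub1 <- concatenate_alignments(list(g1 = a1, g2 = a2), "g1")
  sub2 <- concatenate_alignments(list(g1 = a1, g2 = a2), "g2")
  expect_equal(nchar(sub1[[1]]) + nchar(sub2[[1]]), nchar(cc[[1]]))
})

test_that("species monophyly and offenders are scored correctly", {
  asg <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  cg <- species_monophyly(good, asg)
  expect_false(cg$incongruent)
  expect_true(all(cg$monophyly))

  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  cb <- species_monophyly(bad, asg)
  expect_true(cb$incongruent)
  expect_false(any(cb$monophyly))
  expect_length(cb$offending_strains[["A"]], 1L)

  single <- species_monophyly(good, c(a1 = "A", a2 = "A", b1 = "B", b2 = "C"))
  expect_true(single$monophyly[["C"]])      # singleton by convention

  expect_error(species_monophyly(good, asg[1:3]), "unassigned")
})

test_that("RF distance is a split-set symmetric difference", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  expect_equal(rf_distance(t1, t1), 0L)
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1,(e:1,f:1):1);")
  expect_equal(rf_distance(t1, t2), 4L)
  expect_equal(rf_distance(t2, t1), rf_distance(t1, t2))
  n <- 8
  for (s in 1:4) {
    ta <- phylodelim:::with_seed(s, ape::rtree(n))
    tb <- phylodelim:::with_seed(s + 50, ape::rtree(n))
    expect_lte(rf_distance(ta, tb), 2 * (n - 3))
  }
  expect_error(rf_distance(t1, ape::rtree(4)), "leaf sets")
})

test_that("partition comparison separates species-level from within-species", {
  asg <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  t1 <- ape::read.tree(text = "(((a1:1,a2:1):1,a3:1):1,((b1:1,b2:1):1,b3:1):1);")
  same <- partition_tree_comparison(list(x = t1, y = t1), asg)
  expect_true(same$species_level_congruent)
  expect_equal(same$rf["x", "y"], 0L)

  # shuffle within species A only: still species-level congruent, RF > 0
  t2 <- ape::read.tree(text = "(((a1:1,a3:1):1,a2:1):1,((b1:1,b2:1):1,b3:1):1);")
  diff <- partition_tree_comparison(list(x = t1, y = t2), asg)
  expect_true(diff$species_level_congruent)
  expect_gt(diff$rf["x", "y"], 0L)
})

test_that("partial-tract recombination leaves a strict minority-to-majority
           band of incongruent gene trees", {
  # tract 0.5 cross-clade events: some gene trees flip, never all of them
  p <- sim_params(n_species = 3, strains_per_species = 4, n_core_genes = 60,
                  n_accessory_genes = 0, paralog_rate = 0,
                  within_species_div = 0.01, between_species_div = 0.06,
                  recomb_gene_fraction = 0.6, recomb_tract_fraction = 0.5,
                  seed = 909)
  g <- simulate_genus(p)
  rec <- unique(g$truth_events$family_id)
  fl <- vapply(rec, function(f) {
    gt <- nj_tree(jc69_distances(g$alignments[[f]]))
    species_monophyly(gt, g$truth_species)$incongruent
  }, logical(1))
  expect_gt(mean(fl), 0)
  expect_lt(mean(fl), 1)
})

test_that("whole-allele transfer makes gene trees species-incongruent", {
  tr <- simulate_species_tree(2, 4, 0.01, 0.05, seed = 61)
  truth <- attr(tr, "truth_species")
  flags <- vapply(1:30, function(i) {
    aln <- evolve_family(tr, rand_dna(900, seed = 8000 + i), 1, seed = 8100 + i)
    aln[["s02_01"]] <- aln[["s01_01"]]     # donor allele replaces the recipient
    gt <- nj_tree(jc69_distances(aln))
    species_monophyly(gt, truth)$incongruent
  }, logical(1))
  expect_gte(mean(flags), 0.9)
})
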
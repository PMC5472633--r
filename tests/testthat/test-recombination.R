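# build an alignment from explicit columns (rows = sequences)
aln_from_cols <- function(cols, n_pad = 0, pad_at = NULL, total_len = NULL,
                          positions = NULL) {
  m <- do.call(cbind, cols)
  n <- nrow(m)
  if (!is.null(positions)) {
    L <- total_len %||% max(positions)
    full <- matrix("A", n, L)
    full[, positions] <- m
    m <- full
  }
  out <- apply(m, 1, paste, collapse = "")
  names(out) <- sprintf("t%02d", seq_len(n))
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("informative sites are selected as defined", {
  ident <- stats::setNames(rep("ACGTACGT", 4), paste0("s", 1:4))
  expect_equal(informative_sites(ident)$k, 0L)

  cols <- list(c("A", "A", "C", "C"),   # informative
               c("A", "A", "A", "C"),   # singleton variant: dropped
               c("A", "-", "A", "A"),   # gap column: dropped
               c("G", "G", "T", "T"))   # informative
  aln <- aln_from_cols(cols)
  si <- informative_sites(aln)
  expect_equal(si$k, 2L)
  expect_equal(si$positions, c(1L, 4L))
  expect_error(informative_sites(ident[1:3]), ">= 4")
})

test_that("pair incompatibility is the cyclomatic number", {
  # four gametes: incompatible
  expect_equal(pair_incompatibility(c("A", "A", "C", "C"),
                                    c("A", "C", "A", "C")), 1L)
  # three joint states: compatible
  expect_equal(pair_incompatibility(c("A", "A", "C", "C"),
                                    c("A", "C", "C", "C")), 0L)
  # 3-state x 2-state, 4 joint states in one component: 4 - 5 + 1 = 0
  expect_equal(pair_incompatibility(c("A", "A", "C", "C", "G", "G"),
                                    c("A", "C", "C", "C", "A", "A")), 0L)
})

test_that("PHI statistic is the windowed mean incompatibility", {
  # all pairs compatible -> 0; nested splits on 8 sequences
  cols <- list(rep(c("A", "C"), each = 4), c("A", "A", "C", "C", "C", "C", "C", "C"))
  aln <- aln_from_cols(cols)
  expect_equal(phi_test(aln, n_perm = 19)$stat, 0)

  # hand mean over scores {0, 1, 0}
  sites <- structure(list(positions = c(1L, 2L, 3L), k = 3L), class = "informative_sites")
  M <- matrix(c(0, 0, 1, 0, 0, 0, 1, 0, 0), 3)
  expect_equal(phi_statistic(sites, window = 100, M = M)$stat, 1 / 3)

  # all pairs incompatible -> 1
  M1 <- 1 - diag(3)
  expect_equal(phi_statistic(sites, window = 100, M = M1)$stat, 1)
})

test_that("permutation p-values obey the add-one rule", {
  expect_equal(permutation_pvalue(0.1, rep(0.5, 19), "lower"), 1 / 20)
  expect_equal(permutation_pvalue(0.5, rep(0.5, 19), "lower"), 1)
  expect_equal(permutation_pvalue(5, rep(1, 99), "upper"), 1 / 100)

  # degenerate alignment: statistic invariant under permutation -> p = 1
  cols <- list(rep(c("A", "C"), each = 4), rep(c("A", "C"), each = 4))
  expect_equal(phi_test(aln_from_cols(cols), n_perm = 49)$p, 1)
})

test_that("PHI Monte-Carlo p matches exhaustive permutation enumeration", {
  # two 3-site blocks from conflicting topologies, far apart (window 100)
  X <- rep(c("A", "C"), each = 4)          # split 1234 | 5678
  Y <- rep(c("A", "A", "C", "C"), 2)       # split 1256 | 3478
  aln <- aln_from_cols(list(X, X, X, Y, Y, Y),
                       positions = c(1, 30, 60, 500, 530, 560),
                       total_len = 600)
  si <- informative_sites(aln)
  expect_equal(si$k, 6L)

  # exhaustive oracle over all 6! site-to-position assignments
  M <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6)
    M[i, j] <- M[j, i] <- pair_incompatibility(si$mat[, i], si$mat[, j])
  pos <- si$positions
  pairs <- which(abs(outer(pos, pos, "-")) <= 100 & upper.tri(M), arr.ind = TRUE)
  perms <- gtools_permutations <- NULL
  allp <- as.matrix(expand.grid(rep(list(1:6), 6)))
  allp <- allp[apply(allp, 1, function(x) length(unique(x)) == 6), ]
  stats_all <- apply(allp, 1, function(p)
    mean(M[cbind(p[pairs[, 1]], p[pairs[, 2]])]))
  obs <- mean(M[pairs])
  p_exact <- mean(stats_all <= obs + 1e-12)
  expect_equal(obs, 0)
  expect_lt(p_exact, 0.2)  # clustering signal exists in this construction

  p_mc <- phi_test(aln, n_perm = 999, seed = 42)$p
  expect_lt(abs(p_mc - p_exact), 0.02)
})

test_that("MaxChi reproduces the hand 2x2 chi-square and degenerate cases", {
  a <- paste(rep(c("C", "A"), c(10, 10)), collapse = "")
  b <- strrep("A", 20)
  r <- maxchi_test(c(x = a, y = b), n_perm = 19, seed = 1)
  expect_equal(r$stat, 20)  # complete association, n * 1

  ident <- c(x = "ACGTACGT", y = "ACGTACGT")
  r0 <- maxchi_test(ident, n_perm = 19)
  expect_equal(r0$stat, 0)
  expect_false(r0$testable)
})

test_that("MaxChi null p-values are close to uniform", {
  tr <- simulate_species_tree(2, 4, 0.01, 0.05, seed = 8)
  ps <- vapply(1:60, function(i) {
    aln <- evolve_family(tr, rand_dna(400, seed = 600 + i), 1, seed = 700 + i)
    maxchi_test(aln, n_perm = 60, seed = 800 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("NSS matches hand values and flags clustered incompatibility", {
  B0 <- matrix(FALSE, 4, 4)
  expect_equal(nss_statistic(B0), 1)              # identical rows
  Bc <- outer(1:4, 1:4, function(i, j) (i + j) %% 2 == 1)
  expect_equal(nss_statistic(Bc), 0)              # checkerboard rows
  B3 <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, 1, 1))
  expect_equal(nss_statistic(B3), (1 + 2 / 3) / 2)

  cols <- list(rep(c("A", "C"), each = 4), rep(c("A", "C"), each = 4))
  expect_equal(nss_test(aln_from_cols(cols), n_perm = 19)$testable, FALSE)
})

test_that("screen_genes partitions the SCC and respects alpha", {
  tr <- simulate_species_tree(2, 4, 0.01, 0.05, seed = 4)
  alns <- lapply(1:6, function(i)
    evolve_family(tr, rand_dna(900, seed = 90 + i), 1, seed = 190 + i))
  names(alns) <- sprintf("g%02d", 1:6)
  # mosaic in two genes: left half from a cross-clade donor
  for (g in c("g01", "g02")) {
    substr(alns[[g]][["s02_01"]], 1, 450) <- substr(alns[[g]][["s01_01"]], 1, 450)
  }
  rep <- screen_genes(alns, alpha = 0.01, n_perm = 199, seed = 5,
                      tests = "phi")
  expect_setequal(c(rep$recombinant_set, rep$minimum_core_set), names(alns))
  expect_length(intersect(rep$recombinant_set, rep$minimum_core_set), 0L)
  expect_true(all(c("g01", "g02") %in% rep$recombinant_set))
  expect_equal(rep$summary$n_recombinant + rep$summary$n_minimum_core, 6L)

  rep0 <- screen_genes(alns, alpha = 0, n_perm = 49, seed = 5, tests = "phi")
  expect_length(rep0$recombinant_set, 0L)

  # untestable gene (identical sequences) lands in the minimum core, flagged
  alns$flat <- stats::setNames(rep(strrep("ACGT", 50), 8), names(alns[[1]]))
  rep2 <- screen_genes(alns["flat"], n_perm = 49, tests = "phi")
  expect_false(rep2$results$testable[1])
  expect_identical(rep2$minimum_core_set, "flat")
})

test_that("PHI is calibrated on recombination-free genes", {
  tr <- simulate_species_tree(2, 4, 0.01, 0.05, seed = 21)
  ps <- vapply(1:60, function(i) {
    aln <- evolve_family(tr, rand_dna(900, seed = 2000 + i), 1, seed = 3000 + i)
    phi_test(aln, n_perm = 199, seed = 4000 + i)$p
  }, numeric(1))
  expect_lte(mean(ps < 0.01), 0.05)
})

test_that("PHI has power against partial-tract cross-clade transfer", {
  # tract 0.5: an intragenic mosaic, the regime PHI is designed to detect
  # (whole-allele replacement is tree-compatible and invisible to PHI; see
  # the acceptance suite and the methods vignette)
  tr <- simulate_species_tree(2, 4, 0.01, 0.05, seed = 22)
  ps <- vapply(1:30, function(i) {
    aln <- evolve_family(tr, rand_dna(900, seed = 5000 + i), 1, seed = 6000 + i)
    substr(aln[["s02_01"]], 1, 450) <- substr(aln[["s01_01"]], 1, 450)
    phi_test(aln, n_perm = 199, seed = 7000 + i)$p
  }, numeric(1))
  expect_gte(mean(ps < 0.01), 0.7)
})
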
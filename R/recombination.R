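# Recombination screening: the pairwise homoplasy index (PHI), MaxChi and the
# neighbor similarity score (NSS), each with a site-permutation p-value, and
# the partition of single-copy-core genes into "evidence of recombination"
# vs the minimum core.

#' Parsimony-informative sites of an alignment
#'
#' Columns containing gaps or `N` are removed; a column is informative when at
#' least two states are each carried by at least two sequences. Original
#' column indices are retained so window-based statistics can use physical
#' distances.
#'
#' @param aln named character vector of equal-length sequences (>= 4).
#' @return list of class `informative_sites`: `positions` (original 1-based
#'   indices), `mat` (sequences x informative columns, character),
#'   `n_seq`, `k` (number of informative sites).
#' @export
informative_sites <- function(aln) {
  if (length(aln) < 4) stop("need >= 4 sequences for recombination tests")
  m <- aln_char_matrix(aln)
  clean <- colSums(!(m == "A" | m == "C" | m == "G" | m == "T")) == 0
  m <- m[, clean, drop = FALSE]
  pos_clean <- which(clean)
  inf <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    tab <- tabulate(.base_lut[utf8ToInt(paste(m[, j], collapse = ""))], 4L)
    inf[j] <- sum(tab >= 2) >= 2
  }
  structure(list(positions = pos_clean[inf],
                 mat = m[, inf, drop = FALSE],
                 n_seq = length(aln), k = sum(inf)),
            class = "informative_sites")
}

#' Refined incompatibility score of a site pair
#'
#' Vertices are the observed states at each site, edges the distinct observed
#' joint states; the score is the cyclomatic number `E - V + C` of that
#' bipartite graph. Zero means the pair is compatible with a single tree
#' (multi-state generalisation of the four-gamete test).
#'
#' @param site_i,site_j character vectors (one state per sequence).
#' @return non-negative integer score.
#' @export
pair_incompatibility <- function(site_i, site_j) {
  si <- unique(site_i); sj <- unique(site_j)
  joint <- unique(paste(site_i, site_j))
  V <- length(si) + length(sj)
  E <- length(joint)
  a <- match(sub(" .*", "", joint), si)
  b <- match(sub(".* ", "", joint), sj) + length(si)
  comp <- uf_components(V, a, b)
  C <- length(unique(comp))
  E - V + C
}

# k x k incompatibility matrix over informative sites
incompat_matrix <- function(sites) {
  k <- sites$k
  M <- matrix(0L, k, k)
  if (k < 2) return(M)
  cols <- lapply(seq_len(k), function(j) sites$mat[, j])
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    M[i, j] <- M[j, i] <- pair_incompatibility(cols[[i]], cols[[j]])
  }
  M
}

#' PHI statistic
#'
#' Mean refined incompatibility over informative-site pairs whose original
#' alignment positions are at most `window` nt apart (PhiPack's default
#' w = 100). Recombination makes nearby pairs unusually compatible, so small
#' values are evidence for recombination (lower-tail permutation test).
#'
#' @param sites an `informative_sites` object.
#' @param window window width in alignment positions.
#' @param M optional precomputed incompatibility matrix.
#' @return list `stat` (NA when undefined), `testable`.
#' @export
phi_statistic <- function(sites, window = 100L, M = NULL) {
  if (sites$k < 2) return(list(stat = NA_real_, testable = FALSE))
  if (is.null(M)) M <- incompat_matrix(sites)
  pr <- .window_pairs(sites$positions, window)
  if (!nrow(pr)) return(list(stat = NA_real_, testable = FALSE))
  list(stat = mean(M[pr]), testable = TRUE)
}

# index pairs (slots i<j) whose positions lie within the window
.window_pairs <- function(positions, window) {
  k <- length(positions)
  d <- abs(outer(positions, positions, "-"))
  which(d <= window & upper.tri(d), arr.ind = TRUE)
}

#' Generic site-permutation p-value
#'
#' Permutes the assignment of informative sites to alignment positions
#' (the genealogy-free null of PhiPack) and applies the add-one rule
#' `p = (1 + #{extreme}) / (n_perm + 1)`, so the smallest attainable p-value
#' is `1/(n_perm+1)`.
#'
#' @param observed observed statistic.
#' @param perm_stats vector of permuted statistics.
#' @param tail `"lower"` (PHI) or `"upper"` (MaxChi, NSS).
#' @return p-value in `[1/(n_perm+1), 1]`.
#' @export
permutation_pvalue <- function(observed, perm_stats, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  eps <- 1e-12
  hits <- if (tail == "lower") sum(perm_stats <= observed + eps)
          else sum(perm_stats >= observed - eps)
  (1 + hits) / (length(perm_stats) + 1)
}

#' PHI permutation test
#'
#' @param aln alignment (named character vector) or `informative_sites`.
#' @param window PHI window (nt, original positions).
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return list `stat, p, testable`.
#' @export
phi_test <- function(aln, window = 100L, n_perm = 1000L, seed = 1L) {
  sites <- if (inherits(aln, "informative_sites")) aln else informative_sites(aln)
  M <- incompat_matrix(sites)
  obs <- phi_statistic(sites, window, M)
  if (!obs$testable) return(list(stat = NA_real_, p = 1.0, testable = FALSE))
  pr <- .window_pairs(sites$positions, window)
  ia <- pr[, 1]; jb <- pr[, 2]
  k <- sites$k
  perm <- numeric(n_perm)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      pi <- sample.int(k)
      perm[r] <- mean(M[cbind(pi[ia], pi[jb])])
    }
  })
  list(stat = obs$stat,
       p = permutation_pvalue(obs$stat, perm, "lower"),
       testable = TRUE)
}

# ---- MaxChi -----------------------------------------------------------------

# gap-free columns; MaxChi scans all of them (match columns carry signal in
# the 2x2 table), with breakpoints restricted to polymorphic columns
.gapfree_sites <- function(aln) {
  m <- aln_char_matrix(aln)
  clean <- colSums(!(m == "A" | m == "C" | m == "G" | m == "T")) == 0
  m <- m[, clean, drop = FALSE]
  varc <- apply(m, 2, function(x) length(unique(x)) > 1)
  list(mat = m, positions = which(clean), variable = varc)
}

# max 2x2 chi-square over sequence pairs and breakpoints, given the 0/1
# mismatch matrix D (pairs x sites, in scan order) and half-window w;
# `bps` are the candidate breakpoints (after-column indices). Everything is
# done in double precision (integer chi-square numerators overflow).
.maxchi_stat <- function(D, w, bps = seq_len(ncol(D) - 1L)) {
  k <- ncol(D)
  if (k < 2 || !length(bps)) return(0)
  cums <- if (nrow(D) == 1) matrix(cumsum(as.numeric(D[1, ])), 1)
          else t(apply(D * 1.0, 1, cumsum))
  CL <- cbind(0, cums)                       # prefix sums, 1-based shift
  lo <- pmax(0L, bps - w); hi <- pmin(k, bps + w)
  lm <- cums[, bps, drop = FALSE] - CL[, lo + 1L, drop = FALSE]
  rm_ <- CL[, hi + 1L, drop = FALSE] - cums[, bps, drop = FALSE]
  lt <- matrix(bps - lo, nrow(D), length(bps), byrow = TRUE)
  rt <- matrix(hi - bps, nrow(D), length(bps), byrow = TRUE)
  a <- lm; bb <- lt - lm; cc <- rm_; d <- rt - rm_
  n <- lt + rt
  den <- (a + bb) * (cc + d) * (a + cc) * (bb + d)
  chi <- n * (a * d - bb * cc)^2
  chi <- chi / pmax(den, 1)
  chi[den <= 0] <- 0
  max(chi)
}

#' MaxChi permutation test
#'
#' For every sequence pair, match/mismatch counts left and right of a
#' candidate breakpoint are contrasted in a 2x2 chi-square within a centered
#' window of `2*ceiling(window_fraction*k)` gap-free sites (`k` = number of
#' gap-free columns); the statistic is the maximum over pairs and
#' breakpoints. All gap-free columns enter the table (a perfectly matching
#' column is informative for this test even when it is not polymorphic);
#' breakpoints are placed after each polymorphic column. Columns are permuted
#' for the upper-tail p-value. Identical sequences yield statistic 0 and are
#' reported untestable.
#'
#' @param aln alignment (named character vector, >= 2 sequences).
#' @param window_fraction half-window as a fraction of gap-free sites
#'   (default 2/3).
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return list `stat, p, testable`.
#' @export
maxchi_test <- function(aln, window_fraction = 2 / 3, n_perm = 1000L, seed = 1L) {
  if (length(aln) < 2) stop("need >= 2 sequences")
  vs <- .gapfree_sites(aln)
  k <- ncol(vs$mat)
  if (k < 2 || !any(vs$variable))
    return(list(stat = 0, p = 1.0, testable = FALSE))
  n <- nrow(vs$mat)
  pairs <- utils::combn(n, 2)
  D <- matrix(0L, ncol(pairs), k)
  for (e in seq_len(ncol(pairs)))
    D[e, ] <- as.integer(vs$mat[pairs[1, e], ] != vs$mat[pairs[2, e], ])
  w <- as.integer(ceiling(window_fraction * k))
  bps <- which(vs$variable)
  bps <- bps[bps < k]
  obs <- .maxchi_stat(D, w, bps)
  perm <- numeric(n_perm)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ord <- sample.int(k)
      Dp <- D[, ord, drop = FALSE]
      bp_p <- which(vs$variable[ord])
      bp_p <- bp_p[bp_p < k]
      perm[r] <- .maxchi_stat(Dp, w, bp_p)
    }
  })
  list(stat = obs, p = permutation_pvalue(obs, perm, "upper"), testable = TRUE)
}

# ---- NSS --------------------------------------------------------------------

#' Neighbor similarity score of a binary incompatibility matrix
#'
#' Mean, over adjacent site pairs `(i, i+1)` in the given ordering, of the
#' fraction of matching entries between rows `i` and `i+1` (all `k` entries
#' compared). 1 for an all-compatible matrix, 0 for perfectly alternating
#' rows.
#'
#' @param B square binary (logical or 0/1) incompatibility matrix.
#' @param ord site ordering (default: as given).
#' @return NSS in `[0, 1]`.
#' @export
nss_statistic <- function(B, ord = seq_len(nrow(B))) {
  Bo <- B[ord, ord, drop = FALSE]
  k <- nrow(Bo)
  mean(vapply(seq_len(k - 1), function(i) mean(Bo[i, ] == Bo[i + 1, ]),
              numeric(1)))
}
.nss_stat <- function(B, ord) nss_statistic(B, ord)

#' Neighbor similarity score permutation test
#'
#' From the binary incompatibility matrix over informative sites, NSS is the
#' mean, over adjacent site pairs, of the fraction of matching entries
#' between their rows. Recombination clusters compatibility along the
#' sequence, inflating NSS (upper-tail permutation test).
#'
#' @param aln alignment or `informative_sites` (>= 3 informative sites).
#' @param n_perm permutation count.
#' @param seed RNG seed.
#' @return list `stat, p, testable`.
#' @export
nss_test <- function(aln, n_perm = 1000L, seed = 1L) {
  sites <- if (inherits(aln, "informative_sites")) aln else informative_sites(aln)
  if (sites$k < 3) return(list(stat = NA_real_, p = 1.0, testable = FALSE))
  B <- incompat_matrix(sites) > 0
  k <- sites$k
  obs <- .nss_stat(B, seq_len(k))
  perm <- numeric(n_perm)
  with_seed(seed, {
    for (r in seq_len(n_perm)) perm[r] <- .nss_stat(B, sample.int(k))
  })
  list(stat = obs, p = permutation_pvalue(obs, perm, "upper"), testable = TRUE)
}

# ---- screening --------------------------------------------------------------

#' Screen single-copy-core genes for recombination
#'
#' Runs the requested tests per gene and partitions the gene set into a
#' recombinant set and the minimum core. The decision rule defaults to PHI
#' alone (`p < alpha`); `"any"`/`"all"` combine the computed tests.
#' Untestable genes (fewer than 2 informative sites) are assigned to the
#' minimum core and flagged.
#'
#' @param alignments named list of per-gene alignments.
#' @param alpha significance level (default 0.01).
#' @param n_perm permutations per test.
#' @param seed master seed (per-gene seeds are derived from it).
#' @param decision `"phi"`, `"any"` or `"all"`.
#' @param tests subset of `c("phi", "maxchi", "nss")` to compute.
#' @param phi_window PHI window in nt.
#' @return object of class `recomb_report`: `results` data frame,
#'   `recombinant_set`, `minimum_core_set`, `summary`.
#' @export
screen_genes <- function(alignments, alpha = 0.01, n_perm = 1000L, seed = 1L,
                         decision = c("phi", "any", "all"),
                         tests = c("phi", "maxchi", "nss"),
                         phi_window = 100L) {
  decision <- match.arg(decision)
  tests <- match.arg(tests, several.ok = TRUE)
  genes <- sort(names(alignments))
  if (!length(genes)) stop("no alignments given")
  seeds <- with_seed(seed, draw_seeds(3L * length(genes)))
  rows <- vector("list", length(genes))
  for (gidx in seq_along(genes)) {
    g <- genes[gidx]
    aln <- alignments[[g]]
    sites <- informative_sites(aln)
    s3 <- seeds[(3L * (gidx - 1L) + 1L):(3L * gidx)]
    phi <- if ("phi" %in% tests) phi_test(sites, phi_window, n_perm, s3[1])
           else list(stat = NA_real_, p = NA_real_, testable = NA)
    mx <- if ("maxchi" %in% tests) maxchi_test(aln, 2 / 3, n_perm, s3[2])
          else list(stat = NA_real_, p = NA_real_)
    ns <- if ("nss" %in% tests) nss_test(sites, n_perm, s3[3])
          else list(stat = NA_real_, p = NA_real_)
    testable <- isTRUE(phi$testable)
    ps <- switch(decision,
                 phi = phi$p,
                 any = suppressWarnings(min(c(phi$p, mx$p, ns$p), na.rm = TRUE)),
                 all = suppressWarnings(max(c(phi$p, mx$p, ns$p), na.rm = TRUE)))
    recomb <- testable && is.finite(ps) && ps < alpha
    rows[[gidx]] <- data.frame(gene_id = g,
                               phi_stat = phi$stat, phi_p = phi$p,
                               maxchi_stat = mx$stat, maxchi_p = mx$p,
                               nss_stat = ns$stat, nss_p = ns$p,
                               testable = testable, recombinant = recomb,
                               stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  recombinant_set <- results$gene_id[results$recombinant]
  minimum_core_set <- setdiff(genes, recombinant_set)
  stopifnot(length(intersect(recombinant_set, minimum_core_set)) == 0,
            setequal(union(recombinant_set, minimum_core_set), genes))
  structure(list(results = results,
                 recombinant_set = recombinant_set,
                 minimum_core_set = minimum_core_set,
                 summary = list(n_scc = length(genes),
                                n_recombinant = length(recombinant_set),
                                n_minimum_core = length(minimum_core_set),
                                pct_recombinant = pct1(length(recombinant_set),
                                                       length(genes)),
                                n_untestable = sum(!results$testable,
                                                   na.rm = TRUE))),
            class = "recomb_report")
}
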
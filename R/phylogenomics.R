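# Distance-based tree inference (JC69 + neighbor joining) with bootstrap,
# midpoint rooting, bipartition machinery, and gene-tree/species congruence
# scoring. The inference engine is deliberately engine-agnostic downstream:
# externally computed Newick trees can be fed to every congruence operation.

#' Jukes-Cantor distances from an alignment
#'
#' Pairwise deletion of gap/N columns; `p` = mismatch fraction over shared
#' comparable sites, `d = -3/4 log(1 - 4p/3)`. Saturated pairs
#' (`p >= 0.75`) are capped at `d = 5` with a warning.
#'
#' @param aln named character vector of equal-length sequences.
#' @param strip_gap_cols drop columns containing any gap/N first (a crude
#'   quality-trim analog; default FALSE, i.e. pairwise deletion only).
#' @return symmetric distance matrix with zero diagonal.
#' @export
jc69_distances <- function(aln, strip_gap_cols = FALSE) {
  m <- aln_int_matrix(aln)
  if (strip_gap_cols) m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  saturated <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    nc <- sum(ok)
    if (nc == 0) stop("no comparable sites between ", rownames(m)[i], " and ",
                      rownames(m)[j])
    p <- sum(m[i, ok] != m[j, ok]) / nc
    if (p >= 0.75) { d[i, j] <- d[j, i] <- 5.0; saturated <- TRUE }
    else d[i, j] <- d[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  if (saturated) warning("saturated pair(s): distance capped at 5.0")
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the Q-criterion. Ties are broken toward the
#' lexicographically smallest label pair (a node is labelled by its smallest
#' descendant leaf), so the result is invariant to input order. Negative
#' branch lengths are clamped to zero with the excess moved to the sister
#' branch (their sum is preserved). On additive matrices the generating tree
#' is recovered exactly.
#'
#' @param dm symmetric distance matrix with labels.
#' @return unrooted `phylo` (trifurcating root); for 2 taxa a degenerate
#'   2-leaf tree with attribute `degenerate = TRUE`.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), !is.null(rownames(dm)))
  labels <- rownames(dm)
  n <- length(labels)
  if (n < 2) stop("need >= 2 taxa")
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);", labels[1],
                                        dm[1, 2] / 2, labels[2], dm[1, 2] / 2))
    attr(tr, "degenerate") <- TRUE
    return(tr)
  }
  frag <- labels                 # newick fragment per active node
  minlab <- labels               # smallest descendant label (tie-breaking)
  D <- dm
  active <- seq_len(n)
  while (length(active) > 3) {
    m <- length(active)
    Da <- D[active, active]
    r <- rowSums(Da)
    Q <- (m - 2) * Da - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(ix) {
        ml <- sort(c(minlab[active[ix[1]]], minlab[active[ix[2]]]))
        paste(ml, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    ai <- active[i]; aj <- active[j]
    dij <- Da[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_id <- length(frag) + 1L
    frag[new_id] <- sprintf("(%s:%.10g,%s:%.10g)", frag[ai], li, frag[aj], lj)
    minlab[new_id] <- min(minlab[ai], minlab[aj])
    newd <- (D[ai, active] + D[aj, active] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    D[new_id, active] <- newd
    D[active, new_id] <- newd
    D[new_id, new_id] <- 0
    active <- c(active[-c(i, j)], new_id)
  }
  a <- active[1]; b <- active[2]; c_ <- active[3]
  la <- max((D[a, b] + D[a, c_] - D[b, c_]) / 2, 0)
  lb <- max((D[a, b] + D[b, c_] - D[a, c_]) / 2, 0)
  lc <- max((D[a, c_] + D[b, c_] - D[a, b]) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[a], la, frag[b], lb, frag[c_], lc)
  ape::read.tree(text = nwk)
}

#' Midpoint rooting
#'
#' Roots at the midpoint of the longest leaf-to-leaf path. Trees whose total
#' path lengths are all zero are rooted at the first internal node and
#' flagged. The 2-leaf case is handled directly; larger trees delegate the
#' edge surgery to \pkg{phangorn}.
#'
#' @param tree unrooted `phylo` with branch lengths.
#' @return rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n == 2) {
    tot <- sum(tree$edge.length)
    labs <- sort(tree$tip.label)
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         labs[1], tot / 2, labs[2], tot / 2)))
  }
  if (is.null(tree$edge.length) || sum(tree$edge.length) == 0) {
    rooted <- ape::root(tree, node = n + 1L, resolve.root = TRUE)
    attr(rooted, "zero_length") <- TRUE
    return(rooted)
  }
  phangorn::midpoint(tree, node.labels = "support")
}

# ---- bipartitions -----------------------------------------------------------

#' Non-trivial bipartitions (splits) of a tree
#'
#' Each internal edge induces a split of the leaf set; splits are canonicalised
#' as the sorted side not containing the alphabetically first leaf, joined by
#' `|`. Topology-only: branch lengths and supports are ignored.
#'
#' @param tree a `phylo`.
#' @return character vector of canonical split keys (possibly empty).
#' @export
tree_splits <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  ref <- sort(tips)[1]
  pp <- ape::prop.part(ape::unroot(tree))
  out <- character(0)
  for (p in pp) {
    side <- tips[p]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance (topology only)
#'
#' Size of the symmetric difference of the two trees' non-trivial split sets;
#' 0 iff the split sets are equal; at most `2(n-3)` for binary trees.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# leaf sets descending from each internal edge (child side), as a list
.edge_tipsets <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  post <- stats::reorder(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tips[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) desc[[tree$edge[e, 2]]])
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the JC69+NJ tree,
#' and labels each internal edge of the full-data tree with the percentage of
#' replicates containing the same bipartition.
#'
#' @param aln alignment (named character vector).
#' @param n_boot replicates (default 100).
#' @param seed RNG seed.
#' @return midpoint-unrooted `phylo` with `node.label` supports (0-100).
#' @export
bootstrap_support <- function(aln, n_boot = 100L, seed = 1L) {
  stopifnot(n_boot >= 1)
  m <- aln_char_matrix(aln)
  L <- ncol(m)
  base_tree <- nj_tree(jc69_distances(aln))
  base_splits <- tree_splits(base_tree)
  tally <- stats::setNames(numeric(length(base_splits)), base_splits)
  with_seed(seed, {
    for (r in seq_len(n_boot)) {
      idx <- sample.int(L, L, replace = TRUE)
      res <- m[, idx, drop = FALSE]
      aln_r <- stats::setNames(apply(res, 1, paste, collapse = ""), rownames(m))
      spl <- tree_splits(nj_tree(jc69_distances(aln_r)))
      hit <- base_splits %in% spl
      tally[hit] <- tally[hit] + 1
    }
  })
  support <- round(100 * tally / n_boot)
  # map supports onto internal nodes of the (rooted representation of the) tree
  tips <- base_tree$tip.label
  ref <- sort(tips)[1]
  ntip <- length(tips)
  labels <- rep("", base_tree$Nnode)
  sets <- .edge_tipsets(base_tree)
  for (e in seq_len(nrow(base_tree$edge))) {
    ch <- base_tree$edge[e, 2]
    if (ch <= ntip) next
    side <- sets[[e]]
    if (ref %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      labels[ch - ntip] <- as.character(support[[key]])
  }
  base_tree$node.label <- labels
  base_tree
}

#' Concatenate per-gene alignments
#'
#' Column-wise concatenation in sorted gene-id order; all genes must cover the
#' identical strain set. A `partition_map` attribute records each gene's
#' 0-based half-open column range.
#'
#' @param alignments named list of alignments.
#' @param gene_subset optional gene ids to include.
#' @return concatenated alignment (named character vector).
#' @export
concatenate_alignments <- function(alignments, gene_subset = NULL) {
  genes <- sort(if (is.null(gene_subset)) names(alignments) else gene_subset)
  if (!length(genes)) stop("empty gene subset")
  missing_genes <- setdiff(genes, names(alignments))
  if (length(missing_genes))
    stop("unknown genes: ", paste(missing_genes, collapse = ", "))
  strains <- sort(names(alignments[[genes[1]]]))
  for (g in genes) {
    miss <- setdiff(strains, names(alignments[[g]]))
    extra <- setdiff(names(alignments[[g]]), strains)
    if (length(miss) || length(extra))
      stop("strain-set mismatch at ", g, ": missing [",
           paste(miss, collapse = ","), "] extra [",
           paste(extra, collapse = ","), "]")
  }
  parts <- lapply(genes, function(g) alignments[[g]][strains])
  out <- do.call(paste0, parts)
  names(out) <- strains
  lens <- vapply(genes, function(g) nchar(alignments[[g]][[1]]), numeric(1))
  ends <- cumsum(lens)
  attr(out, "partition_map") <- data.frame(gene = genes,
                                           start = c(0, utils::head(ends, -1)),
                                           end = ends)
  out
}

#' Species-level monophyly of a tree
#'
#' A species is monophyletic iff its leaf set forms a bipartition of the
#' unrooted tree (singleton species by convention). Offending strains are the
#' extraneous leaves inside the smallest edge-side containing the species.
#'
#' @param tree a `phylo`.
#' @param assignment named character vector strain -> species.
#' @return list of class `congruence_result`: `monophyly` (named logical),
#'   `incongruent` flag, `offending_strains` (named list).
#' @export
species_monophyly <- function(tree, assignment) {
  tips <- tree$tip.label
  un <- setdiff(tips, names(assignment))
  if (length(un)) stop("unassigned strains: ", paste(un, collapse = ", "))
  assignment <- assignment[tips]
  species <- sort(unique(assignment))
  sets <- .edge_tipsets(tree)
  sides <- c(sets, lapply(sets, function(s) setdiff(tips, s)),
             list(tips))  # whole leaf set: a one-species tree is congruent
  mono <- stats::setNames(logical(length(species)), species)
  offend <- stats::setNames(vector("list", length(species)), species)
  for (sp in species) {
    leaves <- tips[assignment == sp]
    if (length(leaves) <= 1) { mono[sp] <- TRUE; offend[[sp]] <- character(0); next }
    hit <- any(vapply(sides, function(s) setequal(s, leaves), logical(1)))
    mono[sp] <- hit
    if (hit) { offend[[sp]] <- character(0); next }
    containing <- sides[vapply(sides, function(s) all(leaves %in% s), logical(1))]
    sizes <- lengths(containing)
    best <- containing[[which.min(sizes)]]
    offend[[sp]] <- sort(setdiff(best, leaves))
  }
  structure(list(monophyly = mono, incongruent = any(!mono),
                 offending_strains = offend),
            class = "congruence_result")
}

#' Compare the SCC / recombinant / minimum-core concatenated trees
#'
#' Per-tree species monophyly plus pairwise Robinson-Foulds distances;
#' species-level congruent iff every species is monophyletic in all trees.
#'
#' @param trees named list of `phylo` objects on the same strains.
#' @param assignment strain -> species.
#' @return list: `monophyly` (matrix species x trees), `rf` (matrix),
#'   `species_level_congruent` flag.
#' @export
partition_tree_comparison <- function(trees, assignment) {
  stopifnot(length(trees) >= 2, !is.null(names(trees)))
  base <- sort(trees[[1]]$tip.label)
  for (t in trees) if (!setequal(t$tip.label, base))
    stop("trees have different leaf sets")
  cong <- lapply(trees, species_monophyly, assignment = assignment)
  mono <- do.call(cbind, lapply(cong, `[[`, "monophyly"))
  colnames(mono) <- names(trees)
  k <- length(trees)
  rf <- matrix(0L, k, k, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]])
  list(monophyly = mono, rf = rf,
       species_level_congruent = all(mono))
}
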
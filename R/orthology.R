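# Orthologous-group inference: all-vs-all nucleotide similarity (seed-and-
# extend replacement for translated BLAST), Markov clustering at a fixed
# inflation, paralog-aware core extraction.

# k-mer keys of a sequence at a stride
.kmers_at <- function(s, k, stride) {
  L <- nchar(s)
  if (L < k) return(character(0))
  starts <- unique(c(seq(1L, L - k + 1L, by = stride), L - k + 1L))
  substring(s, starts, starts + k - 1L)
}

# identity/coverage of one gene pair; equal-length genes (the simulator's
# indel-free regime) compare column-wise, unequal lengths align at the
# majority seed diagonal and score the overlap only
.pair_identity <- function(ia, ib, sa, sb, k = 16L) {
  if (length(ia) == length(ib)) {
    comp <- length(ia)
    matches <- sum(ia == ib, na.rm = TRUE)
    overlap <- comp
  } else {
    qk <- .kmers_at(sa, k, 4L)
    starts <- unique(c(seq(1L, nchar(sa) - k + 1L, by = 4L), nchar(sa) - k + 1L))
    bk <- substring(sb, seq_len(nchar(sb) - k + 1L),
                    seq_len(nchar(sb) - k + 1L) + k - 1L)
    m <- match(qk, bk)
    keep <- !is.na(m)
    if (!any(keep)) return(c(identity = 0, coverage = 0))
    offs <- m[keep] - starts[keep]
    off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
    a_from <- max(1L, 1L - off); a_to <- min(length(ia), length(ib) - off)
    if (a_to <= a_from) return(c(identity = 0, coverage = 0))
    va <- ia[a_from:a_to]; vb <- ib[(a_from + off):(a_to + off)]
    overlap <- length(va)
    matches <- sum(va == vb, na.rm = TRUE)
  }
  c(identity = 100 * matches / overlap,
    coverage = overlap / min(length(ia), length(ib)))
}

#' All-vs-all gene similarity search
#'
#' Candidate pairs are genes sharing at least one exact 16-mer; each candidate
#' pair is scored by percent identity over aligned columns (offset from the
#' majority seed diagonal when lengths differ) and coverage of the shorter
#' gene. Hits below `cutoff` percent identity or `min_coverage` are dropped;
#' surviving hits are emitted in both directions, self-hits never.
#'
#' @param gene_seqs named character vector, gene id -> sequence.
#' @param cutoff percent-identity cutoff (default 70).
#' @param min_coverage minimum aligned fraction of the shorter gene.
#' @param k seed k-mer length.
#' @return data frame `query, subject, identity, coverage, score`.
#' @export
all_vs_all_similarity <- function(gene_seqs, cutoff = 70, min_coverage = 0.5,
                                  k = 16L) {
  if (length(gene_seqs) < 2) stop("need >= 2 genes")
  if (any(!nzchar(gene_seqs))) stop("empty gene sequence")
  ids <- names(gene_seqs)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  ints <- lapply(gene_seqs, seq_to_int)

  km <- lapply(gene_seqs, .kmers_at, k = k, stride = 8L)
  buckets <- split(rep(seq_along(gene_seqs), lengths(km)),
                   unlist(km, use.names = FALSE))
  buckets <- buckets[lengths(buckets) >= 2]
  pair_mats <- lapply(buckets, function(b) {
    g <- sort(unique(b))
    if (length(g) < 2) NULL else utils::combn(g, 2)
  })
  pair_mats <- pair_mats[!vapply(pair_mats, is.null, logical(1))]
  if (length(pair_mats)) {
    cmb <- do.call(cbind, pair_mats)
    key <- cmb[1, ] * (length(gene_seqs) + 1) + cmb[2, ]
    cmb <- cmb[, !duplicated(key), drop = FALSE]
    pair_i <- cmb[1, ]; pair_j <- cmb[2, ]
  } else {
    pair_i <- integer(0); pair_j <- integer(0)
  }
  if (!length(pair_i))
    return(data.frame(query = character(0), subject = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      score = numeric(0)))
  res <- vapply(seq_along(pair_i), function(e)
    .pair_identity(ints[[pair_i[e]]], ints[[pair_j[e]]],
                   gene_seqs[[pair_i[e]]], gene_seqs[[pair_j[e]]], k),
    numeric(2))
  keep <- res["identity", ] >= cutoff & res["coverage", ] >= min_coverage
  qi <- pair_i[keep]; sj <- pair_j[keep]
  data.frame(query = c(ids[qi], ids[sj]), subject = c(ids[sj], ids[qi]),
             identity = rep(res["identity", keep], 2),
             coverage = rep(res["coverage", keep], 2),
             score = rep(res["identity", keep], 2),
             stringsAsFactors = FALSE)
}

# dense MCL on one connected component's weight matrix; returns cluster
# membership (integer vector). Self-loops get the component's maximum weight;
# expansion = matrix square, inflation = elementwise power + column renorm;
# entries < 1e-9 pruned; converged when successive iterates differ < 1e-6.
.mcl_component <- function(W, inflation, max_iter = 100L, prune = 1e-9,
                           conv = 1e-6, extract_tol = 1e-6) {
  n <- nrow(W)
  if (n == 1) return(1L)
  diag(W) <- max(W)
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < conv) break
  }
  A <- (M > extract_tol) | (t(M) > extract_tol)
  edges <- which(A & upper.tri(A), arr.ind = TRUE)
  uf_components(n, edges[, 1], edges[, 2])
}

#' Markov clustering of similarity hits into orthologous groups
#'
#' Standard MCL run independently on each connected component of the hit
#' graph: scores become a column-stochastic matrix (self-loops at the
#' component maximum), then expansion (matrix square) alternates with
#' inflation (elementwise power `inflation`, renormalise), pruning entries
#' below 1e-9, until the iterate changes by less than 1e-6 (or 100 rounds).
#' Clusters are the connected components of the limit matrix's support;
#' overlapping attractor systems merge, which resolves ties toward the
#' cluster containing the lowest gene id. Every gene lands in exactly one
#' multi-member OG or in the singleton pool.
#'
#' @param hits data frame from [all_vs_all_similarity()].
#' @param inflation inflation exponent (default 1.5).
#' @param genes optional full gene universe (ids with no hits become
#'   singletons); defaults to the ids present in `hits`.
#' @param gene_strains optional named map gene id -> strain; defaults to the
#'   prefix of the gene id before the first `|`.
#' @return object of class `ortho_matrix`: `strains`, `og_ids`, `counts`
#'   (strains x OGs), `members` (OG -> gene ids), `singletons`
#'   (data frame gene, strain).
#' @export
mcl_cluster <- function(hits, inflation = 1.5, genes = NULL,
                        gene_strains = NULL) {
  stopifnot(is.data.frame(hits),
            all(c("query", "subject", "score") %in% names(hits)))
  genes <- sort(unique(c(genes, hits$query, hits$subject)))
  if (!length(genes)) stop("no genes to cluster")
  if (is.null(gene_strains)) {
    gene_strains <- sub("\\|.*$", "", genes)
    names(gene_strains) <- genes
  }
  gi <- match(hits$query, genes); gj <- match(hits$subject, genes)
  comp <- uf_components(length(genes), gi, gj)
  clusters <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) { clusters[[length(clusters) + 1L]] <- idx; next }
    sel <- gi %in% idx & gj %in% idx
    W <- matrix(0, length(idx), length(idx))
    ii <- match(gi[sel], idx); jj <- match(gj[sel], idx)
    # symmetric average of the two hit directions
    for (e in seq_along(ii)) {
      W[ii[e], jj[e]] <- W[ii[e], jj[e]] + hits$score[sel][e] / 2
      W[jj[e], ii[e]] <- W[jj[e], ii[e]] + hits$score[sel][e] / 2
    }
    mem <- .mcl_component(W, inflation)
    for (m in unique(mem))
      clusters[[length(clusters) + 1L]] <- idx[mem == m]
  }
  sizes <- lengths(clusters)
  multi <- clusters[sizes >= 2]
  single <- unlist(clusters[sizes == 1])
  ord <- order(vapply(multi, function(ix) genes[min(ix)], character(1)))
  multi <- multi[ord]
  og_ids <- sprintf("OG%05d", seq_along(multi))
  members <- lapply(multi, function(ix) genes[ix])
  names(members) <- og_ids
  strains <- sort(unique(unname(gene_strains[genes])))
  counts <- matrix(0L, length(strains), length(og_ids),
                   dimnames = list(strains, og_ids))
  for (og in og_ids) {
    tab <- table(gene_strains[members[[og]]])
    counts[names(tab), og] <- as.integer(tab)
  }
  singletons <- data.frame(gene = genes[single],
                           strain = unname(gene_strains[genes[single]]),
                           stringsAsFactors = FALSE)
  structure(list(strains = strains, og_ids = og_ids, counts = counts,
                 members = members, singletons = singletons),
            class = "ortho_matrix")
}

#' Core and single-copy-core extraction
#'
#' Core OGs occur in every strain; the single-copy core (SCC) additionally
#' has exactly one member per strain — OGs containing paralogs are thereby
#' removed from the SCC pool.
#'
#' @param matrix an `ortho_matrix`.
#' @return list of class `core_partition` with `core_ogs` and `scc_ogs`.
#' @export
extract_core <- function(matrix) {
  stopifnot(inherits(matrix, "ortho_matrix"))
  if (length(matrix$strains) < 2) stop("need >= 2 strains")
  cnt <- matrix$counts
  core <- colnames(cnt)[apply(cnt, 2, function(x) all(x >= 1))]
  scc <- colnames(cnt)[apply(cnt, 2, function(x) all(x == 1))]
  structure(list(core_ogs = core, scc_ogs = scc), class = "core_partition")
}

#' Pan/core summary statistics
#'
#' @param matrix an `ortho_matrix`.
#' @param core a `core_partition`.
#' @return list: pan size (OGs + singletons), core size, core as integer
#'   percent of the pan and of the average per-strain gene count.
#' @export
og_stats <- function(matrix, core) {
  stopifnot(inherits(matrix, "ortho_matrix"), inherits(core, "core_partition"))
  n_ogs <- length(matrix$og_ids)
  n_singletons <- nrow(matrix$singletons)
  total_genes <- sum(matrix$counts) + n_singletons
  if (total_genes == 0) stop("matrix contains no genes")
  per_strain <- rowSums(matrix$counts) +
    as.integer(table(factor(matrix$singletons$strain, levels = matrix$strains)))
  pan <- n_ogs + n_singletons
  core_n <- length(core$core_ogs)
  list(n_strains = length(matrix$strains), n_ogs = n_ogs,
       n_singletons = n_singletons, pan_size = pan, core_size = core_n,
       scc_size = length(core$scc_ogs),
       avg_gene_count = mean(per_strain),
       core_pct_of_pan = round(100 * core_n / pan),
       core_pct_of_avg_gene_count = round(100 * core_n / mean(per_strain)))
}

#' Build per-OG alignments for the single-copy core
#'
#' For each SCC OG, the member gene sequences (exactly one per strain) are
#' renamed by strain. OGs whose members differ in length (no indel-free
#' alignment available) are skipped with a warning.
#'
#' @param matrix an `ortho_matrix`.
#' @param core a `core_partition`.
#' @param gene_seqs gene id -> sequence.
#' @param gene_strains named map gene id -> strain (default: id prefix).
#' @return named list of alignments (strain-named character vectors).
#' @export
scc_alignments <- function(matrix, core, gene_seqs, gene_strains = NULL) {
  if (is.null(gene_strains)) {
    gene_strains <- sub("\\|.*$", "", names(gene_seqs))
    names(gene_strains) <- names(gene_seqs)
  }
  out <- list()
  for (og in core$scc_ogs) {
    mem <- matrix$members[[og]]
    seqs <- gene_seqs[mem]
    if (length(unique(nchar(seqs))) != 1) {
      warning("skipping ", og, ": unequal member lengths")
      next
    }
    names(seqs) <- unname(gene_strains[mem])
    out[[og]] <- seqs[order(names(seqs))]
  }
  out
}
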
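# Average nucleotide identity: fragment-based ANI (1020-nt windows, best-hit
# seed-and-extend with the 30%-identity / 70%-coverage filter), gene-based
# gANI with alignment fraction, the 100-ANI distance matrix, UPGMA
# dendrograms, and threshold species delineation.

#' Cut a genome into consecutive fragments
#'
#' Non-overlapping windows of `fragment_len`; the trailing remainder is
#' discarded. Fragment starts are 0, `fragment_len`, `2*fragment_len`, ...
#'
#' @param genome_seq one sequence (string).
#' @param fragment_len window size in nt (default 1020).
#' @return character vector of fragments.
#' @export
fragment_genome <- function(genome_seq, fragment_len = 1020L) {
  L <- nchar(genome_seq)
  if (L < fragment_len) stop("genome shorter than fragment_len")
  n <- L %/% fragment_len
  starts <- (seq_len(n) - 1L) * fragment_len + 1L
  substring(genome_seq, starts, starts + fragment_len - 1L)
}

# best local match of one fragment against an indexed subject: majority seed
# diagonal, then the maximal-scoring segment (match +1 / mismatch -2) on that
# diagonal, which emulates a BLAST HSP without the aligner. `m` holds the
# subject positions of the fragment's seed k-mers (NA = unseen).
.fragment_best_hit <- function(frag_int, m, kmer_pos, subject_int) {
  ok <- !is.na(m)
  if (!any(ok)) return(NULL)
  offs <- m[ok] - kmer_pos[ok]
  off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
  flen <- length(frag_int)
  q_from <- max(1L, 1L - off)
  q_to <- min(flen, length(subject_int) - off)
  if (q_to - q_from + 1L < 2L) return(NULL)
  va <- frag_int[q_from:q_to]
  vb <- subject_int[(q_from + off):(q_to + off)]
  eq <- !is.na(va) & !is.na(vb) & va == vb
  sc <- ifelse(eq, 1, -2)
  # maximal-scoring contiguous segment via prefix sums
  S <- cumsum(sc)
  pref <- c(0, S[-length(S)])
  gain <- S - cummin(pref)
  if (max(gain) <= 0) return(NULL)
  b_to <- which.max(gain)
  b_from <- which.min(c(0, S)[seq_len(b_to)])  # start right after the min prefix
  seg <- eq[b_from:b_to]
  c(identity = 100 * sum(seg) / length(seg),
    coverage = length(seg) / flen)
}

# concatenate contigs with N-runs so no k-mer spans a junction
.cat_contigs <- function(contigs, k) paste(contigs, collapse = strrep("N", k))

# precomputed subject k-mer table + integer encoding, reusable across queries
.subject_index <- function(subject_genome, k = 15L) {
  subject <- .cat_contigs(subject_genome, k)
  if (nchar(subject) < k) stop("subject too short")
  sL <- nchar(subject)
  list(kmers = substring(subject, seq_len(sL - k + 1L),
                         seq_len(sL - k + 1L) + k - 1L),
       ints = seq_to_int(subject))
}

#' One-directional fragment-based ANI
#'
#' Every `fragment_len` window of the query is matched to its best location
#' in the subject (exact 15-mer seeding, majority diagonal, HSP-like segment
#' trimming). Hits with >= 30% identity over >= 70% of the fragment length
#' are kept; ANI is their mean percent identity. Returns `NA` when no
#' fragment qualifies.
#'
#' @param query_genome,subject_genome character vector(s) of contigs.
#' @param cfg a [pipeline_config()] (uses `fragment_len`).
#' @param k seed length (default 15).
#' @return list `ani` (percent or NA), `n_used` fragments.
#' @export
ani_pair <- function(query_genome, subject_genome, cfg = pipeline_config(),
                     k = 15L, subject_index = NULL) {
  frag_len <- cfg$fragment_len
  if (is.null(subject_index))
    subject_index <- .subject_index(subject_genome, k)
  subject_kmers <- subject_index$kmers
  subject_int <- subject_index$ints
  frags <- unlist(lapply(query_genome, function(ctg)
    if (nchar(ctg) >= frag_len) fragment_genome(ctg, frag_len)))
  idents <- numeric(0)
  if (length(frags)) {
    kmer_pos <- seq(1L, frag_len - k + 1L, by = 5L)
    # one hashed lookup for all fragments' seeds at once
    all_k <- substring(rep(frags, each = length(kmer_pos)),
                       rep(kmer_pos, length(frags)),
                       rep(kmer_pos + k - 1L, length(frags)))
    all_m <- match(all_k, subject_kmers)
    for (fi in seq_along(frags)) {
      sl <- ((fi - 1L) * length(kmer_pos) + 1L):(fi * length(kmer_pos))
      hit <- .fragment_best_hit(seq_to_int(frags[fi]), all_m[sl], kmer_pos,
                                subject_int)
      if (is.null(hit)) next
      if (hit[["identity"]] >= 30 && hit[["coverage"]] >= 0.7)
        idents <- c(idents, hit[["identity"]])
    }
  }
  if (!length(idents) && sum(nchar(query_genome) >= frag_len) == 0)
    stop("query has no contig of at least fragment_len")
  list(ani = if (length(idents)) mean(idents) else NA_real_,
       n_used = length(idents))
}

#' Pairwise ANI (and optionally gANI/AF) over a set of genomes
#'
#' Directed ANI values are computed for every ordered pair and averaged into
#' one symmetric matrix (ANI is direction-dependent; the dendrogram and
#' clustering need a metric). Both directions are retained in
#' `ani_directed`.
#'
#' @param genomes named list: strain -> character vector of contigs.
#' @param cfg a [pipeline_config()].
#' @param gene_sets optional named list strain -> gene sequences; when given,
#'   gANI and AF matrices are computed too.
#' @return object of class `ani_result` with matrices `ani`, `n_fragments_used`,
#'   `ani_directed`, and (optionally) `gani`, `af`.
#' @export
ani_matrix <- function(genomes, cfg = pipeline_config(), gene_sets = NULL) {
  strains <- sort(names(genomes))
  n <- length(strains)
  ani_d <- matrix(NA_real_, n, n, dimnames = list(strains, strains))
  nfrag <- matrix(0L, n, n, dimnames = list(strains, strains))
  diag(ani_d) <- 100
  idx <- lapply(strains, function(s) .subject_index(genomes[[s]]))
  names(idx) <- strains
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- ani_pair(genomes[[strains[i]]], genomes[[strains[j]]], cfg,
                  subject_index = idx[[strains[j]]])
    ani_d[i, j] <- r$ani
    nfrag[i, j] <- r$n_used
  }
  sym <- ani_d
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    v <- c(ani_d[i, j], ani_d[j, i])
    sym[i, j] <- sym[j, i] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out <- list(labels = strains, ani = sym, ani_directed = ani_d,
              n_fragments_used = nfrag)
  if (!is.null(gene_sets)) {
    gani <- af <- matrix(NA_real_, n, n, dimnames = list(strains, strains))
    diag(gani) <- 100; diag(af) <- 1
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- gani_af_pair(gene_sets[[strains[i]]], gene_sets[[strains[j]]])
      gani[i, j] <- gani[j, i] <- r$gani
      af[i, j] <- af[j, i] <- r$af_mean
    }
    out$gani <- gani
    out$af <- af
  }
  structure(out, class = "ani_result")
}

#' Gene-based gANI and alignment fraction for one genome pair
#'
#' Bidirectional best hits between the two gene sets (same seeded identity
#' search as the orthology stage, no cutoffs); gANI is the aligned-length
#' weighted mean identity of the BBH pairs, AF the aligned fraction of each
#' genome's total coding length, averaged over the two directions.
#'
#' @param genesA,genesB named character vectors of gene sequences.
#' @return list `gani` (percent, NA when no BBH), `af` (aligned fraction of
#'   genome A's coding length; 0 when no BBH), `af_reverse` (B-based),
#'   `af_mean` (direction average, used for the symmetric matrices), `n_bbh`.
#' @export
gani_af_pair <- function(genesA, genesB) {
  if (!length(genesA) || !length(genesB)) stop("empty gene set")
  k <- 16L
  intsA <- lapply(genesA, seq_to_int)
  intsB <- lapply(genesB, seq_to_int)
  kmB <- lapply(genesB, .kmers_at, k = k, stride = 8L)
  lookup <- split(rep(seq_along(genesB), lengths(kmB)),
                  unlist(kmB, use.names = FALSE))
  best <- function(ia, sa) {
    qk <- .kmers_at(sa, k, 8L)
    cand <- sort(unique(unlist(lookup[qk], use.names = FALSE)))
    if (!length(cand)) return(NULL)
    scores <- vapply(cand, function(bi) {
      r <- .pair_identity(ia, intsB[[bi]], sa, genesB[[bi]], k)
      alen <- r[["coverage"]] * min(length(ia), length(intsB[[bi]]))
      c(r[["identity"]], alen, r[["identity"]] * alen)
    }, numeric(3))
    pick <- which.max(scores[3, ])
    c(idx = cand[pick], identity = scores[1, pick], alen = scores[2, pick])
  }
  bestA <- lapply(seq_along(genesA), function(i) best(intsA[[i]], genesA[[i]]))
  # reciprocal check: best hit of B-gene back into A
  kmA <- lapply(genesA, .kmers_at, k = k, stride = 8L)
  lookupA <- split(rep(seq_along(genesA), lengths(kmA)),
                   unlist(kmA, use.names = FALSE))
  bestB_idx <- integer(length(genesB))
  for (bi in seq_along(genesB)) {
    qk <- .kmers_at(genesB[[bi]], k, 8L)
    cand <- sort(unique(unlist(lookupA[qk], use.names = FALSE)))
    if (!length(cand)) { bestB_idx[bi] <- NA_integer_; next }
    sc <- vapply(cand, function(ai) {
      r <- .pair_identity(intsB[[bi]], intsA[[ai]], genesB[[bi]], genesA[[ai]], k)
      r[["identity"]] * r[["coverage"]] * min(length(intsB[[bi]]), length(intsA[[ai]]))
    }, numeric(1))
    bestB_idx[bi] <- cand[which.max(sc)]
  }
  ids <- numeric(0); alens <- numeric(0)
  lenA_hit <- 0; lenB_hit <- 0
  for (ai in seq_along(genesA)) {
    h <- bestA[[ai]]
    if (is.null(h)) next
    bi <- h[["idx"]]
    if (!is.na(bestB_idx[bi]) && bestB_idx[bi] == ai) {
      ids <- c(ids, h[["identity"]])
      alens <- c(alens, h[["alen"]])
      lenA_hit <- lenA_hit + h[["alen"]]
      lenB_hit <- lenB_hit + h[["alen"]]
    }
  }
  if (!length(ids))
    return(list(gani = NA_real_, af = 0, af_reverse = 0, af_mean = 0,
                n_bbh = 0L))
  afA <- lenA_hit / sum(nchar(genesA))
  afB <- lenB_hit / sum(nchar(genesB))
  list(gani = sum(ids * alens) / sum(alens),
       af = afA, af_reverse = afB, af_mean = (afA + afB) / 2,
       n_bbh = length(ids))
}

#' ANI divergence matrix (100 - ANI)
#'
#' @param result an `ani_result`.
#' @return symmetric distance matrix; missing ANI becomes maximal divergence
#'   (100) and is flagged via the `missing_pairs` attribute.
#' @export
ani_distance_matrix <- function(result) {
  stopifnot(inherits(result, "ani_result"))
  a <- result$ani
  miss <- which(is.na(a) & upper.tri(a), arr.ind = TRUE)
  a[is.na(a)] <- 0
  d <- 100 - a
  diag(d) <- 0
  attr(d, "missing_pairs") <- miss
  d
}

# ---- UPGMA ------------------------------------------------------------------

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration with deterministic ties (smallest label
#' pair). Merge heights are non-decreasing; on an ultrametric input the
#' dendrogram reproduces the input distances exactly. Returns both a `phylo`
#' tree (branch lengths = half merge heights, so the tree is ultrametric) and
#' an `hclust`-compatible structure for cutting.
#'
#' @param dm symmetric labelled distance matrix.
#' @param linkage `"average"` (UPGMA), `"single"` or `"complete"`.
#' @return list of class `upgma_dendrogram`: `phylo`, `hclust`.
#' @export
upgma <- function(dm, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(dm), nrow(dm) >= 2, !is.null(rownames(dm)))
  labels <- rownames(dm)
  n <- length(labels)
  D <- dm
  frag <- labels; height <- numeric(n); size <- rep(1L, n)
  minlab <- labels
  merge_id <- -seq_len(n)                      # hclust convention
  active <- seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    Da <- D[active, active, drop = FALSE]
    diag(Da) <- Inf
    dmin <- min(Da)
    cand <- which(Da - dmin < 1e-12 & upper.tri(Da), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      keys <- apply(cand, 1, function(ix)
        paste(sort(c(minlab[active[ix[1]]], minlab[active[ix[2]]])),
              collapse = "\r"))
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    ai <- active[i]; aj <- active[j]
    h <- Da[i, j]
    new_id <- length(frag) + 1L
    frag[new_id] <- sprintf("(%s:%.10g,%s:%.10g)", frag[ai],
                            h / 2 - height[ai], frag[aj], h / 2 - height[aj])
    height[new_id] <- h / 2
    size[new_id] <- size[ai] + size[aj]
    minlab[new_id] <- min(minlab[ai], minlab[aj])
    rest <- setdiff(active, c(ai, aj))
    newd <- switch(linkage,
      average = (size[ai] * D[ai, rest] + size[aj] * D[aj, rest]) /
        (size[ai] + size[aj]),
      single = pmin(D[ai, rest], D[aj, rest]),
      complete = pmax(D[ai, rest], D[aj, rest]))
    D <- rbind(cbind(D, 0), 0)
    if (length(rest)) { D[new_id, rest] <- newd; D[rest, new_id] <- newd }
    merges[step, ] <- sort(c(merge_id[ai], merge_id[aj]))
    heights[step] <- h
    merge_id[new_id] <- step
    active <- c(rest, new_id)
  }
  phylo <- ape::read.tree(text = paste0(frag[length(frag)], ";"))
  ord <- .hclust_order(merges)
  hc <- structure(list(merge = merges, height = heights, order = ord,
                       labels = labels, method = linkage,
                       call = match.call(), dist.method = "user"),
                  class = "hclust")
  structure(list(phylo = phylo, hclust = hc), class = "upgma_dendrogram")
}

# leaf order for plotting/cutting, from the merge matrix
.hclust_order <- function(merges) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merges[i, 1]), expand(merges[i, 2]))
  }
  expand(nrow(merges))
}

#' Threshold-based species delineation
#'
#' Builds a graph with an edge between two strains when the criterion is met
#' (`ani95`: symmetric ANI >= threshold; `gani_af`: gANI > threshold AND
#' AF > threshold) and takes connected components as candidate species.
#' Missing values fail the criterion (conservative). Per-component clique
#' purity (fraction of within-component pairs meeting the criterion) is
#' reported, quantifying how far components are from cliques.
#'
#' @param result an `ani_result` (with `gani`/`af` for method `"gani_af"`).
#' @param method `"ani95"` or `"gani_af"`.
#' @param cfg a [pipeline_config()] (thresholds).
#' @return list of class `species_partition`: `assignment` (strain ->
#'   candidate-species id), `method`, `thresholds`, `clique_purity`.
#' @export
delineate_species <- function(result, method = c("ani95", "gani_af"),
                              cfg = pipeline_config()) {
  method <- match.arg(method)
  stopifnot(inherits(result, "ani_result"))
  labs <- result$labels
  n <- length(labs)
  meets <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  if (method == "ani95") {
    a <- result$ani
    meets <- !is.na(a) & a >= cfg$ani_species_threshold
  } else {
    if (is.null(result$gani)) stop("gANI/AF matrices absent from result")
    g <- result$gani; f <- result$af
    meets <- !is.na(g) & !is.na(f) & g > cfg$gani_threshold & f > cfg$af_threshold
  }
  diag(meets) <- TRUE
  edges <- which(meets & upper.tri(meets), arr.ind = TRUE)
  comp <- uf_components(n, edges[, 1], edges[, 2])
  # stable ids ordered by each component's smallest strain label
  comp_ids <- unique(comp[order(labs)])
  relabel <- stats::setNames(sprintf("cand_sp%02d", seq_along(comp_ids)), comp_ids)
  assignment <- stats::setNames(relabel[as.character(comp)], labs)
  purity <- vapply(comp_ids, function(cid) {
    mem <- which(comp == cid)
    if (length(mem) < 2) return(1)
    sub <- meets[mem, mem]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  names(purity) <- relabel[as.character(comp_ids)]
  structure(list(assignment = assignment, method = method,
                 thresholds = list(ani = cfg$ani_species_threshold,
                                   gani = cfg$gani_threshold,
                                   af = cfg$af_threshold),
                 clique_purity = purity),
            class = "species_partition")
}
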
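# 16S-like marker analyses (SNP counts, SNP-vs-ANI regression) and binary
# trait clustering with partition-agreement scoring.

#' Count SNPs between two aligned sequences
#'
#' Positions where either sequence carries a gap/ambiguity are skipped.
#'
#' @param seq_a,seq_b equal-length strings.
#' @return integer substitution count.
#' @export
snp_count <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("length mismatch")
  a <- seq_to_int(seq_a); b <- seq_to_int(seq_b)
  sum(a != b, na.rm = TRUE)
}

#' Build a marker set from per-strain 16S-like copies
#'
#' Verifies that all copies within a strain are identical (heterogeneous
#' copies are a hard error — intra-genomic 16S heterogeneity would break
#' SNP typing) and keeps one representative per strain.
#'
#' @param marker_seqs named list strain -> character vector of copies.
#' @return named character vector strain -> representative sequence, of class
#'   `marker_set`.
#' @export
marker_set <- function(marker_seqs) {
  reps <- vapply(names(marker_seqs), function(s) {
    cp <- marker_seqs[[s]]
    if (!length(cp)) stop("no marker copies for ", s)
    if (length(unique(cp)) != 1)
      stop("heterogeneous marker copies within strain ", s)
    cp[[1]]
  }, character(1))
  if (length(unique(nchar(reps))) != 1)
    stop("marker sequences have unequal lengths across strains")
  class(reps) <- c("marker_set", class(reps))
  reps
}

#' 16S SNPs versus ANI, with ordinary least squares
#'
#' One row per unordered strain pair (`snps`, `ani`); ANI is regressed on the
#' SNP count so that the fitted SNP count at ANI = 95 reads off directly as
#' `x_at_ani95 = (95 - intercept)/slope`. The fit is refused for fewer than
#' 3 pairs or zero variance in the SNP counts.
#'
#' @param markers a [marker_set()] (or named sequence vector).
#' @param ani symmetric ANI matrix or `ani_result`.
#' @return list of class `snp_ani_fit`: `pairs` data frame and `fit`
#'   (`slope`, `intercept`, `r_squared`, `x_at_ani95`).
#' @export
snp_vs_ani <- function(markers, ani) {
  if (inherits(ani, "ani_result")) ani <- ani$ani
  strains <- sort(intersect(names(markers), rownames(ani)))
  if (length(strains) < 3) stop("need >= 3 overlapping strains")
  cmb <- utils::combn(strains, 2)
  snps <- vapply(seq_len(ncol(cmb)), function(e)
    snp_count(markers[[cmb[1, e]]], markers[[cmb[2, e]]]), numeric(1))
  anis <- vapply(seq_len(ncol(cmb)), function(e)
    ani[cmb[1, e], cmb[2, e]], numeric(1))
  ok <- !is.na(anis)
  pairs <- data.frame(strain_a = cmb[1, ok], strain_b = cmb[2, ok],
                      snps = snps[ok], ani = anis[ok],
                      stringsAsFactors = FALSE)
  if (nrow(pairs) < 3) stop("fit refused: fewer than 3 pairs")
  x <- pairs$snps; y <- pairs$ani
  if (stats::var(x) == 0) stop("fit refused: zero variance in SNP counts")
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  ss_res <- sum((y - pred)^2); ss_tot <- sum((y - mean(y))^2)
  fit <- list(slope = slope, intercept = intercept,
              r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
              x_at_ani95 = (95 - intercept) / slope)
  structure(list(pairs = pairs, fit = fit), class = "snp_ani_fit")
}

#' Jaccard distances between binary rows
#'
#' @param presence strains x traits matrix of 0/1.
#' @return symmetric distance matrix; all-zero rows sit at distance 1 from
#'   everything (with a warning).
#' @export
jaccard_distance <- function(presence) {
  p <- presence > 0
  if (any(rowSums(p) == 0))
    warning("all-zero strain row(s): distance 1 to everything")
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    inter <- sum(p[i, ] & p[j, ]); uni <- sum(p[i, ] | p[j, ])
    d[i, j] <- d[j, i] <- if (uni == 0) 1 else 1 - inter / uni
  }
  d
}

#' Hierarchical clustering of binary traits
#'
#' Jaccard distance on presence/absence vectors, then average-linkage
#' agglomeration (ties by smallest label pair), mirroring the conventional
#' `hclust(..., method = "average")` treatment of COG/BGC tables.
#'
#' @param presence strains x traits binary matrix (>= 2 strains, >= 1 trait).
#' @param linkage linkage method (default `"average"`).
#' @return an `upgma_dendrogram` (see [upgma()]).
#' @export
trait_cluster <- function(presence, linkage = "average") {
  stopifnot(is.matrix(presence), nrow(presence) >= 2, ncol(presence) >= 1,
            !is.null(rownames(presence)))
  upgma(jaccard_distance(presence), linkage = linkage)
}

#' Cut a dendrogram into k groups
#'
#' @param dendro an `upgma_dendrogram`.
#' @param k number of groups.
#' @return named character vector strain -> group id.
#' @export
cut_partition <- function(dendro, k) {
  stopifnot(inherits(dendro, "upgma_dendrogram"))
  grp <- stats::cutree(dendro$hclust, k = k)
  stats::setNames(sprintf("grp%02d", grp), names(grp))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement in `[-1, 1]`; 1 iff the partitions are
#' identical up to relabelling.
#'
#' @param partition_a,partition_b named vectors over the same strain set.
#' @return numeric ARI.
#' @export
partition_agreement <- function(partition_a, partition_b) {
  if (!setequal(names(partition_a), names(partition_b)))
    stop("partitions cover different strain sets")
  b <- partition_b[names(partition_a)]
  tab <- table(partition_a, b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) {
    return(if (sum_ij == max_idx) 1 else 0)
  }
  (sum_ij - expected) / (max_idx - expected)
}
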
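# Pan/core rarefaction and nonparametric richness (incidence-based Chao1 and
# ACE), plus the OG occupancy spectrum behind the histograms.

#' Occupancy spectrum of orthologous groups
#'
#' `Q[j]` = number of gene families present in exactly `j` strains.
#' `collapse_paralogs` collapses within-strain extra copies (counts > 1
#' become presence). With `exclude_singletons = TRUE` the spectrum drops
#' families that occupy a single strain (file-level singleton OGs and
#' single-strain "recent paralog" families) and ignores unclustered
#' singletons; with `FALSE` the unclustered singletons are added to `Q[1]`,
#' which is the inclusive spectrum richness estimation uses.
#'
#' @param matrix an `ortho_matrix`.
#' @param exclude_singletons drop single-strain families (default TRUE).
#' @param collapse_paralogs count presence, not gene copies (default TRUE).
#' @return named numeric vector `Q`, index = occupancy `j` (1..n_strains).
#' @export
occupancy_spectrum <- function(matrix, exclude_singletons = TRUE,
                               collapse_paralogs = TRUE) {
  stopifnot(inherits(matrix, "ortho_matrix"))
  cnt <- matrix$counts
  occ <- colSums(cnt >= 1)
  n <- length(matrix$strains)
  drop <- rep(FALSE, ncol(cnt))
  if (exclude_singletons) {
    # single-strain single-copy families; with paralog collapsing, also the
    # single-strain multi-copy ("recent paralog") families
    drop <- occ == 1 & (if (collapse_paralogs) TRUE else colSums(cnt) == 1)
  }
  occ <- occ[!drop]
  q <- vapply(seq_len(n), function(j) sum(occ == j), numeric(1))
  names(q) <- seq_len(n)
  if (!exclude_singletons) q[1] <- q[1] + nrow(matrix$singletons)
  q
}

#' Pan/core rarefaction over random strain orderings
#'
#' For each of `n_perm` permutations of the strain order, the cumulative
#' pan-genome (union of families, unclustered singletons included) and core
#' genome (families present in all sampled strains) are recorded at each
#' sample size `k`; means and standard errors (sd over permutations /
#' sqrt(n_perm)) summarise the curves. Endpoints are order-invariant:
#' at `k = 1` pan = core = mean per-strain family count, at `k = n` pan is
#' the full pan-genome and core the full core.
#'
#' @param matrix an `ortho_matrix`.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return data frame `k, pan_mean, pan_se, core_mean, core_se` of class
#'   `rarefaction_result`, with `n_perm` and `seed` attributes.
#' @export
rarefy <- function(matrix, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(matrix, "ortho_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  pres <- matrix$counts >= 1
  n <- nrow(pres)
  single_per_strain <- as.integer(table(factor(matrix$singletons$strain,
                                               levels = matrix$strains)))
  names(single_per_strain) <- matrix$strains
  pan <- matrix(0, n_perm, n)
  core <- matrix(0, n_perm, n)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ord <- sample.int(n)
      un <- rep(FALSE, ncol(pres)); inter <- rep(TRUE, ncol(pres))
      singles <- 0L
      for (k in seq_len(n)) {
        row <- pres[ord[k], ]
        un <- un | row
        inter <- inter & row
        singles <- singles + single_per_strain[ord[k]]
        pan[r, k] <- sum(un) + singles
        core[r, k] <- sum(inter) + if (k == 1) singles else 0L
      }
    }
  })
  se <- function(m) apply(m, 2, stats::sd) / sqrt(n_perm)
  out <- data.frame(k = seq_len(n),
                    pan_mean = colMeans(pan), pan_se = se(pan),
                    core_mean = colMeans(core), core_se = se(core))
  # endpoints are order-invariant: report them exactly, not by Monte Carlo
  per_strain <- rowSums(pres) + single_per_strain
  out$pan_mean[1] <- out$core_mean[1] <- mean(per_strain)
  out$pan_mean[n] <- sum(colSums(pres) > 0) + sum(single_per_strain)
  out$core_mean[n] <- sum(colSums(pres) == n)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("rarefaction_result", "data.frame")
  out
}

#' Chao1 richness estimate (incidence form)
#'
#' `chao = S_obs + Q1^2 / (2 Q2)`; when `Q2 = 0` the classic fallback
#' `S_obs + Q1 (Q1 - 1) / 2` is used. Genomes act as incidence samples;
#' within-genome copy numbers are not abundances.
#'
#' @param spectrum occupancy spectrum as from [occupancy_spectrum()].
#' @return estimated family richness (>= observed).
#' @export
chao_estimate <- function(spectrum) {
  s_obs <- sum(spectrum)
  if (s_obs < 1) stop("empty spectrum")
  q1 <- if (length(spectrum) >= 1) spectrum[[1]] else 0
  q2 <- if (length(spectrum) >= 2) spectrum[[2]] else 0
  if (q1 == 0) return(s_obs)
  if (q2 > 0) s_obs + q1^2 / (2 * q2) else s_obs + q1 * (q1 - 1) / 2
}

#' ACE richness estimate (incidence form)
#'
#' Families in at most `rare_cutoff` strains are "rare". With
#' `N_rare = sum_{j<=cut} j Q_j`, sample coverage `C = 1 - Q1 / N_rare` and
#' the squared coefficient of variation
#' `g2 = max(S_rare * sum j(j-1) Qj / (C * N_rare * (N_rare - 1)) - 1, 0)`,
#' `ace = S_abund + S_rare / C + Q1 * g2 / C`. Degenerate inputs fall back:
#' no rare families or `N_rare <= 1` -> `S_obs`; `C = 0` -> [chao_estimate()].
#'
#' @param spectrum occupancy spectrum.
#' @param rare_cutoff occupancy bound for the rare class (default 10).
#' @return estimated family richness.
#' @export
ace_estimate <- function(spectrum, rare_cutoff = 10L) {
  s_obs <- sum(spectrum)
  if (s_obs < 1) stop("empty spectrum")
  j <- if (is.null(names(spectrum))) seq_along(spectrum)
       else as.numeric(names(spectrum))
  rare <- j <= rare_cutoff
  s_rare <- sum(spectrum[rare]); s_abund <- sum(spectrum[!rare])
  n_rare <- sum(j[rare] * spectrum[rare])
  if (s_rare == 0 || n_rare <= 1) return(s_obs)
  q1 <- sum(spectrum[j == 1])
  C <- 1 - q1 / n_rare
  if (C == 0) return(chao_estimate(spectrum))
  g2 <- max(s_rare * sum(j[rare] * (j[rare] - 1) * spectrum[rare]) /
              (C * n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / C + q1 * g2 / C
}
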
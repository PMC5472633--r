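#' Simulation parameters for a synthetic bacterial genus
#'
#' The generator emulates a genus of closely related bacteria: a handful of
#' species-level clades whose core genes differ by a few percent, sporadic
#' within-genome paralogs, clade-biased accessory gene content, homologous
#' recombination between clades, and a slow-evolving multi-copy 16S-like
#' marker (copies identical within a strain, a handful of SNPs across the
#' genus).
#'
#' Divergences are expected substitutions/site from tip to the relevant
#' ancestor, i.e. two conspecific strains sit ~`2 * within_species_div` apart
#' and two strains of different species ~`2 * between_species_div` apart.
#' `paralog_rate` is the per-genome, per-core-family probability of a recent
#' within-genome duplication (copies get 0.5% extra divergence).
#'
#' @param n_species number of species-level clades.
#' @param strains_per_species integer vector (recycled) of strains per species.
#' @param n_core_genes core gene families present in every strain.
#' @param n_accessory_genes accessory families with patchy occupancy.
#' @param gene_len gene length in nt (no indels are simulated).
#' @param marker_len length of the 16S-like marker.
#' @param marker_copies_range inclusive range of identical marker copies.
#' @param within_species_div,between_species_div tip-to-ancestor divergences;
#'   must satisfy `between > within > 0`.
#' @param recomb_gene_fraction fraction of core families receiving one
#'   cross-species recombination event.
#' @param recomb_tract_fraction fraction of the gene length transferred
#'   (1.0 = whole-allele replacement).
#' @param paralog_rate per-genome per-core-family duplication probability.
#' @param accessory_clade_bias probability that an accessory family is
#'   clade-specific rather than cosmopolitan.
#' @param seed master RNG seed for the genus.
#' @return validated list of class `sim_params`.
#' @export
sim_params <- function(n_species = 3L, strains_per_species = 4L,
                       n_core_genes = 100L, n_accessory_genes = 60L,
                       gene_len = 900L, marker_len = 1500L,
                       marker_copies_range = c(2L, 5L),
                       within_species_div = 0.01, between_species_div = 0.06,
                       recomb_gene_fraction = 0, recomb_tract_fraction = 1.0,
                       paralog_rate = 0.02, accessory_clade_bias = 0.7,
                       seed = 1L) {
  strains_per_species <- rep_len(as.integer(strains_per_species), n_species)
  p <- list(n_species = as.integer(n_species),
            strains_per_species = strains_per_species,
            n_core_genes = as.integer(n_core_genes),
            n_accessory_genes = as.integer(n_accessory_genes),
            gene_len = as.integer(gene_len),
            marker_len = as.integer(marker_len),
            marker_copies_range = as.integer(marker_copies_range),
            within_species_div = within_species_div,
            between_species_div = between_species_div,
            recomb_gene_fraction = recomb_gene_fraction,
            recomb_tract_fraction = recomb_tract_fraction,
            paralog_rate = paralog_rate,
            accessory_clade_bias = accessory_clade_bias,
            seed = as.integer(seed))
  stopifnot(p$n_species >= 1, all(p$strains_per_species >= 1),
            p$n_core_genes >= 1, p$n_accessory_genes >= 0,
            p$gene_len >= 1, p$marker_len >= 1,
            length(p$marker_copies_range) == 2,
            p$marker_copies_range[1] >= 1,
            p$marker_copies_range[2] >= p$marker_copies_range[1])
  if (!(p$between_species_div > p$within_species_div &&
        p$within_species_div > 0))
    stop("must have between_species_div > within_species_div > 0")
  for (f in c("recomb_gene_fraction", "recomb_tract_fraction",
              "paralog_rate", "accessory_clade_bias"))
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (p$recomb_gene_fraction > 0 && p$recomb_tract_fraction == 0)
    stop("recomb_tract_fraction must be > 0 when events are requested")
  class(p) <- "sim_params"
  p
}

#' Simulate an ultrametric species/strain tree
#'
#' Species clades attach to the root at depth `between_species_div`; within a
#' species, strains coalesce through a random binary subtree whose root sits
#' at depth `within_species_div` (internal depths uniform below that), so that
#' conspecific leaf pairs are ~`2*within` apart and heterospecific pairs
#' ~`2*between` apart, and every species is monophyletic by construction.
#' Resolved within-species structure matters: it is what gives recombination
#' tests informative site patterns inside clades.
#'
#' @param n_species,strains_per_species,within_species_div,between_species_div
#'   see [sim_params()].
#' @param seed RNG seed.
#' @return rooted ultrametric `phylo`; leaf labels `s<species>_<strain>`,
#'   with a `truth_species` attribute mapping strain to species label.
#' @export
simulate_species_tree <- function(n_species, strains_per_species,
                                  within_species_div, between_species_div,
                                  seed = 1L) {
  strains_per_species <- rep_len(as.integer(strains_per_species), n_species)
  if (any(strains_per_species < 1)) stop("every species needs >= 1 strain")
  with_seed(seed, {
    clade_newick <- function(labels, depth) {
      m <- length(labels)
      if (m == 1) return(list(nwk = labels, height = 0))
      # random join order; coalescence depths increasing, clade root at `depth`
      depths <- if (m == 2) depth else
        c(sort(stats::runif(m - 2, 0.25 * depth, 0.9 * depth)), depth)
      nodes <- lapply(labels, function(l) list(nwk = l, height = 0))
      for (j in seq_len(m - 1)) {
        pick <- sample.int(length(nodes), 2L)
        a <- nodes[[pick[1]]]; b <- nodes[[pick[2]]]
        h <- depths[j]
        nwk <- sprintf("(%s:%.10f,%s:%.10f)", a$nwk, h - a$height,
                       b$nwk, h - b$height)
        nodes <- c(nodes[-pick], list(list(nwk = nwk, height = h)))
      }
      nodes[[1]]
    }
    clades <- vector("list", n_species)
    truth <- character(0)
    for (i in seq_len(n_species)) {
      labs <- sprintf("s%02d_%02d", i, seq_len(strains_per_species[i]))
      truth[labs] <- sprintf("species%02d", i)
      clades[[i]] <- clade_newick(labs, if (strains_per_species[i] > 1)
        within_species_div else 0)
    }
    nwk <- if (n_species == 1) {
      paste0(clades[[1]]$nwk, ";")
    } else {
      parts <- vapply(clades, function(cl)
        sprintf("%s:%.10f", cl$nwk, between_species_div - cl$height),
        character(1))
      paste0("(", paste(parts, collapse = ","), ");")
    }
    tr <- ape::read.tree(text = nwk)
    attr(tr, "truth_species") <- truth
    tr
  })
}

#' Evolve one gene family along a tree under JC69
#'
#' Sites mutate independently on each branch with probability
#' `3/4 * (1 - exp(-4/3 * d))` for branch length `d * rate_multiplier`
#' (the exact Jukes-Cantor transition), substituting a uniform different base.
#' No indels, so the leaf sequences are aligned by construction.
#'
#' @param tree `phylo` with non-negative branch lengths.
#' @param ancestral_seq root sequence (string over ACGT).
#' @param rate_multiplier scales all branch lengths (0 = no change).
#' @param seed RNG seed.
#' @return named character vector, one equal-length sequence per leaf.
#' @export
evolve_family <- function(tree, ancestral_seq, rate_multiplier = 1, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), nchar(ancestral_seq) >= 1)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  with_seed(seed, {
    tr <- stats::reorder(tree, "cladewise")  # parents before children
    ntip <- length(tr$tip.label)
    nnode <- ntip + tr$Nnode
    L <- nchar(ancestral_seq)
    seqs <- vector("list", nnode)
    root <- ntip + 1L
    seqs[[root]] <- seq_to_int(ancestral_seq)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      d <- tr$edge.length[e] * rate_multiplier
      v <- seqs[[p]]
      p_diff <- 0.75 * (1 - exp(-4 * d / 3))
      if (p_diff > 0) {
        hit <- which(stats::runif(L) < p_diff)
        if (length(hit))
          v[hit] <- ((v[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
      }
      seqs[[ch]] <- v
    }
    out <- vapply(seq_len(ntip), function(i) int_to_seq(seqs[[i]]), character(1))
    names(out) <- tr$tip.label
    out
  })
}

# ---- genus construction -----------------------------------------------------

#' Build a synthetic genus (pre-recombination)
#'
#' Generates the species tree, core/accessory family alignments, paralog
#' copies, the 16S-like marker (evolving at 1/20 the core rate; 2-5 identical
#' copies per strain), a shared gene order with shared intergenic spacers
#' (keeping genomes collinear so fragment-based ANI behaves like it does on
#' real congeneric genomes), and per-strain contig break points.
#'
#' @param params a [sim_params()] object.
#' @return object of class `synthetic_genus` (without assembled genomes; see
#'   [simulate_genus()] for the one-call entry point).
#' @export
build_genus <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    tree <- simulate_species_tree(params$n_species, params$strains_per_species,
                                  params$within_species_div,
                                  params$between_species_div,
                                  seed = draw_seeds(1))
    truth_species <- attr(tree, "truth_species")
    strains <- sort(names(truth_species))
    n_strain <- length(strains)

    core_ids <- sprintf("core%04d", seq_len(params$n_core_genes))
    acc_ids <- if (params$n_accessory_genes > 0)
      sprintf("acc%04d", seq_len(params$n_accessory_genes)) else character(0)

    fam_seeds <- draw_seeds(params$n_core_genes + params$n_accessory_genes + 1L)
    alignments <- vector("list", length(core_ids) + length(acc_ids))
    names(alignments) <- c(core_ids, acc_ids)
    for (i in seq_along(core_ids))
      alignments[[core_ids[i]]] <-
        evolve_family(tree, random_seq(params$gene_len), 1, fam_seeds[i])

    # accessory occupancy: clade-specific blocks with prob accessory_clade_bias,
    # otherwise cosmopolitan with a U-shaped per-family occupancy probability
    presence <- matrix(FALSE, n_strain, length(acc_ids),
                       dimnames = list(strains, acc_ids))
    species_of <- truth_species[strains]
    for (j in seq_along(acc_ids)) {
      if (stats::runif(1) < params$accessory_clade_bias) {
        sp <- sample(unique(species_of), 1L)
        presence[species_of == sp, j] <- TRUE
      } else {
        # cosmopolitan family: U-shaped occupancy across species, with
        # within-species cohesion (strains of a carrier species almost
        # always share the gene, as in real accessory genomes)
        pr <- stats::rbeta(1, 0.3, 0.3)
        sp_all <- unique(species_of)
        carrier <- sp_all[stats::runif(length(sp_all)) < pr]
        keep <- species_of %in% carrier & stats::runif(n_strain) < 0.9
        if (!any(keep)) keep[sample.int(n_strain, 1L)] <- TRUE
        presence[keep, j] <- TRUE
      }
      full <- evolve_family(tree, random_seq(params$gene_len), 1,
                            fam_seeds[params$n_core_genes + j])
      alignments[[acc_ids[j]]] <- full[rownames(presence)[presence[, j]]]
    }

    # recent paralogs: per-genome per-core-family duplications, 0.5% extra div
    paralogs <- list()
    for (s in strains) {
      dup <- core_ids[stats::runif(length(core_ids)) < params$paralog_rate]
      for (f in dup)
        paralogs[[length(paralogs) + 1L]] <-
          data.frame(strain = s, family_id = f,
                     gene_id = paste0(s, "|", f, "|p1"),
                     seq = mutate_seq(alignments[[f]][[s]], 0.005),
                     stringsAsFactors = FALSE)
    }
    paralogs <- if (length(paralogs)) do.call(rbind, paralogs) else
      data.frame(strain = character(0), family_id = character(0),
                 gene_id = character(0), seq = character(0))

    marker_aln <- evolve_family(tree, random_seq(params$marker_len), 1 / 20,
                                fam_seeds[length(fam_seeds)])
    copy_range <- params$marker_copies_range[1]:params$marker_copies_range[2]
    n_copies <- copy_range[sample.int(length(copy_range), n_strain,
                                      replace = TRUE)]
    marker_seqs <- lapply(seq_len(n_strain), function(i)
      rep(marker_aln[[strains[i]]], n_copies[i]))
    names(marker_seqs) <- strains

    gene_order <- sample(c(core_ids, acc_ids))
    spacers <- vapply(seq_len(length(gene_order) + 1L),
                      function(i) random_seq(sample(100:300, 1L)), character(1))
    contig_breaks <- lapply(seq_len(n_strain), function(i) {
      k <- sample.int(5L, 1L)
      if (k == 1) integer(0) else
        sort(sample(seq_len(length(gene_order) - 1L), min(k - 1L, length(gene_order) - 1L)))
    })
    names(contig_breaks) <- strains

    genus <- list(params = params, tree = tree, truth_species = truth_species,
                  strains = strains, core_ids = core_ids, acc_ids = acc_ids,
                  alignments = alignments, presence = presence,
                  paralogs = paralogs, marker_seqs = marker_seqs,
                  gene_order = gene_order, spacers = spacers,
                  contig_breaks = contig_breaks,
                  truth_events = data.frame(family_id = character(0),
                                            donor_strain = character(0),
                                            recipient_strain = character(0),
                                            tract_start = integer(0),
                                            tract_end = integer(0)))
    class(genus) <- "synthetic_genus"
    assemble_genomes(genus)
  })
}

#' Assemble genomes and gene tables from the current family alignments
#'
#' Deterministic given the genus object: genes (plus tandem paralog copies)
#' are laid out in the shared order with the shared spacers, split into the
#' pre-drawn 1-5 contigs per strain. Coordinates are 0-based half-open.
#'
#' @param genus a `synthetic_genus`.
#' @return the genus with `$genomes` (strain -> named contig vector) and
#'   `$gene_tables` (one data frame) refreshed.
#' @export
assemble_genomes <- function(genus) {
  stopifnot(inherits(genus, "synthetic_genus"))
  genomes <- list()
  tables <- list()
  for (s in genus$strains) {
    slots <- split(seq_along(genus$gene_order),
                   findInterval(seq_along(genus$gene_order) - 1L,
                                genus$contig_breaks[[s]]) + 1L)
    rows <- list()
    contigs <- character(0)
    for (ci in seq_along(slots)) {
      parts <- character(0)
      pos <- 0L
      cname <- sprintf("%s_ctg%d", s, ci)
      for (gi in slots[[ci]]) {
        fam <- genus$gene_order[gi]
        sp <- genus$spacers[gi]
        parts <- c(parts, sp); pos <- pos + nchar(sp)
        allele <- genus$alignments[[fam]][s]
        if (!is.na(allele)) {
          gid <- paste0(s, "|", fam)
          rows[[length(rows) + 1L]] <- data.frame(
            strain = s, contig = cname, gene_id = gid, family_id = fam,
            start = pos, end = pos + nchar(allele), strand = "+",
            stringsAsFactors = FALSE)
          parts <- c(parts, allele); pos <- pos + nchar(allele)
          pp <- genus$paralogs[genus$paralogs$strain == s &
                               genus$paralogs$family_id == fam, , drop = FALSE]
          for (k in seq_len(nrow(pp))) {
            psp <- genus$spacers[length(genus$gene_order) + 1L]
            parts <- c(parts, psp); pos <- pos + nchar(psp)
            rows[[length(rows) + 1L]] <- data.frame(
              strain = s, contig = cname, gene_id = pp$gene_id[k],
              family_id = fam, start = pos, end = pos + nchar(pp$seq[k]),
              strand = "+", stringsAsFactors = FALSE)
            parts <- c(parts, pp$seq[k]); pos <- pos + nchar(pp$seq[k])
          }
        }
      }
      contigs[cname] <- paste(parts, collapse = "")
    }
    genomes[[s]] <- contigs
    tables[[s]] <- do.call(rbind, rows)
  }
  genus$genomes <- genomes
  genus$gene_tables <- do.call(rbind, tables)
  rownames(genus$gene_tables) <- NULL
  genus
}

#' Apply cross-species homologous recombination events
#'
#' For `recomb_gene_fraction` of the core families, one donor tract
#' (`recomb_tract_fraction` of the gene; 1.0 replaces the whole allele)
#' overwrites the recipient strain's allele; donor and recipient always belong
#' to different species. Events are appended to the truth ledger and genomes
#' are re-assembled.
#'
#' @param genus a `synthetic_genus`.
#' @param params a [sim_params()] (for the recombination fractions).
#' @param seed RNG seed.
#' @return modified genus with `$truth_events` filled in.
#' @export
apply_recombination <- function(genus, params, seed = 1L) {
  stopifnot(inherits(genus, "synthetic_genus"))
  frac <- params$recomb_gene_fraction
  if (frac == 0) return(genus)
  if (params$n_species < 2)
    stop("recombination requires >= 2 species")
  with_seed(seed, {
    n_ev <- round(frac * length(genus$core_ids))
    fams <- sample(genus$core_ids, n_ev)
    species_of <- genus$truth_species
    events <- vector("list", n_ev)
    for (i in seq_along(fams)) {
      f <- fams[i]
      sp_pair <- sample(unique(species_of), 2L)
      donor <- sample(names(species_of)[species_of == sp_pair[1]], 1L)
      recip <- sample(names(species_of)[species_of == sp_pair[2]], 1L)
      L <- nchar(genus$alignments[[f]][[donor]])
      tlen <- max(1L, round(params$recomb_tract_fraction * L))
      t0 <- if (tlen >= L) 0L else sample(0:(L - tlen), 1L)  # 0-based half-open
      recip_seq <- genus$alignments[[f]][[recip]]
      donor_seq <- genus$alignments[[f]][[donor]]
      substr(recip_seq, t0 + 1L, t0 + tlen) <-
        substr(donor_seq, t0 + 1L, t0 + tlen)
      genus$alignments[[f]][[recip]] <- recip_seq
      events[[i]] <- data.frame(family_id = f, donor_strain = donor,
                                recipient_strain = recip,
                                tract_start = t0, tract_end = t0 + tlen,
                                stringsAsFactors = FALSE)
    }
    genus$truth_events <- rbind(genus$truth_events, do.call(rbind, events))
    assemble_genomes(genus)
  })
}

#' Simulate a complete genus
#'
#' One-call wrapper: [build_genus()], then [apply_recombination()] when
#' requested. Fully deterministic under `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return a `synthetic_genus` with assembled genomes, gene tables, truth
#'   species labels and the recombination-event ledger.
#' @export
simulate_genus <- function(params) {
  genus <- build_genus(params)
  if (params$recomb_gene_fraction > 0)
    genus <- apply_recombination(genus, params,
                                 seed = params$seed + 104729L)
  genus
}

#' Write a genus to disk
#'
#' Emits per-strain genome FASTAs (one record per contig), per-strain gene
#' tables, per-family aligned FASTAs, the 16S-like marker copies, and the
#' ground-truth species/event tables. Byte-identical across runs for the same
#' genus object.
#'
#' @param genus a `synthetic_genus`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
emit_genus <- function(genus, out_dir) {
  stopifnot(inherits(genus, "synthetic_genus"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", out_dir)
  for (d in c("genomes", "gene_tables", "alignments", "markers"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  for (s in genus$strains) {
    write_fasta(genus$genomes[[s]], file.path(out_dir, "genomes", paste0(s, ".fna")))
    tab <- genus$gene_tables[genus$gene_tables$strain == s, , drop = FALSE]
    utils::write.table(tab[, c("gene_id", "family_id", "contig", "start", "end",
                               "strand")],
                       file.path(out_dir, "gene_tables", paste0(s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cps <- genus$marker_seqs[[s]]
    names(cps) <- sprintf("%s|16S_copy%d", s, seq_along(cps))
    write_fasta(cps, file.path(out_dir, "markers", paste0(s, "_16S.fasta")))
  }
  for (f in names(genus$alignments))
    write_fasta(genus$alignments[[f]],
                file.path(out_dir, "alignments", paste0(f, ".fasta")))
  utils::write.table(data.frame(strain = names(genus$truth_species),
                                species = unname(genus$truth_species)),
                     file.path(out_dir, "truth_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genus$truth_events,
                     file.path(out_dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(genus$tree, file.path(out_dir, "species_tree.nwk"))
  invisible(out_dir)
}

#' Extract gene sequences by slicing genomes with a gene table
#'
#' Coordinates are 0-based half-open; this is the same path a user of real
#' annotated genomes would take.
#'
#' @param genomes strain -> named character vector of contigs.
#' @param gene_table data frame with columns strain, contig, gene_id, start, end.
#' @return named character vector gene_id -> sequence.
#' @export
extract_gene_seqs <- function(genomes, gene_table) {
  out <- character(nrow(gene_table))
  for (i in seq_len(nrow(gene_table))) {
    ctg <- genomes[[gene_table$strain[i]]][[gene_table$contig[i]]]
    out[i] <- substr(ctg, gene_table$start[i] + 1L, gene_table$end[i])
  }
  names(out) <- gene_table$gene_id
  out
}
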
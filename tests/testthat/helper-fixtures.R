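# Shared fixtures, built in code at test time.

# an ortho_matrix constructed directly from a counts matrix (tests of the
# pan-genome stage shouldn't have to run the clustering stage)
make_om <- function(counts, singleton_strains = character(0)) {
  members <- lapply(seq_len(ncol(counts)), function(j) {
    reps <- counts[, j]
    unlist(lapply(which(reps > 0), function(i)
      sprintf("%s|%s|m%d", rownames(counts)[i], colnames(counts)[j],
              seq_len(reps[i]))))
  })
  names(members) <- colnames(counts)
  singles <- if (length(singleton_strains))
    data.frame(gene = sprintf("%s|single%02d", singleton_strains,
                              seq_along(singleton_strains)),
               strain = singleton_strains, stringsAsFactors = FALSE)
  else data.frame(gene = character(0), strain = character(0))
  structure(list(strains = rownames(counts), og_ids = colnames(counts),
                 counts = counts, members = members, singletons = singles),
            class = "ortho_matrix")
}

# a small fixed genus reused by several files (memoised per session)
.tiny_genus_cache <- new.env(parent = emptyenv())
tiny_genus <- function() {
  if (is.null(.tiny_genus_cache$g)) {
    p <- sim_params(n_species = 3, strains_per_species = 2, n_core_genes = 15,
                    n_accessory_genes = 8, paralog_rate = 0.05, seed = 401)
    .tiny_genus_cache$g <- simulate_genus(p)
  }
  .tiny_genus_cache$g
}

rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else phylodelim:::with_seed(seed, draw())
}

# mutate a fraction of positions, always to a different base
mutate_frac <- function(s, frac, seed = 1) {
  phylodelim:::with_seed(seed, {
    v <- strsplit(s, "")[[1]]
    idx <- sample(length(v), round(frac * length(v)))
    for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  })
}
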
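#' Read a multi-record FASTA file
#'
#' Sequences are upper-cased, `U` is mapped to `T`, and any character outside
#' the `{A,C,G,T,N,-}` alphabet is replaced by `N`, so that one canonical
#' alphabet feeds every identity computation downstream. Record order is
#' preserved; ids are the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA format error in '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) stop("FASTA format error: no records in '", path, "'")
  ids <- sub("\\s.*$", "", names(ss))
  if (any(!nzchar(ids))) stop("FASTA format error: empty record id in '", path, "'")
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_seq(as.character(ss))
  if (any(!nzchar(seqs))) stop("FASTA format error: empty sequence in '", path, "'")
  names(seqs) <- ids
  seqs
}

#' Canonicalize a nucleotide string
#' @param s character vector of sequences.
#' @return upper-case sequences over `{A,C,G,T,N,-}`.
#' @export
normalize_seq <- function(s) {
  s <- gsub("[ \t\r]", "", toupper(s))
  s <- chartr("U", "T", s)
  gsub("[^ACGTN-]", "N", s)
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over \pkg{ape}. Support values are carried as internal-node
#' labels (the most portable Newick dialect); branch lengths survive a
#' round-trip to at least 6 decimals.
#'
#' @param tree a `phylo` object with at least 2 named leaves.
#' @param path file path.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 8L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 leaves")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("unnamed leaf in tree")
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("Newick format error in '", path, "'")
  tr
}

#' Read a labelled numeric matrix from TSV
#'
#' First row holds column labels, first column row labels. Ragged rows and
#' non-numeric cells are format errors.
#'
#' @param path file path.
#' @return numeric matrix with dimnames, label order preserved.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("matrix TSV format error: need header plus >= 1 row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol_expect <- length(header)
  body <- cells[-1]
  widths <- lengths(body)
  if (any(widths != ncol_expect))
    stop("matrix TSV format error: ragged row(s) ",
         paste(which(widths != ncol_expect), collapse = ", "))
  row_labels <- vapply(body, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1]), numeric(ncol_expect - 1L)))
  if (anyNA(vals)) stop("matrix TSV format error: non-numeric cell")
  m <- t(matrix(vals, nrow = ncol_expect - 1L))
  dimnames(m) <- list(row_labels, header[-1])
  m
}

#' @rdname read_matrix_tsv
#' @param m numeric matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, digits = 15)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Pipeline configuration
#'
#' Central knobs shared by the analysis stages; defaults follow the study
#' design this package reproduces (similarity cutoff 70, inflation 1.5,
#' PHI window 100 nt, alpha 0.01, 1000 permutations, 1020-nt ANI fragments,
#' 95 / 96.5 / 0.6 delineation thresholds, 100 / 1000 bootstraps).
#'
#' @param similarity_cutoff percent identity cutoff for orthology hits.
#' @param evalue_analog retained for provenance; similarity filtering uses
#'   `similarity_cutoff` plus `min_coverage` instead of e-values.
#' @param inflation Markov-clustering inflation exponent.
#' @param min_coverage minimum fraction of the shorter gene aligned.
#' @param phi_window PHI window in alignment positions (nt).
#' @param alpha significance level of the recombination screen.
#' @param n_permutations permutation count for PHI/MaxChi/NSS (>= 19).
#' @param fragment_len ANI fragment length in nt.
#' @param ani_species_threshold percent ANI for same-species pairs.
#' @param gani_threshold percent gANI for same-species pairs.
#' @param af_threshold alignment-fraction threshold for same-species pairs.
#' @param bootstrap_gene per-gene bootstrap replicates.
#' @param bootstrap_concat concatenated-tree bootstrap replicates.
#' @param rng_seed master seed; every stochastic stage consumes from it.
#' @param verbose emit progress to stderr.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(similarity_cutoff = 70, evalue_analog = 1e-5,
                            inflation = 1.5, min_coverage = 0.5,
                            phi_window = 100L, alpha = 0.01,
                            n_permutations = 1000L, fragment_len = 1020L,
                            ani_species_threshold = 95, gani_threshold = 96.5,
                            af_threshold = 0.6, bootstrap_gene = 100L,
                            bootstrap_concat = 1000L, rng_seed = 1L,
                            verbose = FALSE) {
  cfg <- list(similarity_cutoff = similarity_cutoff,
              evalue_analog = evalue_analog, inflation = inflation,
              min_coverage = min_coverage, phi_window = as.integer(phi_window),
              alpha = alpha, n_permutations = as.integer(n_permutations),
              fragment_len = as.integer(fragment_len),
              ani_species_threshold = ani_species_threshold,
              gani_threshold = gani_threshold, af_threshold = af_threshold,
              bootstrap_gene = as.integer(bootstrap_gene),
              bootstrap_concat = as.integer(bootstrap_concat),
              rng_seed = as.integer(rng_seed), verbose = isTRUE(verbose))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$similarity_cutoff >= 0, cfg$similarity_cutoff <= 100,
            cfg$inflation > 1,
            cfg$min_coverage > 0, cfg$min_coverage <= 1,
            cfg$phi_window >= 1,
            cfg$alpha >= 0, cfg$alpha <= 1,
            cfg$fragment_len >= 100,
            cfg$ani_species_threshold > 0, cfg$ani_species_threshold <= 100,
            cfg$gani_threshold > 0, cfg$gani_threshold <= 100,
            cfg$af_threshold > 0, cfg$af_threshold <= 1,
            cfg$bootstrap_gene >= 1, cfg$bootstrap_concat >= 1)
  if (cfg$n_permutations < 19)
    stop("n_permutations must be >= 19")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a structured JSON config file
#'
#' Two optional top-level sections are recognised: `pipeline` (arguments for
#' [pipeline_config()]) and `simulation` (arguments for [sim_params()]). A flat
#' file is treated as the `pipeline` section.
#'
#' @param path JSON file.
#' @return list with elements `pipeline` and (possibly NULL) `simulation`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pipe_args <- raw$pipeline %||% raw[setdiff(names(raw), "simulation")]
  pipeline <- do.call(pipeline_config, pipe_args)
  simulation <- if (!is.null(raw$simulation)) do.call(sim_params, raw$simulation)
  list(pipeline = pipeline, simulation = simulation)
}

# stderr logger; silenced unless option or config asks for verbosity
pd_log <- function(..., verbose = getOption("phylodelim.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[phylodelim] ", ...)
  invisible(NULL)
}
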
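# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# lookup table: utf8 code -> base index 1..4, NA for anything else (N, -, ...)
.base_lut <- local({
  lut <- rep(NA_integer_, 128)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# sub-seeds derived from one stream; kept < 2^31
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

#' Integer encoding of a DNA string (A=1 C=2 G=3 T=4, else NA)
#' @noRd
seq_to_int <- function(s) .base_lut[utf8ToInt(s)]

#' Back-conversion from integer codes; NA renders as "N"
#' @noRd
int_to_seq <- function(v) {
  codes <- utf8ToInt("ACGTN")[ifelse(is.na(v), 5L, v)]
  intToUtf8(codes)
}

random_seq <- function(len) int_to_seq(sample.int(4L, len, replace = TRUE))

# point mutations at rate `rate` per site under JC (new base uniform among other 3)
mutate_seq <- function(s, rate) {
  v <- seq_to_int(s)
  hit <- which(stats::runif(length(v)) < rate & !is.na(v))
  if (length(hit))
    v[hit] <- ((v[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  int_to_seq(v)
}

#' Alignment (named character vector of equal-length strings) to character matrix
#' rows = sequences, columns = sites
#' @noRd
aln_char_matrix <- function(aln) {
  stopifnot(length(aln) >= 1)
  lens <- nchar(aln)
  if (length(unique(lens)) != 1)
    stop("alignment sequences have unequal lengths")
  m <- matrix(unlist(strsplit(aln, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln), byrow = TRUE)
  rownames(m) <- names(aln)
  m
}

#' Alignment to integer matrix (NA for gaps/ambiguities)
#' @noRd
aln_int_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln, seq_to_int))
  rownames(m) <- names(aln)
  m
}

# minimal union-find used by clustering and delineation
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}
uf_components <- function(n, edges_i, edges_j) {
  parent <- uf_new(n)
  for (e in seq_along(edges_i)) parent <- uf_union(parent, edges_i[e], edges_j[e])
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

# round-half-even percentage with one decimal, as printed in the summaries
pct1 <- function(num, den) round(100 * num / den, 1)
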